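#' Area under the ROC curve
#'
#' Computed exactly as the Mann-Whitney pair statistic
#' `P(score+ > score-) + 0.5 * P(tie)` via midranks, so tied scores receive
#' half credit.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  npos <- sum(labels)
  nneg <- length(labels) - npos
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of the precision-recall curve without interpolation:
#' `AP = sum over thresholds of (recall_k - recall_{k-1}) * precision_k`,
#' with tied scores grouped into one threshold. Prevalence-sensitive by
#' construction.
#'
#' @inheritParams auroc
#' @return average precision in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  npos <- sum(labels)
  if (npos == 0L) stop("at least one positive label is required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / npos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' ROC curve coordinates
#'
#' @inheritParams auroc
#' @return data.frame with columns `fpr`, `tpr`, `threshold`, monotone in
#'   `fpr` (tied scores grouped).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels)
  nneg <- length(labels) - npos
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos),
             threshold = c(Inf, s[last]))
}

#' Precision-recall curve coordinates
#'
#' @inheritParams auroc
#' @return data.frame with columns `recall`, `precision`, `threshold`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels)
  if (npos == 0L) stop("at least one positive label is required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(recall = tp[last] / npos,
             precision = tp[last] / (tp[last] + fp[last]),
             threshold = s[last])
}

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Resamples (score, label) pairs with replacement `n_boot` times under a
#' fixed seed and returns the percentile interval of the metric. Resamples
#' that lose one of the classes are redrawn (their count is recorded in the
#' `n_redraws` attribute).
#'
#' @param metric a function `(scores, labels) -> numeric`, e.g. [auroc()].
#' @param scores,labels the evaluation data (`n >= 10`, both classes).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @param max_attempts redraw budget per resample before erroring.
#' @return numeric `c(low, high)` with attributes `n_redraws` and `point`.
#' @export
bootstrap_ci <- function(metric, scores, labels, n_boot = 2000L, level = 0.95,
                         seed = 0L, max_attempts = 100L) {
  labels <- as.integer(labels)
  n <- length(scores)
  if (n < 10L) stop("bootstrap CI needs at least 10 samples")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  stats_boot <- with_local_seed(seed, {
    redraws <- 0L
    vals <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(max_attempts)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redraws <- redraws + 1L
        if (attempt == max_attempts) {
          stop("could not draw a two-class resample within the attempt budget")
        }
      }
      vals[b] <- metric(scores[idx], labels[idx])
    }
    list(vals = vals, redraws = redraws)
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_boot$vals, c(alpha, 1 - alpha)))
  attr(ci, "n_redraws") <- stats_boot$redraws
  attr(ci, "point") <- metric(scores, labels)
  ci
}

#' Classification metric report
#'
#' AUROC and AUPRC point estimates with 95% percentile-bootstrap confidence
#' intervals and full curve coordinates.
#'
#' @inheritParams bootstrap_ci
#' @return object of class `metric_report`.
#' @export
metric_report <- function(scores, labels, n_boot = 2000L, level = 0.95,
                          seed = 0L) {
  ci_roc <- bootstrap_ci(auroc, scores, labels, n_boot, level, seed)
  ci_pr <- bootstrap_ci(auprc, scores, labels,
                        n_boot, level, derive_seed(seed, "auprc"))
  structure(list(auroc = auroc(scores, labels),
                 auroc_ci = as.numeric(ci_roc),
                 auprc = auprc(scores, labels),
                 auprc_ci = as.numeric(ci_pr),
                 level = level, n_boot = n_boot, seed = seed,
                 n = length(labels),
                 roc = roc_curve(scores, labels),
                 pr = pr_curve(scores, labels)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f [%.0f%% CI: %.3f-%.3f]\nAUPRC %.3f [%.0f%% CI: %.3f-%.3f]\n",
              x$auroc, 100 * x$level, x$auroc_ci[1], x$auroc_ci[2],
              x$auprc, 100 * x$level, x$auprc_ci[1], x$auprc_ci[2]))
  invisible(x)
}

#' Layer-by-attribute expressivity profile
#'
#' Fills the full (layer stage x attribute) grid of expressivity estimates by
#' composing [extract_features()] and [expressivity()]. Cells are computed
#' independently with seeds derived from `seed0`, the stage and the
#' attribute, so results do not depend on computation order.
#'
#' @param model a trained backbone from [train_classifier()].
#' @param images an `image_set` (or pixel matrix) to extract features from.
#' @param cohort data.frame holding the attribute columns for the same
#'   samples.
#' @param attributes character vector of cohort column names to probe.
#' @param stages layer stages to tap (default early/mid/final).
#' @param net_cfg,train_cfg MINE configuration, see [expressivity()].
#' @param seed0 base seed.
#' @param binary_attributes attribute names handled as binary.
#' @return object of class `expressivity_profile`: a data.frame `grid`
#'   (stage, attribute, mean, std, negative_flag) plus the full list of
#'   [expressivity()] results.
#' @export
expressivity_profile <- function(model, images, cohort, attributes,
                                 stages = c("early", "mid", "final"),
                                 net_cfg = statistics_net_config(),
                                 train_cfg = mine_train_config(),
                                 seed0 = 0L,
                                 binary_attributes = c("sex", "slvh")) {
  missing_cols <- setdiff(attributes, colnames(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort is missing attribute column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  cells <- list()
  rows <- list()
  for (st in stages) {
    fm <- extract_features(model, images, st)
    keep <- setdiff(seq_len(ncol(fm$values)),
                    attr(fm, "zero_variance") %||% integer(0))
    fm_use <- feature_matrix(fm$values[, keep, drop = FALSE],
                             sample_ids = fm$sample_ids,
                             layer_tag = fm$layer_tag)
    for (at in attributes) {
      kind <- if (at %in% binary_attributes) "binary" else "continuous"
      av <- attribute_vector(cohort[[at]], kind = kind, name = at)
      res <- expressivity(fm_use, av, net_cfg, train_cfg,
                          seed0 = derive_seed(seed0, st, at))
      cells[[paste(st, at, sep = ":")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, attribute = at, mean = res$mean_estimate,
        std = res$std_estimate, negative_flag = res$negative_flag,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(grid = do.call(rbind, rows), cells = cells,
                 stages = stages, attributes = attributes,
                 config_fingerprint = hash_obj(list(net_cfg, train_cfg, seed0))),
            class = "expressivity_profile")
}

#' @export
print.expressivity_profile <- function(x, ...) {
  cat("<expressivity_profile> (nats)\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Check an expected expressivity ordering at one stage
#'
#' Ranks the mean estimates at the chosen stage and compares against an
#' expected attribute ordering (most to least expressive). Returns an
#' exact-match flag and the Kendall rank correlation; exact ties in the means
#' set `match = FALSE` with a tie flag and both orders reported.
#'
#' @param profile an [expressivity_profile()], or a named numeric vector of
#'   mean estimates.
#' @param stage stage to examine (ignored for a named vector).
#' @param expected character vector, expected order from most to least
#'   expressive.
#' @return list with `match`, `tau`, `estimated_order`, `expected_order`,
#'   `tie`.
#' @export
ordering_check <- function(profile, stage = "final", expected) {
  if (inherits(profile, "expressivity_profile")) {
    g <- profile$grid[profile$grid$stage == stage, ]
    if (!all(expected %in% g$attribute)) {
      stop("not all expected attributes are present at this stage")
    }
    means <- stats::setNames(g$mean, g$attribute)[expected]
  } else {
    means <- profile[expected]
  }
  if (anyNA(means)) stop("missing mean estimate for an expected attribute")
  est_order <- names(sort(means, decreasing = TRUE))
  tie <- anyDuplicated(means) > 0
  # expected ranks: first name is rank 1 (highest)
  exp_rank <- seq_along(expected)
  est_rank <- rank(-means, ties.method = "average")
  tau <- stats::cor(exp_rank, est_rank, method = "kendall")
  list(match = identical(est_order, expected) && !tie,
       tau = tau,
       estimated_order = est_order,
       expected_order = expected,
       tie = tie)
}
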