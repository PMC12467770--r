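#' Feature matrix container
#'
#' Wraps an `n x d` matrix of per-sample representations harvested from one
#' layer of a classifier, together with sample identifiers and an optional
#' provenance tag naming the layer the rows came from.
#'
#' @param values numeric matrix, one row per sample, one column per feature
#'   dimension. All entries must be finite; at least 2 rows and 1 column.
#' @param sample_ids character or integer identifiers, one per row; must be
#'   unique. Defaults to `1:n`.
#' @param layer_tag optional character label recording which layer produced
#'   the features.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, sample_ids = NULL, layer_tag = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a feature matrix needs at least 2 samples")
  if (ncol(values) < 1L) stop("a feature matrix needs at least 1 dimension")
  stop_if_not_finite(values, "feature matrix")
  if (is.null(sample_ids)) sample_ids <- seq_len(nrow(values))
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length must match the number of rows")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  structure(list(values = values, sample_ids = sample_ids,
                 layer_tag = layer_tag),
            class = "feature_matrix")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) return(x)
  feature_matrix(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d dimensions%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$layer_tag)) "" else paste0(" [", x$layer_tag, "]")))
  invisible(x)
}

#' Scalar attribute vector
#'
#' A length-`n` scalar attribute paired with a feature matrix: continuous
#' (age in years, echocardiographic dimensions in cm, or any real-valued
#' covariate) or binary coded 0/1 (sex, class label).
#'
#' @param values numeric vector, all finite, with positive sample variance.
#' @param kind `"continuous"` or `"binary"`; binary requires every entry in
#'   \{0, 1\}.
#' @param name attribute label used in reports.
#' @return an object of class `attribute_vector`.
#' @export
attribute_vector <- function(values, kind = c("continuous", "binary"),
                             name = "attribute") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  stop_if_not_finite(values, sprintf("attribute '%s'", name))
  if (stats::var(values) <= 0) {
    stop(sprintf("attribute '%s' has zero sample variance", name))
  }
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop(sprintf("binary attribute '%s' must contain only 0/1", name))
  }
  structure(list(values = values, kind = kind, name = name),
            class = "attribute_vector")
}

as_attribute_vector <- function(x, name = "attribute") {
  if (inherits(x, "attribute_vector")) return(x)
  kind <- if (all(x %in% c(0, 1))) "binary" else "continuous"
  attribute_vector(x, kind, name)
}

#' Statistics-network architecture
#'
#' Configuration of the critic network \eqn{T_\theta} that scores
#' feature-attribute pairs: an MLP mapping the concatenated `(d+1)`-vector to
#' one scalar. The default two-hidden-layer 256/64 design with ELU activations
#' and Xavier initialization is the reference architecture; the shallow
#' `c(256)` and deep `c(512, 256, 64)` variants support ablation of the
#' ranking's architecture-invariance.
#'
#' @param hidden_sizes positive integers, widths of the hidden layers.
#' @param activation `"elu"` (default) or `"relu"`.
#' @param init weight initialization scheme; only `"xavier"` is implemented.
#' @return an object of class `statistics_net_config`.
#' @export
statistics_net_config <- function(hidden_sizes = c(256L, 64L),
                                  activation = c("elu", "relu"),
                                  init = "xavier") {
  activation <- match.arg(activation)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L)) {
    stop("hidden_sizes must be a non-empty vector of positive integers")
  }
  if (!identical(init, "xavier")) stop("only Xavier initialization is implemented")
  structure(list(hidden_sizes = hidden_sizes, activation = activation,
                 init = init),
            class = "statistics_net_config")
}

#' MINE training configuration
#'
#' Optimization settings for the Donsker-Varadhan bound: Adam with learning
#' rate 1e-3 and mini-batches of 100 pairs, an exponential moving average
#' (decay 0.99) damping the marginal term in the gradient, estimates averaged
#' over `n_seeds` independent fits, and plateau early stopping on the
#' full-data bound.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size `b`; must not exceed `n` at fit time.
#' @param max_epochs upper bound on training epochs.
#' @param ema_decay decay of the running mean of `exp(marginal scores)` used
#'   in the gradient denominator (in (0,1)).
#' @param n_seeds number of independent fits `M` averaged into one estimate.
#' @param plateau_patience epochs without monitored-bound improvement before
#'   stopping.
#' @param val_fraction fraction of pairs held out as an internal monitoring
#'   split: the per-epoch bound that drives plateau stopping and checkpoint
#'   selection is computed on these held-out pairs, which keeps the stopping
#'   signal from being inflated by critic overfitting (the reported estimate
#'   is still the full-data bound of the selected network). `0` monitors the
#'   training data itself.
#' @param standardize_inputs z-score feature columns and continuous
#'   attributes before fitting (binary attributes stay 0/1). Mutual
#'   information is invariant to these affine maps; standardization only
#'   stabilizes optimization.
#' @return an object of class `mine_train_config`.
#' @export
mine_train_config <- function(learning_rate = 1e-3, batch_size = 100L,
                              max_epochs = 200L, ema_decay = 0.99,
                              n_seeds = 10L, plateau_patience = 20L,
                              val_fraction = 0.2,
                              standardize_inputs = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 2, max_epochs >= 1,
            ema_decay > 0, ema_decay < 1, n_seeds >= 1, plateau_patience >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 ema_decay = ema_decay,
                 n_seeds = as.integer(n_seeds),
                 plateau_patience = as.integer(plateau_patience),
                 val_fraction = val_fraction,
                 standardize_inputs = isTRUE(standardize_inputs)),
            class = "mine_train_config")
}

#' Mismatched pairs for the marginal term
#'
#' Builds the mismatched (marginal) feature-attribute pairs for one
#' mini-batch. The marginal expectation averages `exp(T(f_i, a_j))` with
#' `i != j`; this routine realizes the constraint as a seeded random
#' derangement (a cyclic shift of a shuffled order), so exactly `b` pairs are
#' produced, every feature index and every attribute index is used exactly
#' once, and no pair is matched.
#'
#' @param feature_batch matrix of feature rows for the batch (or anything with
#'   a row count); only its length matters here.
#' @param attribute_batch attribute values for the same batch.
#' @param rng_seed integer seed for the shuffle.
#' @return data.frame with columns `feature_index` and `attribute_index`
#'   (1-based positions within the batch).
#' @export
make_marginal_pairs <- function(feature_batch, attribute_batch, rng_seed = 0L) {
  b <- if (is.matrix(feature_batch)) nrow(feature_batch) else length(feature_batch)
  ba <- length(attribute_batch)
  if (!is.null(attribute_batch) && ba > 0 && ba != b) {
    stop("feature and attribute batches must have the same length")
  }
  if (b < 2L) {
    stop("batch length < 2: the i != j constraint is unsatisfiable")
  }
  p <- with_local_seed(rng_seed, sample.int(b))
  attribute_index <- integer(b)
  attribute_index[p] <- p[c(2:b, 1L)]
  data.frame(feature_index = seq_len(b), attribute_index = attribute_index)
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Donsker-Varadhan lower bound
#'
#' Evaluates the DV lower bound on mutual information from critic scores on
#' one batch: `mean(joint_scores) - log(mean(exp(marginal_scores)))`, in
#' nats. The log-mean-exp is computed max-shifted so large scores cannot
#' overflow.
#'
#' @param joint_scores critic scores of matched pairs.
#' @param marginal_scores critic scores of mismatched pairs (same length).
#' @return the bound value in nats.
#' @export
dv_lower_bound <- function(joint_scores, marginal_scores) {
  if (length(joint_scores) == 0L || length(marginal_scores) == 0L) {
    stop("empty score vectors")
  }
  if (!all(is.finite(joint_scores))) stop("non-finite values in joint_scores")
  if (!all(is.finite(marginal_scores))) stop("non-finite values in marginal_scores")
  mean(joint_scores) - log_mean_exp(marginal_scores)
}

#' MINE mini-batch loss with EMA-stabilized marginal term
#'
#' The loss reported (and minimized) is the negative DV bound of the batch.
#' The exponential moving average of the mean of `exp(marginal_scores)` is the
#' state used by the gradient-path denominator during training, damping
#' mini-batch noise in the log term; the reported loss always uses the raw
#' batch term.
#'
#' @param joint_scores,marginal_scores critic scores for the batch.
#' @param ema_state running mean of `exp(marginal scores)`; `NULL` on the
#'   first batch (initialized from this batch).
#' @param ema_decay decay in (0,1).
#' @return list with `loss` (negative DV bound of the batch) and the updated
#'   `ema_state`.
#' @export
mine_batch_loss <- function(joint_scores, marginal_scores, ema_state = NULL,
                            ema_decay = 0.99) {
  bound <- dv_lower_bound(joint_scores, marginal_scores)
  batch_mean_exp <- exp(log_mean_exp(marginal_scores))
  if (is.null(ema_state)) {
    ema_state <- batch_mean_exp
  } else {
    if (!is.finite(ema_state) || ema_state <= 0) {
      stop("ema_state must be positive (log of non-positive value)")
    }
    ema_state <- ema_decay * ema_state + (1 - ema_decay) * batch_mean_exp
  }
  list(loss = -bound, ema_state = ema_state)
}

prepare_mine_inputs <- function(F, A, train_cfg) {
  F <- as_feature_matrix(F)
  A <- as_attribute_vector(A)
  fv <- F$values
  av <- A$values
  if (length(av) != nrow(fv)) {
    stop("feature matrix and attribute vector lengths differ")
  }
  if (train_cfg$batch_size > nrow(fv)) {
    stop(sprintf(paste0("n = %d is smaller than batch_size = %d; ",
                        "lower batch_size"), nrow(fv), train_cfg$batch_size))
  }
  n_tr <- nrow(fv) - floor(train_cfg$val_fraction * nrow(fv))
  if (train_cfg$batch_size > n_tr) {
    stop(sprintf(paste0("training split (%d) is smaller than batch_size = %d; ",
                        "lower batch_size or val_fraction"),
                 n_tr, train_cfg$batch_size))
  }
  if (train_cfg$standardize_inputs) {
    fv <- standardize_columns(fv)
    if (A$kind == "continuous") {
      av <- (av - mean(av)) / stats::sd(av)
    }
  }
  list(F = F, A = A, fv = fv, av = av)
}

#' Fit the statistics network on one seed
#'
#' Trains \eqn{T_\theta} by mini-batch gradient ascent on the DV bound with
#' per-epoch data shuffling and fresh derangements for the marginal term. The
#' returned `final_bound` is the DV bound evaluated on the full dataset (one
#' pass, fresh derangement) using the best-epoch network - not the last
#' mini-batch value. Training stops at `max_epochs` or when the full-data
#' bound fails to improve for `plateau_patience` epochs. Fully reproducible
#' given `(seed, data, configs)`.
#'
#' @param F a [feature_matrix()] (or plain matrix).
#' @param A an [attribute_vector()] (or plain numeric vector).
#' @param net_cfg a [statistics_net_config()].
#' @param train_cfg a [mine_train_config()].
#' @param seed integer seed keying initialization, shuffling and derangements.
#' @return list of class `mine_fit` with elements `network` (weights +
#'   activation), `final_bound` (nats), `bound_history`, `epochs_run`.
#' @export
train_statistics_network <- function(F, A,
                                     net_cfg = statistics_net_config(),
                                     train_cfg = mine_train_config(),
                                     seed = 0L) {
  inp <- prepare_mine_inputs(F, A, train_cfg)
  fit <- mine_train_cpp(inp$fv, inp$av, net_cfg$hidden_sizes,
                        net_cfg$activation, train_cfg$learning_rate,
                        train_cfg$batch_size, train_cfg$max_epochs,
                        train_cfg$ema_decay, train_cfg$plateau_patience,
                        train_cfg$val_fraction, as.double(seed))
  structure(list(network = list(weights = fit$weights,
                                activation = net_cfg$activation,
                                input_dim = ncol(inp$fv) + 1L),
                 final_bound = fit$final_bound,
                 bound_history = fit$bound_history,
                 epochs_run = fit$epochs_run,
                 seed = seed),
            class = "mine_fit")
}

#' Expressivity of an attribute in a feature representation
#'
#' The headline estimator: runs [train_statistics_network()] over `M`
#' independent seeds (`seed0, ..., seed0 + M - 1`) and averages the resulting
#' full-data DV bounds. Raw per-seed estimates are reported - slightly
#' negative values are kept, never truncated to zero, and flagged.
#'
#' @inheritParams train_statistics_network
#' @param seed0 first seed of the `M`-seed protocol.
#' @return object of class `expressivity_result`: `per_seed_estimates`,
#'   `mean_estimate`, `std_estimate` (all in nats), `attribute_name`,
#'   `layer_tag`, `config_fingerprint`, `units = "nats"`, `negative_flag`.
#' @export
expressivity <- function(F, A, net_cfg = statistics_net_config(),
                         train_cfg = mine_train_config(), seed0 = 0L) {
  F <- as_feature_matrix(F)
  A <- as_attribute_vector(A)
  seeds <- seed0 + seq_len(train_cfg$n_seeds) - 1L
  per_seed <- vapply(seeds, function(s) {
    train_statistics_network(F, A, net_cfg, train_cfg, seed = s)$final_bound
  }, numeric(1))
  res <- structure(list(
    per_seed_estimates = per_seed,
    mean_estimate = mean(per_seed),
    std_estimate = if (length(per_seed) > 1L) stats::sd(per_seed) else 0,
    attribute_name = A$name,
    layer_tag = F$layer_tag,
    config_fingerprint = hash_obj(list(net_cfg, train_cfg, seed0)),
    units = "nats",
    negative_flag = any(per_seed < 0),
    seeds = seeds), class = "expressivity_result")
  res
}

#' @export
print.expressivity_result <- function(x, ...) {
  cat(sprintf("<expressivity> %s%s: %.4f +/- %.4f nats (M = %d seeds)%s\n",
              x$attribute_name,
              if (is.null(x$layer_tag)) "" else paste0(" @ ", x$layer_tag),
              x$mean_estimate, x$std_estimate, length(x$per_seed_estimates),
              if (x$negative_flag) "  [flag: negative per-seed estimate]" else ""))
  invisible(x)
}

#' Read a feature table from a delimited file
#'
#' Expects a header `sample_id, f_0, ..., f_{d-1}` (comma- or tab-separated,
#' inferred from the file name).
#'
#' @param path file path.
#' @param layer_tag optional provenance tag to attach.
#' @return a [feature_matrix()].
#' @export
read_feature_table <- function(path, layer_tag = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("feature table needs a sample_id column")
  fcols <- setdiff(names(df), "sample_id")
  feature_matrix(as.matrix(df[, fcols, drop = FALSE]),
                 sample_ids = df$sample_id, layer_tag = layer_tag)
}

#' Read an attribute column joined on sample ids
#'
#' @param path CSV with columns `sample_id` and the named attribute.
#' @param attribute column name to extract.
#' @param sample_ids optional id vector to join/align against (errors on
#'   missing ids).
#' @param kind attribute kind; inferred (0/1 implies binary) when `NULL`.
#' @return an [attribute_vector()].
#' @export
read_attribute_table <- function(path, attribute, sample_ids = NULL,
                                 kind = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("attribute table needs a sample_id column")
  if (!attribute %in% names(df)) {
    stop(sprintf("attribute column '%s' not found", attribute))
  }
  vals <- df[[attribute]]
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, df$sample_id)
    if (anyNA(idx)) stop("some sample_ids are missing from the attribute table")
    vals <- vals[idx]
  }
  if (is.null(kind)) {
    kind <- if (all(vals %in% c(0, 1))) "binary" else "continuous"
  }
  attribute_vector(vals, kind = kind, name = attribute)
}

#' Serialize expressivity results to JSON
#'
#' Writes one JSON record per result with per-seed estimates, mean, std,
#' config fingerprint and a units field fixed to `"nats"`.
#'
#' @param results a single `expressivity_result` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expressivity_json <- function(results, path) {
  if (inherits(results, "expressivity_result")) results <- list(results)
  recs <- lapply(results, function(r) {
    list(attribute = r$attribute_name,
         layer = r$layer_tag %||% NA,
         per_seed_estimates = r$per_seed_estimates,
         mean = r$mean_estimate,
         std = r$std_estimate,
         units = r$units,
         negative_flag = r$negative_flag,
         config_fingerprint = r$config_fingerprint)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
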