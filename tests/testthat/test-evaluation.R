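# independent oracles: exhaustive pair enumeration for AUROC, stepwise
# integral over ranked positives for average precision (unique scores)
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

ap_enumerate <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  hits <- which(y == 1)
  mean(vapply(seq_along(hits), function(k) k / hits[k], numeric(1)))
}

test_that("auroc equals exhaustive pair enumeration", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  # worked 3-sample example: one concordant, one discordant pair
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  set.seed(21)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels))
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auprc equals stepwise integration", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # worked 4-sample example: (1/1 + 2/3) / 2
  expect_equal(auprc(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)), 5 / 6)
  set.seed(22)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    labels <- c(1, sample(0:1, n - 1, replace = TRUE))
    scores <- sample(seq_len(50), n)  # unique scores
    expect_equal(auprc(scores / 50, labels), ap_enumerate(scores, labels))
  }
  # tied-score grouping: both tied samples sit at one threshold, so the
  # single step has precision 2/3 (hand-computed)
  expect_equal(auprc(c(0.5, 0.5, 0.5, 0.1), c(1, 1, 0, 0)), 2 / 3)
  expect_error(auprc(c(0.4, 0.6), c(0, 0)), "positive")
})

test_that("average precision approaches prevalence for random scores", {
  set.seed(23)
  n <- 20000
  labels <- rbinom(n, 1, 0.3)
  scores <- runif(n)
  expect_lt(abs(auprc(scores, labels) - 0.3), 0.02)
})

test_that("curves are monotone and consistent with the areas", {
  set.seed(24)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  roc <- roc_curve(scores, labels)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(max(roc$fpr), 1)
  expect_equal(max(roc$tpr), 1)
  # trapezoid over the ROC steps reproduces the Mann-Whitney AUROC
  expect_equal(sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2),
               auroc(scores, labels))
  pr <- pr_curve(scores, labels)
  expect_true(all(diff(pr$recall) >= 0))
  expect_equal(sum(diff(c(0, pr$recall)) * pr$precision),
               auprc(scores, labels))
})

test_that("bootstrap intervals are seeded, nested and degenerate-safe", {
  set.seed(25)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  ci_a <- bootstrap_ci(auroc, scores, labels, n_boot = 300, seed = 7)
  ci_b <- bootstrap_ci(auroc, scores, labels, n_boot = 300, seed = 7)
  expect_identical(as.numeric(ci_a), as.numeric(ci_b))
  ci_50 <- bootstrap_ci(auroc, scores, labels, n_boot = 300, level = 0.5,
                        seed = 7)
  expect_lte(ci_a[1], ci_50[1])
  expect_gte(ci_a[2], ci_50[2])
  # all-tie scores: every resample scores AUROC 0.5 exactly
  ci_tie <- bootstrap_ci(auroc, rep(0.4, 40), rep(c(0, 1), 20), n_boot = 100,
                         seed = 3)
  expect_equal(as.numeric(ci_tie), c(0.5, 0.5))
  expect_error(bootstrap_ci(auroc, rnorm(5), c(0, 1, 0, 1, 0)), "10")
})

test_that("bootstrap intervals cover a known true AUROC", {
  # scores: positives N(mu, 1), negatives N(0, 1) -> AUROC = pnorm(mu/sqrt(2))
  mu <- 1.2
  truth <- pnorm(mu / sqrt(2))
  set.seed(26)
  covered <- 0
  n_data <- 150
  for (i in seq_len(n_data)) {
    labels <- rep(c(1, 0), each = 60)
    scores <- c(rnorm(60, mu), rnorm(60))
    ci <- bootstrap_ci(auroc, scores, labels, n_boot = 400, seed = i)
    covered <- covered + (truth >= ci[1] && truth <= ci[2])
  }
  expect_gte(covered / n_data, 0.88)
})

test_that("metric_report assembles point estimates, CIs and curves", {
  set.seed(27)
  scores <- c(rnorm(50, 1), rnorm(50))
  labels <- rep(c(1, 0), each = 50)
  rep <- metric_report(scores, labels, n_boot = 200, seed = 2)
  expect_lte(rep$auroc_ci[1], rep$auroc)
  expect_gte(rep$auroc_ci[2], rep$auroc)
  expect_lte(rep$auprc_ci[1], rep$auprc)
  expect_gte(rep$auprc_ci[2], rep$auprc)
  expect_s3_class(rep$roc, "data.frame")
  expect_output(print(rep), "AUROC")
})

test_that("ordering_check scores rankings by Kendall tau", {
  means <- c(age = 1.0, sex = 0.6, IVSDd = 0.35, LVPWDd = 0.2, LVIDd = 0.05)
  expected <- names(means)
  oc <- ordering_check(means, expected = expected)
  expect_true(oc$match)
  expect_equal(oc$tau, 1)
  oc_rev <- ordering_check(means, expected = rev(expected))
  expect_false(oc_rev$match)
  expect_equal(oc_rev$tau, -1)
  # one adjacent swap among 5 items: tau = 1 - 2/choose(5,2)
  swapped <- means[c(1, 2, 4, 3, 5)]
  oc_swap <- ordering_check(swapped, expected = names(swapped))
  expect_false(oc_swap$match)
  expect_equal(oc_swap$tau, 1 - 2 / choose(5, 2))
  # exact ties flagged, never silently matched
  oc_tie <- ordering_check(c(a = 0.5, b = 0.5, c = 0.1),
                           expected = c("a", "b", "c"))
  expect_false(oc_tie$match)
  expect_true(oc_tie$tie)
})

test_that("expressivity profile fills the grid order-independently", {
  dat <- tiny_image_data()
  model <- tiny_conv_model()
  idx <- seq_len(100)
  tc <- quick_mine_cfg(n_seeds = 2L)
  tc$batch_size <- 25L
  prof <- expressivity_profile(model, dat$images[idx, ], dat$cohort[idx, ],
                               attributes = c("age", "sex"),
                               stages = c("early", "final"),
                               net_cfg = quick_net_cfg(), train_cfg = tc,
                               seed0 = 5)
  expect_equal(nrow(prof$grid), 4L)
  expect_setequal(names(prof$cells),
                  c("early:age", "early:sex", "final:age", "final:sex"))
  expect_true(all(vapply(prof$cells,
                         function(cl) length(cl$per_seed_estimates), 1L) == 2L))
  # cells derive their seeds from (stage, attribute): recomputing one cell in
  # isolation reproduces the grid value, so computation order cannot matter
  fm <- extract_features(model, dat$images[idx, ], "final")
  keep <- setdiff(seq_len(ncol(fm$values)), attr(fm, "zero_variance"))
  fm <- feature_matrix(fm$values[, keep, drop = FALSE], fm$sample_ids,
                       layer_tag = fm$layer_tag)
  av <- attribute_vector(dat$cohort$age[idx], "continuous", "age")
  solo <- expressivity(fm, av, quick_net_cfg(), tc,
                       seed0 = expressivity:::derive_seed(5, "final", "age"))
  expect_identical(solo$mean_estimate,
                   prof$cells[["final:age"]]$mean_estimate)
  expect_error(
    expressivity_profile(model, dat$images[idx, ], dat$cohort[idx, ],
                         attributes = c("age", "bmi")),
    "bmi")
})
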