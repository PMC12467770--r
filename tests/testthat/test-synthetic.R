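test_that("cohort sampling is deterministic and matches its config", {
  cfg <- cohort_config(n = 10000L, seed = 42L)
  coh <- sample_cohort(cfg)
  coh2 <- sample_cohort(cfg)
  expect_identical(coh, coh2)
  expect_false(identical(coh$age,
                         sample_cohort(cohort_config(n = 10000L, seed = 43L))$age))
  # Bernoulli(0.5) concentration: within 3 binomial standard errors
  expect_lt(abs(mean(coh$sex) - 0.5), 3 * sqrt(0.25 / 10000))
  # age truncation honored, moments near configured values
  expect_true(all(coh$age >= 18 & coh$age <= 95))
  expect_lt(abs(mean(coh$age) - 62), 3 * 14 / sqrt(10000))
  # label rule applied exactly
  thr_i <- ifelse(coh$sex == 1, 1.14, 1.04)
  thr_p <- ifelse(coh$sex == 1, 1.10, 1.02)
  expect_identical(coh$slvh, as.integer(coh$IVSDd > thr_i | coh$LVPWDd > thr_p))
  expect_true(mean(coh$slvh) > 0 && mean(coh$slvh) < 1)
})

test_that("zero coefficients decouple anatomy from demographics", {
  coh <- sample_cohort(independent_cohort_config(n = 10000L, seed = 9L))
  for (col in c("IVSDd", "LVPWDd", "LVIDd")) {
    expect_lt(abs(cor(coh[[col]], coh$age)), 0.05)
    expect_lt(abs(cor(coh[[col]], coh$sex)), 0.05)
  }
})

test_that("channel MI oracles agree with independent evaluations", {
  # closed form at unit SNR
  expect_equal(gaussian_channel_mi(1, 1), 0.5 * log(2))
  expect_equal(gaussian_channel_mi(0, 1), 0)
  expect_equal(binary_channel_mi(0, 1), 0)
  # binary channel approaches log(2) as the components separate
  expect_lt(abs(binary_channel_mi(40, 1) - log(2)), 1e-6)
  # independent oracle for the quadrature: plain Riemann sum of the mixture
  # entropy on a fine fixed grid
  g <- 2; s <- 1
  x <- seq(-14, 14, by = 1e-3)
  p <- 0.5 * dnorm(x, -g, s) + 0.5 * dnorm(x, g, s)
  h_riemann <- -sum(p * log(p)) * 1e-3
  expect_equal(binary_channel_mi(g, s),
               h_riemann - 0.5 * log(2 * pi * exp(1) * s^2),
               tolerance = 1e-6)
  # gain_for_mi inverts both families
  for (mi in c(0.05, 0.35, 1.0)) {
    expect_equal(gaussian_channel_mi(gain_for_mi(mi, "continuous")), mi,
                 tolerance = 1e-8)
  }
  for (mi in c(0.2, 0.6)) {
    expect_equal(binary_channel_mi(gain_for_mi(mi, "binary")), mi,
                 tolerance = 1e-6)
  }
  expect_error(gain_for_mi(0.8, "binary"), "log\\(2\\)")
})

test_that("linear-Gaussian features realize the channel spec", {
  coh <- sample_cohort(independent_cohort_config(n = 8000L, seed = 3L))
  spec <- channel_spec(c(age = 2, sex = 1, LVIDd = 0), noise_sd = 1, d = 6L)
  expect_equal(unname(spec$true_mi["age"]), 0.5 * log(5))
  expect_equal(unname(spec$true_mi["LVIDd"]), 0)
  fg <- make_linear_gaussian_features(coh, spec, seed = 4L)
  fg2 <- make_linear_gaussian_features(coh, spec, seed = 4L)
  expect_identical(fg$features$values, fg2$features$values)
  expect_equal(dim(fg$features$values), c(8000L, 6L))
  v <- fg$features$values
  # injected coordinate correlates as gain/sqrt(gain^2 + sd^2) predicts
  expect_equal(cor(v[, 1], coh$age), 2 / sqrt(5), tolerance = 0.02)
  # zero-gain and spare coordinates stay uninformative
  expect_lt(abs(cor(v[, 3], coh$LVIDd)), 0.05)
  expect_lt(abs(cor(v[, 5], coh$age)), 0.05)
  expect_error(channel_spec(c(age = 1), noise_sd = 0), "positive")
  expect_error(make_linear_gaussian_features(coh, channel_spec(c(bmi = 1))),
               "bmi")
})

test_that("the estimator recovers channel ground truth, binary included", {
  # oracle chain at moderate scale: quadrature truth for the binary channel
  coh <- sample_cohort(independent_cohort_config(n = 5000L, seed = 21L))
  spec <- channel_spec(c(sex = 2), noise_sd = 1, d = 3L)
  fg <- make_linear_gaussian_features(coh, spec, seed = 22L)
  av <- attribute_vector(coh$sex, "binary", "sex")
  res <- expressivity(fg$features, av,
                      train_cfg = mine_train_config(n_seeds = 2L), seed0 = 5)
  truth <- unname(spec$true_mi["sex"])
  expect_lt(abs(res$mean_estimate - truth), max(0.1 * truth, 0.05))
})

test_that("rendered images are deterministic functions of the attributes", {
  coh <- sample_cohort(cohort_config(n = 40L, seed = 15L))
  # duplicate a row: identical attributes must render identically without
  # stochastic corruption
  coh2 <- rbind(as.data.frame(coh), as.data.frame(coh)[7, ])
  coh2$sample_id[41] <- "dup"
  rc0 <- render_config(size = 64L, noise_sd = 0, brightness_sd = 0,
                       contrast_sd = 0)
  im <- render_images(coh2, rc0, seed = 1)
  expect_identical(im[7, ], im[41, ])
  im_b <- render_images(coh2, rc0, seed = 1)
  expect_identical(unclass(im), unclass(im_b))
  # noise changes pixels but not the seeded reproducibility
  rc1 <- render_config(size = 64L)
  expect_identical(unclass(render_images(coh2, rc1, seed = 2)),
                   unclass(render_images(coh2, rc1, seed = 2)))
  expect_false(identical(render_images(coh2, rc1, seed = 2),
                         render_images(coh2, rc1, seed = 3)))
})

test_that("annulus thickness grows monotonically with wall thickness", {
  # sweep IVSDd with everything else fixed; count ring pixels in the
  # noiseless render by thresholding above the silhouette plateau
  base <- as.data.frame(sample_cohort(cohort_config(n = 9L, seed = 31L)))
  base$age <- 60; base$sex <- 1; base$LVPWDd <- 1.0; base$LVIDd <- 5.0
  base$IVSDd <- seq(0.7, 1.3, length.out = 9)
  im <- render_images(base, render_config(size = 64L, noise_sd = 0,
                                          brightness_sd = 0, contrast_sd = 0),
                      seed = 1)
  ring_px <- rowSums(im > 0.55)
  expect_true(all(diff(ring_px) >= 0))
  expect_gt(ring_px[9], ring_px[1])
})

test_that("impossible geometry is rejected with advice", {
  coh <- sample_cohort(cohort_config(n = 30L, seed = 2L))
  expect_error(render_images(coh, render_config(size = 64L,
                                                silhouette_r = 0.6)),
               "frame")
  expect_error(render_images(coh, render_config(size = 64L,
                                                thickness_gain = 0.2)),
               "smaller gains")
})

test_that("balanced subsets equalize classes in every split", {
  # toy 20/80: minority kept whole, majority down-sampled
  labs <- rep(c(1L, 0L), c(20L, 80L))
  sel <- make_balanced_subset(labs, rep("train", 100L), seed = 1)
  expect_length(sel$train, 40L)
  expect_equal(sum(labs[sel$train]), 20L)
  # already balanced input returned unchanged up to ordering
  labs2 <- rep(c(1L, 0L), 15L)
  sel2 <- make_balanced_subset(labs2, rep("all", 30L), seed = 2)
  expect_setequal(sel2$all, seq_len(30L))
  # three splits (20/80, 5/20, 5/15) -> balanced sizes 40, 10, 10
  labs3 <- c(rep(c(1L, 0L), c(20L, 80L)), rep(c(1L, 0L), c(5L, 20L)),
             rep(c(1L, 0L), c(5L, 15L)))
  spl3 <- rep(c("train", "val", "test"), c(100L, 25L, 20L))
  sel3 <- make_balanced_subset(labs3, spl3, seed = 3)
  expect_equal(vapply(sel3[c("train", "val", "test")], length, 1L),
               c(train = 40L, val = 10L, test = 10L))
  for (sp in names(sel3)) {
    expect_equal(sum(labs3[sel3[[sp]]]), length(sel3[[sp]]) / 2)
  }
  # determinism and error on an empty class
  expect_identical(make_balanced_subset(labs3, spl3, seed = 3), sel3)
  expect_error(make_balanced_subset(rep(1L, 10), rep("a", 10), seed = 1),
               "lacks")
})

test_that("balanced subsets honor patient grouping", {
  set.seed(6)
  labs <- rep(c(1L, 0L), c(10L, 50L))
  pat <- c(paste0("p", 1:10), rep(paste0("q", 1:10), each = 5))
  sel <- make_balanced_subset(labs, rep("train", 60L), seed = 4, patient = pat)
  expect_equal(sum(labs[sel$train]), 10L)
  expect_equal(sum(1L - labs[sel$train]), 10L)
})

test_that("cohorts round-trip to CSV with provenance", {
  d <- withr::local_tempdir()
  coh <- sample_cohort(cohort_config(n = 50L, seed = 12L))
  write_cohort(coh, file.path(d, "cohort.csv"))
  back <- read.csv(file.path(d, "cohort.csv"))
  expect_equal(back$IVSDd, coh$IVSDd, tolerance = 1e-12)
  prov <- jsonlite::read_json(file.path(d, "cohort_provenance.json"))
  expect_equal(prov$seed, 12L)
  expect_match(prov$config_hash, "^[a-f0-9]{32}$")
})
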