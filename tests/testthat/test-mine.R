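test_that("dv_lower_bound matches literal evaluation of the bound", {
  # constant equal scores: c - log(e^c) = 0 exactly
  for (c0 in c(-3, 0, 2.5)) {
    expect_identical(dv_lower_bound(rep(c0, 4), rep(c0, 4)), 0)
  }
  expect_equal(dv_lower_bound(c(1, 1), c(0, 0)), 1.0)
  # worked example: direct arithmetic at double precision
  expect_equal(dv_lower_bound(c(2, 0), c(1, -1)),
               mean(c(2, 0)) - log((exp(1) + exp(-1)) / 2))
  # property: literal formula on random small score vectors
  set.seed(11)
  for (i in 1:200) {
    b <- sample(1:9, 1)
    j <- rnorm(b, sd = 3)
    m <- rnorm(b, sd = 3)
    expect_equal(dv_lower_bound(j, m), mean(j) - log(mean(exp(m))))
  }
})

test_that("dv_lower_bound is stable for large scores and rejects bad input", {
  # max-shifted log-mean-exp: naive exp would overflow at 1000
  expect_equal(dv_lower_bound(c(0, 0), c(1000, 1000)), -1000)
  expect_error(dv_lower_bound(numeric(0), numeric(0)), "empty")
  expect_error(dv_lower_bound(c(1, NA), c(0, 0)), "joint")
  expect_error(dv_lower_bound(c(1, 1), c(Inf, 0)), "marginal")
})

test_that("make_marginal_pairs always returns a derangement", {
  # exhaustive over batch sizes 2..8 and several seeds
  for (b in 2:8) {
    for (s in 1:5) {
      p <- make_marginal_pairs(matrix(0, b, 3), rep(0, b), rng_seed = s)
      expect_equal(nrow(p), b)
      expect_equal(sum(p$feature_index == p$attribute_index), 0)
      expect_setequal(p$feature_index, seq_len(b))
      expect_setequal(p$attribute_index, seq_len(b))
    }
  }
  # b = 2 has a unique fixed-point-free permutation
  p2 <- make_marginal_pairs(matrix(0, 2, 1), c(0, 0), rng_seed = 99)
  expect_equal(p2$attribute_index, c(2L, 1L))
  expect_error(make_marginal_pairs(matrix(0, 1, 1), 0), "constraint")
})

test_that("mine_batch_loss reports the negative bound and updates the EMA", {
  # equal constant scores: zero bound regardless of decay
  for (decay in c(0.5, 0.99)) {
    r <- mine_batch_loss(rep(2, 5), rep(2, 5), ema_state = 1, ema_decay = decay)
    expect_equal(r$loss, 0)
  }
  # EMA recursion over two batches: init from batch 1, then blend
  m1 <- mean(exp(c(0.3, -0.2, 0.1)))
  m2 <- mean(exp(c(1.0, 0.5, -0.5)))
  r1 <- mine_batch_loss(rep(0, 3), c(0.3, -0.2, 0.1), ema_state = NULL,
                        ema_decay = 0.99)
  expect_equal(r1$ema_state, m1)
  r2 <- mine_batch_loss(rep(0, 3), c(1.0, 0.5, -0.5), ema_state = r1$ema_state,
                        ema_decay = 0.99)
  expect_equal(r2$ema_state, 0.99 * m1 + 0.01 * m2)
  # reported loss is the raw batch term, independent of the EMA state
  expect_equal(r2$loss, -dv_lower_bound(rep(0, 3), c(1.0, 0.5, -0.5)))
  expect_error(mine_batch_loss(1, 1, ema_state = -2), "positive")
})

test_that("input containers validate their invariants", {
  expect_error(feature_matrix(matrix(1, 1, 3)), "2 samples")
  expect_error(feature_matrix(matrix(c(1, NA), 2, 1)), "finite")
  expect_error(feature_matrix(matrix(1:4, 2, 2), sample_ids = c("a", "a")),
               "unique")
  expect_error(attribute_vector(rep(1, 5)), "variance")
  expect_error(attribute_vector(c(0, 1, 2), kind = "binary"), "0/1")
  fm <- feature_matrix(matrix(rnorm(10), 5, 2), layer_tag = "early")
  expect_s3_class(fm, "feature_matrix")
  expect_equal(fm$layer_tag, "early")
})

test_that("statistics network training is seeded and validates sizes", {
  set.seed(4)
  F <- matrix(rnorm(400), 200, 2)
  A <- rnorm(200)
  cfg <- quick_mine_cfg()
  f1 <- train_statistics_network(F, A, quick_net_cfg(), cfg, seed = 5)
  f2 <- train_statistics_network(F, A, quick_net_cfg(), cfg, seed = 5)
  f3 <- train_statistics_network(F, A, quick_net_cfg(), cfg, seed = 6)
  expect_identical(f1$final_bound, f2$final_bound)
  expect_identical(f1$network$weights$W, f2$network$weights$W)
  expect_false(identical(f1$final_bound, f3$final_bound))
  expect_length(f1$bound_history, f1$epochs_run)
  expect_error(
    train_statistics_network(F[1:40, ], A[1:40], quick_net_cfg(),
                             mine_train_config(batch_size = 100)),
    "batch_size")
})

test_that("expressivity averages seeded fits and never truncates", {
  set.seed(8)
  F <- matrix(rnorm(300), 150, 2)
  A <- rnorm(150)
  cfg1 <- quick_mine_cfg(n_seeds = 1L)
  res1 <- expressivity(F, A, quick_net_cfg(), cfg1, seed0 = 3)
  fit <- train_statistics_network(F, A, quick_net_cfg(), cfg1, seed = 3)
  # M = 1: the average equals that single run exactly
  expect_identical(res1$mean_estimate, fit$final_bound)
  cfg3 <- quick_mine_cfg(n_seeds = 3L)
  res3 <- expressivity(F, A, quick_net_cfg(), cfg3, seed0 = 3)
  expect_length(res3$per_seed_estimates, 3)
  expect_identical(res3$mean_estimate, mean(res3$per_seed_estimates))
  expect_identical(res3$std_estimate, sd(res3$per_seed_estimates))
  expect_equal(res3$units, "nats")
  # under-trained fits on independent data can dip negative; flag must track
  # the raw values, which are reported unclipped
  expect_identical(res3$negative_flag, any(res3$per_seed_estimates < 0))
})

test_that("feature/attribute tables round-trip through delimited files", {
  d <- withr::local_tempdir()
  fm <- feature_matrix(matrix(rnorm(12), 4, 3),
                       sample_ids = c("a", "b", "c", "d"))
  df <- data.frame(sample_id = fm$sample_ids, fm$values)
  names(df) <- c("sample_id", paste0("f_", 0:2))
  write.csv(df, file.path(d, "feats.csv"), row.names = FALSE)
  fm2 <- read_feature_table(file.path(d, "feats.csv"), layer_tag = "mid")
  expect_equal(fm2$values, fm$values, ignore_attr = TRUE)
  expect_equal(fm2$sample_ids, fm$sample_ids)

  at <- data.frame(sample_id = c("d", "a", "b", "c"),
                   age = c(40, 71, 55, 62), sex = c(1, 0, 1, 0))
  write.csv(at, file.path(d, "attrs.csv"), row.names = FALSE)
  av <- read_attribute_table(file.path(d, "attrs.csv"), "age",
                             sample_ids = fm2$sample_ids)
  expect_equal(av$values, c(71, 55, 62, 40))  # joined on sample_id
  expect_equal(av$kind, "continuous")
  sx <- read_attribute_table(file.path(d, "attrs.csv"), "sex")
  expect_equal(sx$kind, "binary")
  expect_error(read_attribute_table(file.path(d, "attrs.csv"), "bmi"),
               "bmi")

  res <- expressivity(matrix(rnorm(300), 150, 2), rnorm(150),
                      quick_net_cfg(), quick_mine_cfg(), seed0 = 1)
  out <- file.path(d, "expr.json")
  write_expressivity_json(res, out)
  rec <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(rec$mean[1], res$mean_estimate)
  expect_equal(rec$units[1], "nats")
})
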