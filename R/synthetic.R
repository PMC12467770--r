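#' Synthetic cohort configuration
#'
#' Defines the generative model for a synthetic echocardiography-linked
#' cohort: age drawn from a truncated normal, sex from Bernoulli(0.5), three
#' left-ventricular dimensions (cm) as linear functions of age and sex plus
#' Gaussian noise, and a binary severe-hypertrophy (SLVH) label set when the
#' septal or posterior wall thickness exceeds a sex-specific threshold. All
#' numeric defaults are synthetic conveniences chosen to give physiologically
#' plausible ranges and a label prevalence usable for balanced training; none
#' of them is estimated from real data.
#'
#' @param n cohort size.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   config including this seed.
#' @param age_mean,age_sd,age_range age model (years), truncated normal.
#' @param sex_prob probability of sex = 1 (male).
#' @param anat named list per dimension (`IVSDd`, `LVPWDd`, `LVIDd`), each
#'   with `intercept`, `beta_age`, `beta_sex`, `sd` (cm).
#' @param thresholds named list with `IVSDd` and `LVPWDd`, each a length-2
#'   vector `c(male, female)` of label thresholds in cm.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 2000L, seed = 1L,
                          age_mean = 62, age_sd = 14, age_range = c(18, 95),
                          sex_prob = 0.5,
                          anat = list(
                            IVSDd  = list(intercept = 0.62, beta_age = 0.005,
                                          beta_sex = 0.10, sd = 0.16),
                            LVPWDd = list(intercept = 0.60, beta_age = 0.005,
                                          beta_sex = 0.08, sd = 0.15),
                            LVIDd  = list(intercept = 5.20, beta_age = -0.006,
                                          beta_sex = 0.25, sd = 0.35)),
                          thresholds = list(IVSDd = c(male = 1.14, female = 1.04),
                                            LVPWDd = c(male = 1.10, female = 1.02))) {
  stopifnot(n >= 2, age_sd > 0, sex_prob > 0, sex_prob < 1)
  for (nm in c("IVSDd", "LVPWDd", "LVIDd")) {
    if (is.null(anat[[nm]])) stop(sprintf("anat is missing '%s'", nm))
    if (anat[[nm]]$sd <= 0) stop(sprintf("anat$%s$sd must be positive", nm))
  }
  if (any(unlist(thresholds) <= 0)) stop("thresholds must be positive")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 sex_prob = sex_prob, anat = anat, thresholds = thresholds),
            class = "cohort_config")
}

#' Draw a synthetic cohort
#'
#' Samples attribute columns and the SLVH label under a [cohort_config()].
#' The label rule is applied exactly: `slvh = 1` iff IVSDd or LVPWDd exceeds
#' its sex-specific threshold.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame of class `synthetic_cohort` with columns `sample_id`,
#'   `age`, `sex`, `IVSDd`, `LVPWDd`, `LVIDd`, `slvh`; the generating config
#'   is attached as attribute `config`.
#' @export
sample_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  df <- with_local_seed(cfg$seed, {
    n <- cfg$n
    # truncated normal via inverse CDF (deterministic in the seed)
    plo <- stats::pnorm(cfg$age_range[1], cfg$age_mean, cfg$age_sd)
    phi <- stats::pnorm(cfg$age_range[2], cfg$age_mean, cfg$age_sd)
    age <- stats::qnorm(stats::runif(n, plo, phi), cfg$age_mean, cfg$age_sd)
    sex <- stats::rbinom(n, 1L, cfg$sex_prob)
    anat_col <- function(p) {
      p$intercept + p$beta_age * age + p$beta_sex * sex +
        stats::rnorm(n, 0, p$sd)
    }
    data.frame(sample_id = sprintf("s%05d", seq_len(n)),
               age = age, sex = sex,
               IVSDd = anat_col(cfg$anat$IVSDd),
               LVPWDd = anat_col(cfg$anat$LVPWDd),
               LVIDd = anat_col(cfg$anat$LVIDd),
               stringsAsFactors = FALSE)
  })
  thr_ivs <- ifelse(df$sex == 1, cfg$thresholds$IVSDd[["male"]],
                    cfg$thresholds$IVSDd[["female"]])
  thr_pw <- ifelse(df$sex == 1, cfg$thresholds$LVPWDd[["male"]],
                   cfg$thresholds$LVPWDd[["female"]])
  df$slvh <- as.integer(df$IVSDd > thr_ivs | df$LVPWDd > thr_pw)
  prev <- mean(df$slvh)
  if (prev <= 0 || prev >= 1) {
    stop(sprintf(paste0("label prevalence is %.3f; adjust thresholds so both ",
                        "classes are realized"), prev))
  }
  attr(df, "config") <- cfg
  class(df) <- c("synthetic_cohort", "data.frame")
  df
}

#' Cohort with mutually independent attributes
#'
#' Variant of [cohort_config()] with all anatomical age/sex coefficients set
#' to zero, so the five attributes are generated mutually independent. This
#' is the configuration under which the linear-Gaussian channel closed forms
#' are the exact per-attribute mutual information (with coupled attributes,
#' other feature coordinates leak correlated information and the channel
#' value is only a lower bound on the true MI).
#'
#' @inheritParams cohort_config
#' @param ... further arguments passed to [cohort_config()].
#' @return object of class `cohort_config`.
#' @export
independent_cohort_config <- function(n = 2000L, seed = 1L, ...) {
  cohort_config(
    n = n, seed = seed,
    anat = list(
      IVSDd  = list(intercept = 1.00, beta_age = 0, beta_sex = 0, sd = 0.16),
      LVPWDd = list(intercept = 0.95, beta_age = 0, beta_sex = 0, sd = 0.15),
      LVIDd  = list(intercept = 5.00, beta_age = 0, beta_sex = 0, sd = 0.35)),
    thresholds = list(IVSDd = c(male = 1.10, female = 1.10),
                      LVPWDd = c(male = 1.05, female = 1.05)),
    ...)
}

#' Mutual information of a scalar Gaussian channel
#'
#' Closed form for `f = gain * z + noise` with `z ~ N(0,1)` and
#' `noise ~ N(0, sd^2)`: `0.5 * log(1 + gain^2 / sd^2)` nats.
#'
#' @param gain injection amplitude.
#' @param sd noise standard deviation (> 0).
#' @return mutual information in nats.
#' @export
gaussian_channel_mi <- function(gain, sd = 1) {
  if (sd <= 0) stop("noise sd must be positive")
  0.5 * log1p((gain / sd)^2)
}

#' Mutual information of a symmetric binary Gaussian channel
#'
#' For a balanced binary input injected as `f = gain * s + noise` with
#' `s = +/-1` (the z-scored 0/1 attribute) and Gaussian noise, there is no
#' closed form; the differential entropy of the two-component mixture
#' `0.5 N(-gain, sd^2) + 0.5 N(gain, sd^2)` is computed by adaptive
#' quadrature and `MI = H(f) - 0.5 * log(2 * pi * e * sd^2)`. The upper bound
#' is `log(2)` nats.
#'
#' @inheritParams gaussian_channel_mi
#' @param rel.tol quadrature relative tolerance.
#' @return mutual information in nats.
#' @export
binary_channel_mi <- function(gain, sd = 1, rel.tol = 1e-10) {
  if (sd <= 0) stop("noise sd must be positive")
  dens <- function(x) {
    0.5 * stats::dnorm(x, -gain, sd) + 0.5 * stats::dnorm(x, gain, sd)
  }
  integrand <- function(x) {
    p <- dens(x)
    out <- numeric(length(x))
    pos <- p > 0
    out[pos] <- -p[pos] * log(p[pos])
    out
  }
  lim <- abs(gain) + 12 * sd
  h_mix <- stats::integrate(integrand, -lim, lim, rel.tol = rel.tol,
                            subdivisions = 500L)$value
  h_cond <- 0.5 * log(2 * pi * exp(1) * sd^2)
  max(h_mix - h_cond, 0)
}

#' Injection gain achieving a target mutual information
#'
#' Inverts [gaussian_channel_mi()] (closed form) or [binary_channel_mi()]
#' (root finding) for the linear-Gaussian feature channel.
#'
#' @param mi target mutual information in nats.
#' @param kind `"continuous"` or `"binary"`; binary targets must be below
#'   `log(2)`.
#' @param sd channel noise standard deviation.
#' @return the gain.
#' @export
gain_for_mi <- function(mi, kind = c("continuous", "binary"), sd = 1) {
  kind <- match.arg(kind)
  stopifnot(mi >= 0)
  if (mi == 0) return(0)
  if (kind == "continuous") {
    return(sd * sqrt(expm1(2 * mi)))
  }
  if (mi >= log(2)) {
    stop(sprintf("binary attribute MI is bounded by log(2) = %.4f nats", log(2)))
  }
  stats::uniroot(function(g) binary_channel_mi(g, sd) - mi,
                 lower = 1e-6, upper = 50 * sd, tol = 1e-10)$root
}

#' Feature-channel specification
#'
#' Describes how cohort attributes are injected into a synthetic feature
#' matrix: each named attribute occupies its own coordinate as
#' `f_k = gain_k * z(attr_k) + noise`, remaining coordinates are pure noise.
#' The implied true mutual information per attribute (closed form for
#' continuous, quadrature for binary) is computed at construction.
#'
#' @param gains named numeric vector of injection gains; names must be cohort
#'   columns.
#' @param noise_sd channel noise standard deviation (> 0).
#' @param d total feature dimension (>= number of injected attributes).
#' @param binary_attributes names treated as binary (default `"sex"`,
#'   `"slvh"`).
#' @return object of class `channel_spec` with a `true_mi` field in nats.
#' @export
channel_spec <- function(gains, noise_sd = 1, d = 16L,
                         binary_attributes = c("sex", "slvh")) {
  if (noise_sd <= 0) stop("noise sd must be positive")
  if (is.null(names(gains)) || any(names(gains) == "")) {
    stop("gains must be a named vector")
  }
  d <- as.integer(d)
  if (d < length(gains)) stop("d must be at least the number of injected attributes")
  true_mi <- vapply(names(gains), function(nm) {
    if (nm %in% binary_attributes) {
      binary_channel_mi(gains[[nm]], noise_sd)
    } else {
      gaussian_channel_mi(gains[[nm]], noise_sd)
    }
  }, numeric(1))
  structure(list(gains = gains, noise_sd = noise_sd, d = d,
                 binary_attributes = binary_attributes, true_mi = true_mi),
            class = "channel_spec")
}

#' Linear-Gaussian features with known ground-truth MI
#'
#' Generates a feature matrix from a cohort under a [channel_spec()]: every
#' injected attribute is z-scored and written into its own coordinate with
#' additive Gaussian noise; spare coordinates are pure noise. Serves as the
#' validation harness for the neural MI estimator, since the true mutual
#' information of every coordinate is known.
#'
#' @param cohort a [sample_cohort()] result (or any data.frame holding the
#'   named attribute columns).
#' @param spec a [channel_spec()].
#' @param seed integer seed for the noise draws.
#' @return list with `features` (a [feature_matrix()]) and `true_mi` (named,
#'   nats).
#' @export
make_linear_gaussian_features <- function(cohort, spec, seed = 0L) {
  stopifnot(inherits(spec, "channel_spec"))
  nms <- names(spec$gains)
  missing_cols <- setdiff(nms, colnames(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort lacks attribute column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(cohort)
  vals <- with_local_seed(seed, {
    m <- matrix(stats::rnorm(n * spec$d, 0, spec$noise_sd), n, spec$d)
    for (k in seq_along(nms)) {
      z <- as.numeric(scale(cohort[[nms[k]]]))
      m[, k] <- m[, k] + spec$gains[[k]] * z
    }
    m
  })
  colnames(vals) <- c(nms, paste0("noise_", seq_len(spec$d - length(nms))))[seq_len(spec$d)]
  ids <- if ("sample_id" %in% colnames(cohort)) cohort$sample_id else seq_len(n)
  list(features = feature_matrix(vals, sample_ids = ids,
                                 layer_tag = "linear_gaussian_channel"),
       true_mi = spec$true_mi)
}

#' Image rendering configuration
#'
#' Controls the toy radiograph-like renderer: a noisy field containing a
#' centered cardiac silhouette and an annular wall. Geometry gains are in
#' fractions of the image size per standard deviation of the attribute.
#'
#' @param size image side in pixels (>= 32).
#' @param noise_sd additive Gaussian pixel noise.
#' @param silhouette_r,silhouette_gain silhouette radius: base fraction and
#'   per-z(age) gain.
#' @param inner_r,inner_gain annulus inner radius: base and per-z(LVIDd) gain.
#' @param thickness,thickness_gain annulus thickness: base and gain per unit
#'   of `z(IVSDd) + z(LVPWDd)`.
#' @param sex_asym amplitude of the lateral intensity asymmetry encoding sex.
#' @param edge softness (pixels) of the anti-aliased structure edges.
#' @param brightness_sd,contrast_sd standard deviations of the per-image
#'   additive offset and multiplicative gain jitter, emulating the exposure
#'   variation of real radiographs. These nuisances carry no attribute
#'   information; a classifier must learn to discount them.
#' @return object of class `render_config`.
#' @export
render_config <- function(size = 64L, noise_sd = 0.05,
                          silhouette_r = 0.32, silhouette_gain = 0.022,
                          inner_r = 0.10, inner_gain = 0.012,
                          thickness = 0.072, thickness_gain = 0.008,
                          sex_asym = 0.12, edge = 0.7,
                          brightness_sd = 0.10, contrast_sd = 0.12) {
  size <- as.integer(size)
  if (size < 32L) stop("image size must be at least 32")
  stopifnot(noise_sd >= 0, thickness > 0, inner_r > 0, silhouette_r > 0,
            brightness_sd >= 0, contrast_sd >= 0)
  structure(list(size = size, noise_sd = noise_sd,
                 silhouette_r = silhouette_r, silhouette_gain = silhouette_gain,
                 inner_r = inner_r, inner_gain = inner_gain,
                 thickness = thickness, thickness_gain = thickness_gain,
                 sex_asym = sex_asym, edge = edge,
                 brightness_sd = brightness_sd, contrast_sd = contrast_sd),
            class = "render_config")
}

soft_band <- function(r, lo, hi, edge) {
  stats::plogis((r - lo) / edge) * stats::plogis((hi - r) / edge)
}

#' Render toy radiograph-like images from a cohort
#'
#' Each image is a noisy field with a centered annular "cardiac" structure:
#' the annulus thickness grows with the summed z-scores of IVSDd and LVPWDd,
#' its inner radius with z(LVIDd), the outer silhouette radius with z(age),
#' and a lateral intensity ramp encodes sex. Structure edges are soft
#' (logistic in radius), so sub-pixel geometry changes remain visible.
#' Deterministic given the seed; with `noise_sd = 0` two samples with
#' identical attributes render identically.
#'
#' @param cohort a [sample_cohort()] result.
#' @param render_cfg a [render_config()].
#' @param seed integer seed for the pixel noise.
#' @return object of class `image_set`: an `n x size^2` matrix of grayscale
#'   pixels in `[0, 1]` (rows are images, column-major pixel order), with
#'   attributes `size` and `sample_ids`.
#' @export
render_images <- function(cohort, render_cfg = render_config(), seed = 0L) {
  rc <- render_cfg
  S <- rc$size
  # constant attributes render at their baseline geometry
  z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  z_age <- z(cohort$age)
  z_in <- z(cohort$LVIDd)
  z_th <- z(cohort$IVSDd) + z(cohort$LVPWDd)
  sex_sign <- ifelse(cohort$sex == 1, 1, -1)

  r_sil <- S * (rc$silhouette_r + rc$silhouette_gain * z_age)
  r_in <- S * (rc$inner_r + rc$inner_gain * z_in)
  thick <- S * (rc$thickness + rc$thickness_gain * z_th)
  r_out <- r_in + thick
  margin <- 2
  if (any(r_out >= S / 2 - margin) || any(r_sil >= S / 2 - margin)) {
    stop("rendered geometry exceeds the frame; use smaller gains or a larger image")
  }
  if (any(thick <= 0) || any(r_in <= 0)) {
    stop("rendered geometry collapsed (non-positive radius/thickness); use smaller gains")
  }

  cx <- (S + 1) / 2
  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), times = S), S, S)  # row index
  r_px <- sqrt((xs - cx)^2 + (ys - cx)^2)
  ramp <- (xs - cx) / S

  n <- nrow(cohort)
  imgs <- matrix(0, n, S * S)
  jitter <- with_local_seed(seed, {
    list(noise = if (rc$noise_sd > 0)
           matrix(stats::rnorm(n * S * S, 0, rc$noise_sd), n, S * S)
         else matrix(0, n, S * S),
         gain = 1 + stats::rnorm(n, 0, rc$contrast_sd),
         offset = stats::rnorm(n, 0, rc$brightness_sd))
  })
  for (i in seq_len(n)) {
    sil <- stats::plogis((r_sil[i] - r_px) / rc$edge)
    ring <- soft_band(r_px, r_in[i], r_out[i], rc$edge)
    img <- 0.08 + 0.25 * sil + 0.55 * ring +
      rc$sex_asym * sex_sign[i] * ramp * sil
    imgs[i, ] <- jitter$gain[i] * as.numeric(img) + jitter$offset[i]
  }
  imgs <- imgs + jitter$noise
  imgs[imgs < 0] <- 0
  imgs[imgs > 1] <- 1
  structure(imgs, size = S,
            sample_ids = if ("sample_id" %in% colnames(cohort))
              cohort$sample_id else seq_len(n),
            class = "image_set")
}

#' Class-balanced subset construction
#'
#' Within every split, keeps the minority class whole and down-samples the
#' majority class without replacement to the same count, with a fixed seed,
#' so each split ends up exactly class-balanced while relative split sizes
#' are preserved. When a patient grouping is supplied, majority-class images
#' are drawn patient by patient (in seeded random order), topping up with
#' part of the last patient's images to reach exact equality.
#'
#' @param labels binary 0/1 vector.
#' @param splits character/factor vector of split names (same length).
#' @param seed integer seed.
#' @param patient optional grouping vector (same length).
#' @return named list of integer index vectors (into the input) per split,
#'   each exactly class-balanced; attribute `counts` tabulates the result.
#' @export
make_balanced_subset <- function(labels, splits, seed = 0L, patient = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(splits) != length(labels)) stop("labels and splits lengths differ")
  split_names <- unique(as.character(splits))
  out <- with_local_seed(seed, {
    res <- list()
    for (sp in split_names) {
      idx <- which(as.character(splits) == sp)
      pos <- idx[labels[idx] == 1L]
      neg <- idx[labels[idx] == 0L]
      if (length(pos) == 0L || length(neg) == 0L) {
        stop(sprintf("split '%s' lacks one of the classes", sp))
      }
      n_keep <- min(length(pos), length(neg))
      minority <- if (length(pos) <= length(neg)) pos else neg
      majority <- if (length(pos) <= length(neg)) neg else pos
      if (is.null(patient)) {
        kept_maj <- sample(majority, n_keep)
      } else {
        pats <- sample(unique(patient[majority]))
        kept_maj <- integer(0)
        for (pt in pats) {
          imgs <- majority[patient[majority] == pt]
          need <- n_keep - length(kept_maj)
          if (need <= 0L) break
          if (length(imgs) > need) imgs <- sample(imgs, need)
          kept_maj <- c(kept_maj, imgs)
        }
      }
      res[[sp]] <- sort(c(minority, kept_maj))
    }
    res
  })
  counts <- t(vapply(out, function(ix) {
    c(n = length(ix), positives = sum(labels[ix]),
      negatives = sum(1L - labels[ix]))
  }, numeric(3)))
  attr(out, "counts") <- counts
  out
}

#' Write a cohort and its provenance to disk
#'
#' @param cohort a [sample_cohort()] result.
#' @param path CSV output path; a provenance JSON (config hash + seed) is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  prov <- list(config_hash = hash_obj(cfg), seed = cfg$seed, n = cfg$n)
  jsonlite::write_json(prov, sub("\\.csv$", "_provenance.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
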