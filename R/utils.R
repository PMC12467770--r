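# Internal helpers shared across modules.

# Evaluate `expr` under a temporary R RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps package randomness from perturbing
# user sessions while staying fully reproducible.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Fold a base seed and any number of string/numeric labels into one 31-bit
# integer, so every stage and repeat gets its own reproducible stream.
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(parts)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

# md5 fingerprint of an arbitrary R object (serialized canonically)
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# z-score columns; zero-variance columns are centered but left unscaled
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sds, "/")
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
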