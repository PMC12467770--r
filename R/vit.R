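# Small vision-transformer encoder, forward pass only. The encoder is used
# frozen (head-only training), so no encoder backprop is needed; features are
# deterministic functions of (weights, images).

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

vit_init <- function(cfg, seed = 0L) {
  S <- cfg$input_size
  P <- cfg$patch_size
  D <- cfg$embed_dim
  n_tok <- (S / P)^2
  pdim <- 3L * P^2
  H <- as.integer(round(cfg$mlp_ratio * D))
  tn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  with_local_seed(seed, {
    blocks <- lapply(seq_len(cfg$depth), function(b) {
      list(ln1_g = rep(1, D), ln1_b = rep(0, D),
           Wq = tn(D, D), bq = rep(0, D),
           Wk = tn(D, D), bk = rep(0, D),
           Wv = tn(D, D), bv = rep(0, D),
           Wo = tn(D, D), bo = rep(0, D),
           ln2_g = rep(1, D), ln2_b = rep(0, D),
           W1 = tn(D, H), b1 = rep(0, H),
           W2 = tn(H, D), b2 = rep(0, D))
    })
    list(patch_W = tn(pdim, D), patch_b = rep(0, D),
         cls = tn(1, D), pos = tn(n_tok + 1L, D),
         blocks = blocks, lnf_g = rep(1, D), lnf_b = rep(0, D))
  })
}

layer_norm <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  sweep(sweep((x - mu) / sqrt(v + eps), 2, g, "*"), 2, b, "+")
}

row_softmax <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)

# index matrix mapping column-major S x S pixels to (n_tok x P^2) patch rows
patch_index <- function(S, P) {
  nside <- S %/% P
  idx <- matrix(0L, nside^2, P^2)
  t <- 0L
  for (pr in seq_len(nside)) {
    for (pc in seq_len(nside)) {
      t <- t + 1L
      rows <- (pr - 1L) * P + seq_len(P)
      cols <- (pc - 1L) * P + seq_len(P)
      idx[t, ] <- as.integer(outer(rows, (cols - 1L) * S, "+"))
    }
  }
  idx
}

# Encode images; returns list(final = n x D CLS after final LN,
# blocks = named list of n x D CLS after each requested block)
vit_encode <- function(encoder, imgs, cfg, blocks = NULL, pooling = "cls") {
  S <- cfg$input_size
  P <- cfg$patch_size
  D <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- D / nh
  n <- nrow(imgs)
  pidx <- patch_index(S, P)
  want <- sort(unique(c(blocks)))
  out_blocks <- lapply(want, function(b) matrix(0, n, D))
  names(out_blocks) <- as.character(want)
  final <- matrix(0, n, D)
  for (i in seq_len(n)) {
    g <- imgs[i, ]
    pm <- matrix(g[pidx], nrow(pidx), ncol(pidx))
    # replicate to 3 normalized channels, matching the conv preprocessing
    X <- cbind((pm - IMAGENET_MEAN[1]) / IMAGENET_SD[1],
               (pm - IMAGENET_MEAN[2]) / IMAGENET_SD[2],
               (pm - IMAGENET_MEAN[3]) / IMAGENET_SD[3])
    tok <- X %*% encoder$patch_W
    tok <- sweep(tok, 2, encoder$patch_b, "+")
    tok <- rbind(encoder$cls, tok) + encoder$pos
    for (b in seq_along(encoder$blocks)) {
      bl <- encoder$blocks[[b]]
      a <- layer_norm(tok, bl$ln1_g, bl$ln1_b)
      Q <- sweep(a %*% bl$Wq, 2, bl$bq, "+")
      K <- sweep(a %*% bl$Wk, 2, bl$bk, "+")
      V <- sweep(a %*% bl$Wv, 2, bl$bv, "+")
      att_out <- matrix(0, nrow(tok), D)
      for (h in seq_len(nh)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        A <- row_softmax(Q[, cols, drop = FALSE] %*%
                           t(K[, cols, drop = FALSE]) / sqrt(dh))
        att_out[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      tok <- tok + sweep(att_out %*% bl$Wo, 2, bl$bo, "+")
      a2 <- layer_norm(tok, bl$ln2_g, bl$ln2_b)
      hmid <- gelu(sweep(a2 %*% bl$W1, 2, bl$b1, "+"))
      tok <- tok + sweep(hmid %*% bl$W2, 2, bl$b2, "+")
      if (as.character(b) %in% names(out_blocks)) {
        out_blocks[[as.character(b)]][i, ] <-
          if (pooling == "cls") tok[1, ] else colMeans(tok[-1, , drop = FALSE])
      }
    }
    fin <- layer_norm(tok, encoder$lnf_g, encoder$lnf_b)
    final[i, ] <- if (pooling == "cls") fin[1, ] else colMeans(fin[-1, , drop = FALSE])
  }
  list(final = final, blocks = out_blocks)
}
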