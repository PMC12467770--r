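#' Backbone configuration
#'
#' Describes a classifier backbone: a convolutional stack (a stem plus
#' `n_stages` stride-2 stages, global average pooling, and a fully connected
#' head with ReLU and dropout) or a transformer encoder operating on image
#' patches with a classification head on the \[CLS\] token. The full-size
#' defaults (256-pixel inputs, head 128-64-1 with dropout 0.3 for the conv
#' family; head 512-128-1 on the \[CLS\] token with a frozen encoder for the
#' transformer family) mirror the reference training protocol; tests and the
#' desk-scale pipeline use 64-pixel inputs and narrower stacks.
#'
#' @param family `"conv"` or `"transformer"`.
#' @param input_size input image side in pixels.
#' @param base_width stem width of the conv stack; stage widths double per
#'   stage.
#' @param n_stages number of stride-2 stages after the stem (conv family).
#' @param conv_head hidden widths of the conv classification head.
#' @param dropout dropout probability in the conv head, in `[0, 1)`.
#' @param embed_dim,depth,n_heads,mlp_ratio,patch_size transformer encoder
#'   geometry.
#' @param vit_head hidden widths of the transformer classification head.
#' @param freeze_encoder keep transformer encoder parameters fixed and train
#'   only the head (the supported mode for this family).
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(family = c("conv", "transformer"),
                            input_size = 256L,
                            base_width = 8L, n_stages = 3L,
                            conv_head = c(128L, 64L), dropout = 0.3,
                            embed_dim = 48L, depth = 4L, n_heads = 4L,
                            mlp_ratio = 2, patch_size = 8L,
                            vit_head = c(512L, 128L),
                            freeze_encoder = TRUE) {
  family <- match.arg(family)
  input_size <- as.integer(input_size)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (family == "transformer") {
    if (input_size %% patch_size != 0) {
      stop("input_size must be divisible by patch_size")
    }
    if (embed_dim %% n_heads != 0) {
      stop("embed_dim must be divisible by n_heads")
    }
    if (!isTRUE(freeze_encoder)) {
      stop(paste0("the transformer family trains a head on a frozen encoder; ",
                  "freeze_encoder = FALSE is not supported"))
    }
  }
  widths <- as.integer(base_width * 2^(0:n_stages))
  structure(list(family = family, input_size = input_size,
                 widths = widths, conv_head = as.integer(conv_head),
                 dropout = dropout,
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
                 patch_size = as.integer(patch_size),
                 vit_head = as.integer(vit_head),
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "backbone_config")
}

#' Training-run configuration for classifiers
#'
#' Binary cross-entropy throughout. Family defaults follow the reference
#' protocol: Adam with weight decay and a constant learning rate for
#' end-to-end conv training, and linear warmup followed by cosine decay for
#' head-only training on a frozen encoder; the best checkpoint is selected by
#' validation AUROC.
#'
#' @param learning_rate Adam step size; `NULL` uses the family default
#'   (1e-4 conv, 1e-3 head-only).
#' @param weight_decay L2 penalty (default 1e-5).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param schedule `"constant"` or `"warmup_cosine"`; `NULL` uses the family
#'   default.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return object of class `train_run_config`.
#' @export
train_run_config <- function(learning_rate = NULL, weight_decay = 1e-5,
                             epochs = 10L, batch_size = 32L,
                             schedule = NULL, seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, weight_decay >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 schedule = schedule, seed = as.integer(seed)),
            class = "train_run_config")
}

image_values <- function(images, input_size) {
  m <- unclass(images)
  if (!is.matrix(m)) stop("images must be an image_set or pixel matrix")
  if (ncol(m) != input_size^2) {
    stop(sprintf("images have %d pixels per row; backbone expects %d (%dx%d)",
                 ncol(m), input_size^2, input_size, input_size))
  }
  m
}

#' Build a classifier backbone
#'
#' Deterministically initializes a backbone given a seed. Externally trained
#' weights (e.g. an encoder pretrained elsewhere) can be supplied through
#' `pretrained_weights`; tests never require them.
#'
#' @param cfg a [backbone_config()].
#' @param seed integer seed.
#' @param pretrained_weights optional weights list matching the family's
#'   structure, loaded in place of the random initialization.
#' @return object of class `backbone_model`.
#' @export
build_backbone <- function(cfg, seed = 0L, pretrained_weights = NULL) {
  stopifnot(inherits(cfg, "backbone_config"))
  if (cfg$family == "conv") {
    weights <- pretrained_weights %||%
      convnet_init_cpp(cfg$widths, cfg$conv_head, as.double(seed))
  } else {
    weights <- list(encoder = (pretrained_weights$encoder %||%
                                 vit_init(cfg, seed)),
                    head = pretrained_weights$head %||% NULL)
  }
  structure(list(family = cfg$family, cfg = cfg, weights = weights,
                 seed = seed, trained = FALSE, history = NULL),
            class = "backbone_model")
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("<backbone_model> family=%s input=%dpx %s\n", x$family,
              x$cfg$input_size, if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

#' Train a classifier backbone
#'
#' Binary cross-entropy training with Adam; the returned model carries the
#' checkpoint with the best validation AUROC and the per-epoch history of
#' training loss and validation AUROC. The conv family trains end to end;
#' the transformer family keeps the encoder frozen and trains only the MLP
#' head on the \[CLS\] representation.
#'
#' @param model a [build_backbone()] result.
#' @param images,labels training images (`image_set` or pixel matrix) and
#'   binary 0/1 labels.
#' @param val_images,val_labels non-empty validation set.
#' @param run_cfg a [train_run_config()].
#' @return the trained `backbone_model` with a `history` element
#'   (`loss`, `val_auroc`, `best_epoch`, `best_val_auroc`).
#' @export
train_classifier <- function(model, images, labels, val_images, val_labels,
                             run_cfg = train_run_config()) {
  stopifnot(inherits(model, "backbone_model"))
  labels <- as.integer(labels)
  val_labels <- as.integer(val_labels)
  if (length(val_labels) == 0L) stop("validation set must be non-empty")
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single class; binary cross-entropy evaluation is degenerate")
  }
  S <- model$cfg$input_size
  x <- image_values(images, S)
  xv <- image_values(val_images, S)
  if (model$family == "conv") {
    lr <- run_cfg$learning_rate %||% 1e-4
    fit <- convnet_train_cpp(x, as.numeric(labels), xv, as.numeric(val_labels),
                             S, model$cfg$widths, model$cfg$conv_head,
                             model$cfg$dropout, lr, run_cfg$weight_decay,
                             run_cfg$batch_size, run_cfg$epochs,
                             as.double(run_cfg$seed), model$weights)
    model$weights <- fit$weights
  } else {
    lr <- run_cfg$learning_rate %||% 1e-3
    schedule <- run_cfg$schedule %||% "warmup_cosine"
    feats <- vit_encode(model$weights$encoder, x, model$cfg)
    featsv <- vit_encode(model$weights$encoder, xv, model$cfg)
    fit <- dense_bce_train_cpp(feats$final, as.numeric(labels),
                               featsv$final, as.numeric(val_labels),
                               model$cfg$vit_head, "relu", 0.0,
                               lr, run_cfg$weight_decay, run_cfg$batch_size,
                               run_cfg$epochs, schedule,
                               as.double(run_cfg$seed))
    model$weights$head <- fit$weights
  }
  model$trained <- TRUE
  model$history <- list(loss = fit$loss, val_auroc = fit$val_auroc,
                        best_epoch = fit$best_epoch,
                        best_val_auroc = fit$best_val_auroc)
  model
}

#' Layer taps available on a backbone
#'
#' @param model a `backbone_model`.
#' @return character vector of tags accepted by [extract_features()].
#' @export
available_taps <- function(model) {
  if (model$family == "conv") {
    c("early", "mid", "final", "pool",
      paste0("conv", seq_along(model$cfg$widths)))
  } else {
    c("early", "mid", "final", paste0("block", seq_len(model$cfg$depth)))
  }
}

resolve_tap <- function(model, tag) {
  if (model$family == "conv") {
    L <- length(model$cfg$widths)
    switch(tag,
           early = list(kind = "pooled", idx = min(2L, L)),
           mid = list(kind = "pooled", idx = max(min(2L, L), L - 1L)),
           final = list(kind = "prelogit"),
           pool = list(kind = "pooled", idx = L),
           {
             m <- regmatches(tag, regexec("^conv([0-9]+)$", tag))[[1]]
             if (length(m) == 2 && as.integer(m[2]) >= 1 &&
                 as.integer(m[2]) <= L) {
               list(kind = "pooled", idx = as.integer(m[2]))
             } else {
               stop(sprintf("unknown tap '%s'; available: %s", tag,
                            paste(available_taps(model), collapse = ", ")))
             }
           })
  } else {
    L <- model$cfg$depth
    switch(tag,
           early = list(kind = "block", idx = max(1L, ceiling(L / 6))),
           mid = list(kind = "block", idx = ceiling(L / 2)),
           final = list(kind = "final"),
           {
             m <- regmatches(tag, regexec("^block([0-9]+)$", tag))[[1]]
             if (length(m) == 2 && as.integer(m[2]) >= 1 &&
                 as.integer(m[2]) <= L) {
               list(kind = "block", idx = as.integer(m[2]))
             } else {
               stop(sprintf("unknown tap '%s'; available: %s", tag,
                            paste(available_taps(model), collapse = ", ")))
             }
           })
  }
}

#' Harvest layer-wise features
#'
#' Evaluation-mode forward pass (dropout off), one feature row per image in
#' input order, bit-identical across repeated calls. Convolutional taps are
#' reduced by global average pooling over spatial positions; the conv
#' `"final"` tap is the penultimate (pre-logit) activation of the head, and
#' `"pool"` is the post-pooling encoder vector feeding the head. Transformer
#' taps return the \[CLS\] vector after the chosen block (`"final"` after the
#' closing layer norm). Zero-variance feature columns (e.g. from constant
#' inputs) are flagged in the `zero_variance` attribute for downstream
#' exclusion.
#'
#' @param model a `backbone_model` (trained or freshly built).
#' @param images an `image_set` or pixel matrix.
#' @param tag a tap tag, see [available_taps()].
#' @return a [feature_matrix()] with `layer_tag = tag` and attribute
#'   `zero_variance` (column indices).
#' @export
extract_features <- function(model, images, tag = "final") {
  stopifnot(inherits(model, "backbone_model"))
  S <- model$cfg$input_size
  x <- image_values(images, S)
  tap <- resolve_tap(model, tag)
  if (model$family == "conv") {
    fwd <- convnet_forward_cpp(x, S, model$weights)
    vals <- if (tap$kind == "prelogit") fwd$prelogit else fwd$pooled[[tap$idx]]
  } else {
    enc <- vit_encode(model$weights$encoder, x, model$cfg,
                      blocks = if (tap$kind == "block") tap$idx else NULL)
    vals <- if (tap$kind == "final") enc$final else enc$blocks[[as.character(tap$idx)]]
  }
  ids <- attr(images, "sample_ids") %||% seq_len(nrow(vals))
  fm <- feature_matrix(vals, sample_ids = ids, layer_tag = tag)
  zv <- which(apply(vals, 2, stats::var) == 0)
  attr(fm, "zero_variance") <- zv
  fm
}

#' Predicted class probabilities
#'
#' Sigmoid of the classifier logit for each image.
#'
#' @param model a `backbone_model`.
#' @param images an `image_set` or pixel matrix.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "backbone_model"))
  S <- model$cfg$input_size
  x <- image_values(images, S)
  if (model$family == "conv") {
    logits <- convnet_forward_cpp(x, S, model$weights)$logits
  } else {
    if (is.null(model$weights$head)) stop("transformer head is untrained")
    feats <- vit_encode(model$weights$encoder, x, model$cfg)
    logits <- mlp_score_cpp(feats$final, model$weights$head, "relu")
  }
  stats::plogis(as.numeric(logits))
}
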