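#' Transformer decoder configuration
#'
#' Hyperparameters of the motor-imagery transformer classifier. The defaults
#' reproduce the reference architecture exactly: a `(44, 16)` spectral input
#' (44 frequency bins as sequence positions, 16 channels as the embedding),
#' sinusoidal positional encoding, two encoder blocks with 4-head attention
#' of head size 64 and a 128-unit feed-forward sub-layer, global average
#' pooling over the bin axis, and a 128-64-2 dense head with batch and layer
#' normalization. In the literal reference graph the second encoder block
#' carries no feed-forward sub-layer; set `symmetric_blocks = TRUE` to
#' restore a conventional symmetric second block.
#'
#' @param seq_len sequence length (frequency bins).
#' @param embed_dim embedding width (channels).
#' @param n_heads,head_size multi-head attention shape.
#' @param ffn_units width of the feed-forward expansion.
#' @param n_encoder_blocks number of encoder blocks.
#' @param dropout_attention dropout rate inside the encoder blocks.
#' @param dropout_ffn dropout rate in the dense head.
#' @param head_units widths of the dense head layers.
#' @param n_classes number of output classes.
#' @param symmetric_blocks give the final block a feed-forward sub-layer too.
#' @return An object of class `model_config`.
#' @export
model_config <- function(seq_len = 44L, embed_dim = 16L, n_heads = 4L,
                         head_size = 64L, ffn_units = 128L,
                         n_encoder_blocks = 2L, dropout_attention = 0.1,
                         dropout_ffn = 0.3, head_units = c(128L, 64L),
                         n_classes = 2L, symmetric_blocks = FALSE) {
  cfg <- list(seq_len = as.integer(seq_len), embed_dim = as.integer(embed_dim),
              n_heads = as.integer(n_heads), head_size = as.integer(head_size),
              ffn_units = as.integer(ffn_units),
              n_encoder_blocks = as.integer(n_encoder_blocks),
              dropout_attention = dropout_attention,
              dropout_ffn = dropout_ffn,
              head_units = as.integer(head_units),
              n_classes = as.integer(n_classes),
              symmetric_blocks = isTRUE(symmetric_blocks))
  with(cfg, {
    if (any(c(seq_len, embed_dim, n_heads, head_size, ffn_units,
              n_encoder_blocks, head_units, n_classes) < 1L))
      stop("all architecture sizes must be positive integers", call. = FALSE)
    if (dropout_attention < 0 || dropout_attention >= 1 ||
        dropout_ffn < 0 || dropout_ffn >= 1)
      stop("dropout rates must lie in [0, 1)", call. = FALSE)
  })
  structure(cfg, class = "model_config")
}

#' Sinusoidal positional encoding
#'
#' The standard non-learned encoding added to the input embeddings so the
#' attention layers can use position: entry `(pos, 2i)` is
#' `sin(pos / 10000^(2i/dim))` and entry `(pos, 2i+1)` the matching cosine
#' (zero-based indices). Row 0 is therefore the alternating `0, 1, 0, 1, ...`
#' pattern, and every entry lies in `[-1, 1]`.
#'
#' @param seq_len number of positions.
#' @param dim embedding dimension (must be even).
#' @return `seq_len x dim` numeric matrix.
#' @export
positional_encoding <- function(seq_len, dim) {
  seq_len <- as.integer(seq_len); dim <- as.integer(dim)
  if (seq_len < 1L || dim < 1L) stop("dimensions must be positive", call. = FALSE)
  if (dim %% 2L != 0L) stop("`dim` must be even", call. = FALSE)
  pos <- seq_len(seq_len) - 1
  i <- seq_len(dim / 2L) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / dim))
  pe <- matrix(0, seq_len, dim)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Focal-loss parameters
#'
#' @param gamma focusing exponent (>= 0); 0 recovers cross-entropy.
#' @param alpha per-class weight vector in class-index order (rest, fist).
#'   `NULL` means balance by inverse class frequency (normalized to mean 1)
#'   at training time.
#' @return An object of class `focal_loss_params`.
#' @export
focal_loss_params <- function(gamma = 2, alpha = NULL) {
  stopifnot_scalar(gamma, "gamma")
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (!is.null(alpha)) {
    if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
      stop("`alpha` must be a positive numeric vector", call. = FALSE)
  }
  structure(list(gamma = gamma, alpha = alpha), class = "focal_loss_params")
}

#' Focal loss of predicted class probabilities
#'
#' `FL = -alpha_c (1 - p_c)^gamma log(p_c)` for the true class `c`; with
#' `gamma = 0` and unit weights this is the cross-entropy. Down-weighting
#' well-classified examples concentrates the training signal on the hard
#' (typically minority-class) epochs.
#'
#' @param probabilities probability vector (one example) or matrix with one
#'   row per example; rows must sum to 1.
#' @param true_class integer class index (1-based) per example.
#' @param params a [focal_loss_params()]; `alpha = NULL` means unit weights.
#' @return Mean loss over the examples (non-negative scalar).
#' @export
focal_loss <- function(probabilities, true_class,
                       params = focal_loss_params()) {
  p <- if (is.null(dim(probabilities))) matrix(probabilities, nrow = 1)
       else as.matrix(probabilities)
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6))
    stop("`probabilities` rows must be valid probability vectors",
         call. = FALSE)
  true_class <- as.integer(true_class)
  if (length(true_class) != nrow(p) || any(true_class < 1L) ||
      any(true_class > ncol(p)))
    stop("`true_class` must hold one valid class index per row", call. = FALSE)
  alpha <- params$alpha %||% rep(1, ncol(p))
  pc <- pmax(p[cbind(seq_len(nrow(p)), true_class)], 1e-12)
  mean(-alpha[true_class] * (1 - pc)^params$gamma * log(pc))
}
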