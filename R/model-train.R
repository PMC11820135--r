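#' Fit the motor-imagery transformer decoder
#'
#' The single fitting entry point of the package: featurizes the training
#' epochs (FFT magnitudes, z-scored per channel), builds the transformer
#' with the requested configuration, and trains it with focal loss and Adam
#' under a fixed seed (single-threaded, bit-reproducible). Validation-loss
#' early stopping with weight restoration guards against overfitting; if no
#' validation set is supplied one is split off by trial so no information
#' leaks through overlapping windows.
#'
#' @param epochs training [epoch_set()] containing both classes.
#' @param val_epochs optional validation [epoch_set()]; if `NULL`, a
#'   `val_fraction` trial-level split of `epochs` is used.
#' @param config a [model_config()].
#' @param loss a [focal_loss_params()]; `alpha = NULL` balances classes by
#'   inverse frequency (normalized to mean 1).
#' @param lr,batch_size,max_epochs,patience Adam learning rate, minibatch
#'   size, training-epoch cap, and early-stopping patience.
#' @param val_fraction fraction of trials used for validation when
#'   `val_epochs` is `NULL`.
#' @param seed RNG seed governing initialization, shuffling, and dropout.
#' @param verbose print per-epoch losses.
#' @return An object of class `mi_decoder` with components `weights`,
#'   `config`, `loss`, `classes` (index order: rest = 0, fist = 1),
#'   `history` (per-epoch losses and validation accuracy), and `seed`.
#' @seealso [predict.mi_decoder()], [decode_intent()], [count_params()]
#' @export
mi_decoder <- function(epochs, val_epochs = NULL, config = model_config(),
                       loss = focal_loss_params(), lr = 1e-3,
                       batch_size = 32L, max_epochs = 60L, patience = 10L,
                       val_fraction = 0.2, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(config, "model_config"),
            inherits(loss, "focal_loss_params"))
  if (length(unique(epochs$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  if (is.null(val_epochs)) {
    parts <- split_by_group(epochs, "trial", val_fraction, seed = seed)
    epochs <- parts$train
    val_epochs <- parts$test
  }
  classes <- c("rest", "fist")   # class indices 0 and 1
  Xtr <- featurize_epochs(epochs)
  ytr <- match(epochs$labels, classes)
  Xva <- featurize_epochs(val_epochs)
  yva <- match(val_epochs$labels, classes)
  alpha <- loss$alpha
  if (is.null(alpha)) {
    freq <- tabulate(ytr, nbins = 2L) / length(ytr)
    alpha <- (1 / freq) / mean(1 / freq)
  }
  fit <- with_seed(seed, {
    w <- init_weights(config, seed = stats::runif(1, 1, 2^30))
    train_loop(w, config, Xtr, ytr, Xva, yva, loss$gamma, alpha, lr,
               batch_size, max_epochs, patience, verbose)
  })
  structure(list(weights = fit$weights, config = config,
                 loss = focal_loss_params(loss$gamma, alpha),
                 classes = classes, history = fit$history,
                 channel_names = epochs$channel_names,
                 fs = epochs$fs, seed = as.integer(seed)),
            class = "mi_decoder")
}

#' Build an untrained decoder
#'
#' Initializes the transformer weights for a configuration without
#' training, mainly to inspect the architecture (e.g. [count_params()]).
#'
#' @inheritParams mi_decoder
#' @return An untrained `mi_decoder` (empty history).
#' @export
build_mi_decoder <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  structure(list(weights = init_weights(config, seed), config = config,
                 loss = focal_loss_params(), classes = c("rest", "fist"),
                 history = NULL, channel_names = NULL, fs = NULL,
                 seed = as.integer(seed)),
            class = "mi_decoder")
}

# Minibatch Adam with early stopping; assumes the RNG is already seeded.
train_loop <- function(w, cfg, Xtr, ytr, Xva, yva, gamma, alpha, lr,
                       batch_size, max_epochs, patience, verbose) {
  tn <- trainable_names(w)
  m_t <- lapply(w[tn], function(x) x * 0)
  v_t <- m_t
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- dim(Xtr)[1]
  best <- list(loss = Inf, weights = w, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next  # batch norm needs >= 2 examples
      Xb <- Xtr[idx, , , drop = FALSE]
      yb <- ytr[idx]
      fw <- model_forward(w, cfg, Xb, train = TRUE, collect = TRUE)
      for (nm in names(fw$bn_updates)) w[[nm]] <- fw$bn_updates[[nm]]
      batch_losses <- c(batch_losses,
                        focal_loss(fw$probs, yb,
                                   focal_loss_params(gamma, alpha)))
      dZ <- focal_loss_grad_logits(fw$probs, yb, gamma, alpha)
      g <- model_backward(w, cfg, fw$cache, dZ, length(idx))
      step <- step + 1L
      for (nm in tn) {
        m_t[[nm]] <- beta1 * m_t[[nm]] + (1 - beta1) * g[[nm]]
        v_t[[nm]] <- beta2 * v_t[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m_t[[nm]] / (1 - beta1^step)
        vhat <- v_t[[nm]] / (1 - beta2^step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val <- model_forward(w, cfg, Xva, train = FALSE)
    val_loss <- focal_loss(val$probs, yva, focal_loss_params(gamma, alpha))
    val_acc <- mean(max.col(val$probs) == yva)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = mean(batch_losses),
                                val_loss = val_loss, val_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      ep, mean(batch_losses), val_loss, val_acc))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, weights = w, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  list(weights = best$weights, history = history)
}

#' Count model parameters
#'
#' Total or per-layer parameter counts of a decoder, with the convention
#' that dense and attention layers count weights plus biases, layer
#' normalization counts scale and shift, and batch normalization counts
#' scale, shift, and the (non-trainable) running mean and variance.
#' Layer names follow the reference table (`multi_head_attention`, `dense`,
#' `dense_1`, ..., `layer_normalization`, `layer_normalization_2`, ...,
#' `batch_normalization`, ...).
#'
#' @param decoder an `mi_decoder` (trained or freshly built).
#' @param layer_name optional layer name; `NULL` returns the total.
#' @return Integer count, or the full named vector via
#'   `attr(, "by_layer")` on the total.
#' @export
count_params <- function(decoder, layer_name = NULL) {
  stopifnot(inherits(decoder, "mi_decoder"))
  cfg <- decoder$config
  w <- decoder$weights
  counts <- integer(0)
  nm_count <- function(base, k) if (k == 1L) base else sprintf("%s_%d", base, k)
  n_mha <- 0L; n_ln <- 0L; n_dense <- -1L; n_bn <- 0L
  add <- function(name, parts) {
    counts[[name]] <<- sum(vapply(parts, function(p) length(w[[p]]), 0L))
  }
  for (b in seq_len(cfg$n_encoder_blocks)) {
    p <- sprintf("b%d_", b)
    n_mha <- n_mha + 1L
    add(nm_count("multi_head_attention", n_mha),
        paste0(p, "mha_", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")))
    if (block_has_ffn(cfg, b)) {
      n_ln <- n_ln + 1L
      add(nm_count("layer_normalization", n_ln), paste0(p, c("lna_g", "lna_b")))
      n_dense <- n_dense + 1L
      add(if (n_dense == 0L) "dense" else sprintf("dense_%d", n_dense),
          paste0(p, c("ffn1_W", "ffn1_b")))
      n_dense <- n_dense + 1L
      add(sprintf("dense_%d", n_dense), paste0(p, c("ffn2_W", "ffn2_b")))
      n_ln <- n_ln + 1L
      add(nm_count("layer_normalization", n_ln), paste0(p, c("lnb_g", "lnb_b")))
    }
  }
  for (j in seq_along(cfg$head_units)) {
    n_dense <- n_dense + 1L
    add(if (n_dense == 0L) "dense" else sprintf("dense_%d", n_dense),
        sprintf("head%d_%s", j, c("W", "b")))
    n_bn <- n_bn + 1L
    add(nm_count("batch_normalization", n_bn),
        sprintf("bn%d_%s", j, c("g", "b", "rm", "rv")))
    n_ln <- n_ln + 1L
    add(nm_count("layer_normalization", n_ln),
        sprintf("lnh%d_%s", j, c("g", "b")))
  }
  n_dense <- n_dense + 1L
  add(if (n_dense == 0L) "dense" else sprintf("dense_%d", n_dense),
      c("out_W", "out_b"))
  if (!is.null(layer_name)) {
    if (!layer_name %in% names(counts))
      stop("unknown layer '", layer_name, "'; available: ",
           paste(names(counts), collapse = ", "), call. = FALSE)
    return(counts[[layer_name]])
  }
  structure(sum(counts), by_layer = counts)
}

# Normalize a raw spectral feature the way training features were
# normalized: z-score each channel across its 44 bins.
normalize_feature <- function(f) {
  mu <- colMeans(f)
  sd <- apply(f, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(f, 2, mu), 2, sd, "/")
}

#' Predict class probabilities or labels
#'
#' @param object a trained `mi_decoder`.
#' @param newdata an [epoch_set()], a single `spectral_feature`, or an
#'   `n x 44 x 16` feature array of raw magnitudes.
#' @param type `"prob"` for the probability matrix (columns `rest`, `fist`)
#'   or `"class"` for hard labels at the 0.5 threshold.
#' @param ... unused.
#' @return Probability matrix or character vector of labels.
#' @export
predict.mi_decoder <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  X <- decoder_features(object, newdata)
  probs <- model_forward(object$weights, object$config, X)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "last")]
}

decoder_features <- function(object, newdata) {
  cfg <- object$config
  if (inherits(newdata, "epoch_set")) return(featurize_epochs(newdata))
  if (inherits(newdata, "spectral_feature") ||
      (is.matrix(newdata) && length(dim(newdata)) == 2L)) {
    f <- unclass(newdata)
    if (!all(dim(f) == c(cfg$seq_len, cfg$embed_dim)))
      stop(sprintf("feature shape (%d, %d) does not match the model input (%d, %d)",
                   dim(f)[1], dim(f)[2], cfg$seq_len, cfg$embed_dim),
           call. = FALSE)
    return(array(normalize_feature(f), dim = c(1, dim(f))))
  }
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    if (!all(dim(newdata)[2:3] == c(cfg$seq_len, cfg$embed_dim)))
      stop("feature array shape does not match the model input", call. = FALSE)
    out <- newdata
    for (i in seq_len(dim(out)[1])) out[i, , ] <- normalize_feature(out[i, , ])
    return(out)
  }
  stop("`newdata` must be an epoch_set, a spectral_feature, or a 3-d array",
       call. = FALSE)
}

#' Decode motor intent from one spectral feature
#'
#' Maps a single `(44, 16)` feature to the binary intent `s_t`: 1 (close
#' hand / fist) when `P(fist)` reaches the threshold, else 0 (rest). The
#' tie at exactly the threshold resolves to fist.
#'
#' @param decoder trained `mi_decoder`.
#' @param feature a `spectral_feature` from [featurize()].
#' @param threshold decision threshold on `P(fist)` (default 0.5).
#' @return List with `s_t` (0 or 1) and `probabilities` (named vector).
#' @export
decode_intent <- function(decoder, feature, threshold = 0.5) {
  probs <- predict(decoder, feature)[1, ]
  list(s_t = as.integer(probs[["fist"]] >= threshold),
       probabilities = probs)
}

#' @export
print.mi_decoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mi_decoder> transformer (%d x %d input, %d block%s, %d heads x %d)\n",
              cfg$seq_len, cfg$embed_dim, cfg$n_encoder_blocks,
              if (cfg$n_encoder_blocks > 1) "s" else "", cfg$n_heads,
              cfg$head_size))
  cat(sprintf("  parameters: %d\n", as.integer(count_params(x))))
  if (!is.null(x$history) && nrow(x$history)) {
    b <- which.min(x$history$val_loss)
    cat(sprintf("  trained %d epochs; best val loss %.4f (epoch %d), val accuracy %.3f\n",
                nrow(x$history), x$history$val_loss[b], b,
                x$history$val_accuracy[b]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.mi_decoder <- function(object, ...) {
  print(object)
  by_layer <- attr(count_params(object), "by_layer")
  cat("  per-layer parameters:\n")
  for (nm in names(by_layer))
    cat(sprintf("    %-26s %8d\n", nm, by_layer[[nm]]))
  invisible(by_layer)
}

#' @export
coef.mi_decoder <- function(object, ...) object$weights

#' @export
plot.mi_decoder <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("decoder has no training history",
                                   call. = FALSE)
  ylim <- range(c(h$train_loss, h$val_loss))
  plot(h$epoch, h$train_loss, type = "l", xlab = "training epoch",
       ylab = "focal loss", ylim = ylim, ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(h)
}

#' Save / load a decoder checkpoint
#'
#' The checkpoint is a single RDS archive holding configuration, weights,
#' class mapping, and training history, with a format version that is
#' checked on load.
#'
#' @param decoder an `mi_decoder`.
#' @param path file path.
#' @return `load_checkpoint` returns the `mi_decoder`.
#' @export
save_checkpoint <- function(decoder, path) {
  stopifnot(inherits(decoder, "mi_decoder"))
  saveRDS(list(format = "mibci_checkpoint", version = 1L,
               decoder = unclass(decoder)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mibci_checkpoint"))
    stop("not a decoder checkpoint: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("unsupported checkpoint version: ", obj$version, call. = FALSE)
  structure(obj$decoder, class = "mi_decoder")
}
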