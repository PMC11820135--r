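#' Canonical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz. Bands are
#' half-open `[low, high)` so shared edges belong to the upper band (4 Hz is
#' theta, 13 Hz beta, 30 Hz gamma) and the five bands tile 0.5-45 Hz without
#' overlap. At the 1 Hz bin resolution of 1-second epochs the delta band is
#' effectively truncated to `[1, 4)`.
#'
#' @return Data frame with columns `band`, `low`, `high`.
#' @export
canonical_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.5, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 45),
             stringsAsFactors = FALSE)
}

#' FFT featurization of a single 1-second epoch
#'
#' Transforms one epoch into the frequency-domain matrix the classifier
#' consumes: per channel, the magnitude spectrum at integer frequencies
#' 1..44 Hz. A 1-second window makes the FFT bin spacing exactly 1 Hz, so
#' the output is always `44 x n_channels` (44 bins spanning `[1, 45)` Hz);
#' with the standard montage that is the `(44, 16)` classifier input.
#'
#' @param epoch numeric matrix `n_channels x n_samples`, one second of data.
#' @param fs sampling rate in Hz; must be a whole number >= 90 (so that the
#'   window holds `fs` samples and bin 44 lies below Nyquist) and equal the
#'   epoch length in samples.
#' @return A `spectral_feature`: `44 x n_channels` matrix of non-negative
#'   magnitudes with attributes `bin_freqs` (1..44 Hz) and `channel_names`.
#' @examples
#' x <- matrix(0, 16, 125)
#' x[3, ] <- sin(2 * pi * 10 * (0:124) / 125)
#' f <- featurize(x, 125)
#' which.max(f[, 3])  # bin 10
#' @export
featurize <- function(epoch, fs) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1)
  stopifnot_scalar(fs, "fs")
  if (abs(fs - round(fs)) > 1e-9 || fs < 90)
    stop("`fs` must be a whole number >= 90 Hz for 1 Hz bin spacing",
         call. = FALSE)
  n <- ncol(epoch)
  if (n != round(fs))
    stop(sprintf(
      "epoch has %d samples at fs = %g Hz (%.3g s); featurization requires 1 s epochs so the 44 bins span 1-45 Hz",
      n, fs, n / fs), call. = FALSE)
  vals <- apply(epoch, 1, function(x) 2 * Mod(stats::fft(x))[2:45] / n)
  channel_names <- rownames(epoch) %||% paste0("ch", seq_len(nrow(epoch)))
  structure(vals, bin_freqs = 1:44, channel_names = channel_names,
            class = c("spectral_feature", "matrix", "array"))
}

# Featurize every epoch of a set into an (n, 44, n_channels) array;
# optionally z-score each channel's 44 bins within each epoch (the
# normalization the classifier trains on).
#' Featurize an epoch set
#'
#' @param epochs an [epoch_set()] of 1-second windows.
#' @param normalize z-score each channel's bins within each epoch (the
#'   classifier input convention). `FALSE` returns raw magnitudes.
#' @return Array `n_epochs x 44 x n_channels`.
#' @export
featurize_epochs <- function(epochs, normalize = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- length(epochs)
  out <- array(0, dim = c(n, 44, length(epochs$channel_names)))
  for (i in seq_len(n)) {
    f <- featurize(epochs$windows[i, , ], epochs$fs)
    if (normalize) {
      mu <- colMeans(f)
      sd <- apply(f, 2, stats::sd)
      sd[sd == 0] <- 1
      f <- sweep(sweep(f, 2, mu), 2, sd, "/")
    }
    out[i, , ] <- f
  }
  out
}

#' Band power per epoch, channel, and band
#'
#' Integrated spectral power (sum of squared FFT magnitudes over the band's
#' bins) for each epoch and channel, in long format for condition-wise
#' comparison. With half-open bands the five canonical band powers sum to
#' the total 1-45 Hz power.
#'
#' @param epochs a non-empty [epoch_set()].
#' @param bands band table as from [canonical_bands()].
#' @return Data frame with columns `epoch_id`, `channel`, `band`, `power`,
#'   `label`, `trial`, `session`.
#' @export
band_power <- function(epochs, bands = canonical_bands()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!length(epochs)) stop("`epochs` is empty", call. = FALSE)
  if (any(bands$high > 45.0001) || any(bands$low >= bands$high))
    stop("bands must be valid intervals within the representable 1-45 Hz",
         call. = FALSE)
  n <- length(epochs)
  nch <- length(epochs$channel_names)
  bins <- 1:44
  bin_sets <- lapply(seq_len(nrow(bands)), function(b)
    which(bins >= bands$low[b] & bins < bands$high[b]))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- featurize(epochs$windows[i, , ], epochs$fs)
    pow <- vapply(seq_len(nrow(bands)), function(b)
      colSums(f[bin_sets[[b]], , drop = FALSE]^2), numeric(nch))
    rows[[i]] <- data.frame(
      epoch_id = i,
      channel = rep(epochs$channel_names, times = nrow(bands)),
      band = rep(bands$band, each = nch),
      power = as.vector(pow),
      label = epochs$labels[i],
      trial = epochs$provenance$trial[i],
      session = epochs$provenance$session[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition contrast of band power between two labels
#'
#' Standardized mean difference (Cohen's d, pooled SD) of band power between
#' two conditions, per channel and band, with sign convention `a - b`.
#'
#' @param table long band-power table from [band_power()].
#' @param label_a,label_b condition labels to contrast.
#' @return Data frame with columns `channel`, `band`, `effect`.
#' @export
condition_contrast <- function(table, label_a = "fist", label_b = "rest") {
  needed <- c("channel", "band", "power", "label")
  if (!all(needed %in% names(table)))
    stop("`table` must come from band_power()", call. = FALSE)
  for (l in c(label_a, label_b))
    if (!l %in% table$label)
      stop("label '", l, "' not present in the table", call. = FALSE)
  if (label_a == label_b) stop("labels must differ", call. = FALSE)
  cells <- unique(table[, c("channel", "band")])
  eff <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- table$channel == cells$channel[i] & table$band == cells$band[i]
    xa <- table$power[sel & table$label == label_a]
    xb <- table$power[sel & table$label == label_b]
    na <- length(xa); nb <- length(xb)
    sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) /
      (na + nb - 2)
    eff[i] <- (mean(xa) - mean(xb)) / sqrt(sp2)
  }
  data.frame(channel = cells$channel, band = cells$band, effect = eff,
             stringsAsFactors = FALSE, row.names = NULL)
}
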