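#' Filtering specification for the preprocessing chain
#'
#' Describes the zero-phase signal chain applied to raw recordings: a
#' Butterworth bandpass (default 0.5-45 Hz, the range retaining the neural
#' bands relevant to motor imagery) followed by a mains notch (default
#' 60 Hz). Both are applied forward-backward so epochs stay phase-aligned.
#'
#' @param band_low,band_high bandpass edges in Hz.
#' @param notch_freq notch centre frequency in Hz.
#' @param filter_order Butterworth prototype order (the bandpass has twice
#'   this many poles).
#' @param notch_q quality factor of the notch (bandwidth = freq / Q).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 0.5, band_high = 45, notch_freq = 60,
                        filter_order = 4, notch_q = 30) {
  for (nm in c("band_low", "band_high", "notch_freq", "filter_order",
               "notch_q"))
    stopifnot_scalar(get(nm), nm)
  if (band_low <= 0 || band_low >= band_high)
    stop("need 0 < band_low < band_high", call. = FALSE)
  if (notch_freq <= band_low)
    stop("`notch_freq` must exceed `band_low`", call. = FALSE)
  if (filter_order < 1 || notch_q <= 0)
    stop("invalid filter order or notch Q", call. = FALSE)
  structure(list(band_low = band_low, band_high = band_high,
                 notch_freq = notch_freq,
                 filter_order = as.integer(filter_order),
                 notch_q = notch_q),
            class = "filter_spec")
}

# Butterworth bandpass design as second-order sections.
# Classic zpk route: analog lowpass prototype poles -> lowpass-to-bandpass
# transform -> bilinear transform with prewarped edges. Returns a matrix
# with rows [b0 b1 b2 1 a1 a2]; the overall gain sits in the first row.
butter_bandpass_sos <- function(order, low, high, fs) {
  if (high >= fs / 2)
    stop(sprintf("bandpass edge %g Hz is not below Nyquist (%g Hz)",
                 high, fs / 2), call. = FALSE)
  n <- as.integer(order)
  # prewarped analog edge frequencies (rad/s)
  wl <- 2 * fs * tan(pi * low / fs)
  wh <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # analog lowpass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each prototype pole spawns two poles
  pb <- p_proto * bw / 2
  poles <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  # analog zeros: n at s = 0 (n more at infinity); analog gain bw^n
  k_analog <- bw^n
  # bilinear transform (z = (2fs + s)/(2fs - s))
  zd <- (2 * fs + poles) / (2 * fs - poles)
  k_digital <- k_analog * Re(prod(2 * fs - rep(0+0i, n)) /
                               prod(2 * fs - poles))
  # digital zeros: n at +1 (from s = 0) and n at -1 (from infinity);
  # pair each conjugate pole pair with one zero at +1 and one at -1,
  # i.e. numerator (z - 1)(z + 1) = z^2 - 1 per section.
  idx <- order(Re(zd)^2 + Im(zd)^2, decreasing = TRUE) # innermost last
  zd <- zd[idx]
  used <- rep(FALSE, length(zd))
  sos <- matrix(0, nrow = n, ncol = 6)
  s <- 1L
  for (i in seq_along(zd)) {
    if (used[i]) next
    # find the conjugate partner
    j <- which(!used & abs(zd - Conj(zd[i])) < 1e-8 & seq_along(zd) != i)[1]
    used[c(i, j)] <- TRUE
    p1 <- zd[i]; p2 <- zd[j]
    sos[s, ] <- c(1, 0, -1, 1, -Re(p1 + p2), Re(p1 * p2))
    s <- s + 1L
  }
  sos[1, 1:3] <- sos[1, 1:3] * k_digital
  sos
}

# Second-order IIR notch (constrained biquad, RBJ cookbook form).
notch_sos <- function(freq, q, fs) {
  if (freq >= fs / 2)
    stop(sprintf("notch frequency %g Hz is not below Nyquist (%g Hz)",
                 freq, fs / 2), call. = FALSE)
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0), nrow = 1)
}

# One section, forward, with the initial state matched to the first sample
# so step inputs produce no start-up transient.
filt_section <- function(x, coef) {
  b <- coef[1:3]; a <- coef[4:6]
  K <- sum(b) / sum(a)
  zi <- c(K - b[1], b[3] - a[3] * K) * x[1]
  biquad_filter_cpp(x, b, a, zi)
}

# Zero-phase application of an SOS cascade with odd-reflection padding.
filtfilt_sos <- function(x, sos, padlen) {
  n <- length(x)
  padlen <- max(0L, min(as.integer(padlen), n - 1L))
  if (padlen > 0) {
    head_ext <- 2 * x[1] - x[(padlen + 1):2]
    tail_ext <- 2 * x[n] - x[(n - 1):(n - padlen)]
    ext <- c(head_ext, x, tail_ext)
  } else ext <- x
  for (s in seq_len(nrow(sos))) ext <- filt_section(ext, sos[s, ])
  ext <- rev(ext)
  for (s in seq_len(nrow(sos))) ext <- filt_section(ext, sos[s, ])
  ext <- rev(ext)
  if (padlen > 0) ext[(padlen + 1):(padlen + n)] else ext
}

#' Apply the zero-phase bandpass + notch chain to a recording
#'
#' Filters every channel with a Butterworth bandpass followed by a mains
#' notch, each applied forward and backward (zero phase, no group delay).
#' Annotations and shape are unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param spec a [filter_spec()]; defaults follow the standard motor-imagery
#'   chain (0.5-45 Hz bandpass, 60 Hz notch).
#' @return The filtered `eeg_recording`.
#' @export
apply_filters <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(spec, "filter_spec"))
  fs <- recording$fs
  if (spec$band_high >= fs / 2)
    stop(sprintf("band_high = %g Hz must be below Nyquist (%g Hz)",
                 spec$band_high, fs / 2), call. = FALSE)
  if (spec$notch_freq >= fs / 2)
    stop(sprintf("notch_freq = %g Hz must be below Nyquist (%g Hz)",
                 spec$notch_freq, fs / 2), call. = FALSE)
  bp <- butter_bandpass_sos(spec$filter_order, spec$band_low,
                            spec$band_high, fs)
  nt <- notch_sos(spec$notch_freq, spec$notch_q, fs)
  sos <- rbind(bp, nt)
  padlen <- round(3 * fs)  # covers the slow 0.5 Hz high-pass transient
  out <- recording
  for (ch in seq_len(nrow(recording$samples)))
    out$samples[ch, ] <- filtfilt_sos(recording$samples[ch, ], sos, padlen)
  out
}
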