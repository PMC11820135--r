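#' Synthetic-subject profile
#'
#' Parameters of the synthetic EEG generator that stand in for an individual
#' subject. The physiological handle is `effect_size`: the fractional
#' event-related desynchronization (ERD) of the mu (alpha-band over motor
#' cortex) and beta rhythms on the sensorimotor channels during imagined or
#' executed movement. `effect_size = 0` produces motor-imagery and rest
#' segments drawn from the same distribution; `effect_size = 1` silences the
#' mu/beta rhythms entirely during movement phases.
#'
#' @param effect_size fractional mu/beta amplitude suppression during
#'   movement phases, in `[0, 1]`.
#' @param noise_scale RMS amplitude of the pink (1/f-power) background noise,
#'   in microvolts.
#' @param rest_alpha_gain multiplicative alpha boost applied on all channels
#'   during rest (>= 1). Defaults to 1 so that `effect_size = 0` yields
#'   MI and rest segments that are statistically indistinguishable.
#' @param seed integer RNG seed; identical (profile, protocol, seed) inputs
#'   give bit-identical recordings.
#' @param erd_channels channels carrying the ERD contrast.
#' @param alpha_amp,beta_amp baseline RMS amplitudes (microvolts) of the
#'   band-limited alpha (~10 Hz) and beta (~20 Hz) oscillators.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(effect_size = 0.5, noise_scale = 10,
                            rest_alpha_gain = 1, seed = 1L,
                            erd_channels = c("C3", "C4", "F3", "F4"),
                            alpha_amp = 8, beta_amp = 4) {
  for (nm in c("effect_size", "noise_scale", "rest_alpha_gain", "seed",
               "alpha_amp", "beta_amp"))
    stopifnot_scalar(get(nm), nm)
  if (effect_size < 0 || effect_size > 1)
    stop("`effect_size` must lie in [0, 1]", call. = FALSE)
  if (noise_scale < 0 || alpha_amp < 0 || beta_amp < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (rest_alpha_gain < 1)
    stop("`rest_alpha_gain` must be >= 1", call. = FALSE)
  structure(list(effect_size = effect_size, noise_scale = noise_scale,
                 rest_alpha_gain = rest_alpha_gain, seed = as.integer(seed),
                 erd_channels = as.character(erd_channels),
                 alpha_amp = alpha_amp, beta_amp = beta_amp),
            class = "subject_profile")
}

#' Acquisition-protocol description
#'
#' One trial consists of the listed phases in order (by default motor
#' execution, motor imagery, rest), each lasting `phase_duration_s` seconds;
#' a session holds `n_trials_per_session` trials and a subject contributes
#' `n_sessions` sessions. With the defaults (3 phases x 16 s x 6 trials x
#' 3 sessions) one subject yields 864 s of annotated task data.
#'
#' @param phase_order phases making up one trial.
#' @param phase_duration_s duration of each phase, seconds.
#' @param n_trials_per_session trials per session.
#' @param n_sessions number of sessions.
#' @param randomize_order randomize the phase order within each trial
#'   (seed-deterministic), emulating a randomized task schedule.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(phase_order = c("motor_execution", "motor_imagery",
                                          "rest"),
                          phase_duration_s = 16, n_trials_per_session = 6,
                          n_sessions = 3, randomize_order = TRUE) {
  phase_order <- match.arg(phase_order, phase_labels(), several.ok = TRUE)
  stopifnot_scalar(phase_duration_s, "phase_duration_s")
  if (phase_duration_s <= 0) stop("`phase_duration_s` must be positive",
                                  call. = FALSE)
  n_trials_per_session <- as.integer(n_trials_per_session)
  n_sessions <- as.integer(n_sessions)
  if (n_trials_per_session < 1L || n_sessions < 1L)
    stop("trial and session counts must be >= 1", call. = FALSE)
  structure(list(phase_order = phase_order,
                 phase_duration_s = phase_duration_s,
                 n_trials_per_session = n_trials_per_session,
                 n_sessions = n_sessions,
                 randomize_order = isTRUE(randomize_order)),
            class = "protocol_spec")
}

# Unit-RMS pink noise (power ~ 1/f) of length n, synthesized in the
# frequency domain from the current RNG stream.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) # two-sided bin index
  f[1] <- 1                                       # guard DC
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Unit-RMS band-limited oscillator centred at f0 Hz with Gaussian spectral
# width bw Hz, synthesized by frequency-domain masking of white noise.
narrowband <- function(n, fs, f0, bw) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  mask <- exp(-0.5 * ((freq - f0) / bw)^2) + exp(-0.5 * ((freq + f0) / bw)^2)
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Build the trial/phase schedule implied by a protocol (seed already set).
build_schedule <- function(protocol) {
  rows <- list()
  k <- 1L
  t0 <- 0
  for (s in seq_len(protocol$n_sessions)) {
    for (tr in seq_len(protocol$n_trials_per_session)) {
      order <- protocol$phase_order
      if (protocol$randomize_order) order <- sample(order)
      for (ph in order) {
        rows[[k]] <- data.frame(onset_s = t0,
                                duration_s = protocol$phase_duration_s,
                                phase = ph, trial = tr, session = s,
                                stringsAsFactors = FALSE)
        t0 <- t0 + protocol$phase_duration_s
        k <- k + 1L
      }
    }
  }
  do.call(rbind, rows)
}

# Per-sample gain envelopes for the alpha and beta oscillators of one
# channel, derived from the annotation schedule.
phase_envelopes <- function(ann, n, fs, is_erd, effect_size, rest_alpha_gain) {
  g_alpha <- rep(1, n)
  g_beta <- rep(1, n)
  for (i in seq_len(nrow(ann))) {
    a <- ann$onset_s[i] * fs + 1
    b <- (ann$onset_s[i] + ann$duration_s[i]) * fs
    idx <- seq.int(round(a), min(round(b), n))
    if (ann$phase[i] == "rest") {
      g_alpha[idx] <- g_alpha[idx] * rest_alpha_gain
    } else if (is_erd) { # motor imagery and motor execution desynchronize
      g_alpha[idx] <- g_alpha[idx] * (1 - effect_size)
      g_beta[idx] <- g_beta[idx] * (1 - effect_size)
    }
  }
  list(alpha = g_alpha, beta = g_beta)
}

#' Generate a protocol-faithful synthetic EEG recording
#'
#' Synthesizes a continuous 16-channel recording as pink (1/f-power)
#' background noise plus band-limited alpha (~10 Hz) and beta (~20 Hz)
#' oscillators, with the mu/beta rhythms attenuated by
#' `1 - effect_size` on the sensorimotor channels during movement phases
#' (the ERD contrast) and the alpha rhythm boosted by `rest_alpha_gain`
#' during rest. The annotation track marks every phase interval with its
#' label, trial, and session.
#'
#' @param profile a [subject_profile()].
#' @param protocol a [protocol_spec()].
#' @param fs sampling rate, Hz (>= 100).
#' @param montage character vector of 16 channel labels.
#' @return An [eeg_recording()] with complete phase annotations.
#' @examples
#' rec <- generate_recording(subject_profile(effect_size = 0.6, seed = 7),
#'                           protocol_spec(n_trials_per_session = 2,
#'                                         n_sessions = 1))
#' rec
#' @export
generate_recording <- function(profile, protocol = protocol_spec(),
                               fs = 125, montage = default_montage()) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(protocol, "protocol_spec"))
  stopifnot_scalar(fs, "fs")
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  montage <- as.character(montage)
  if (length(montage) != 16L)
    stop("`montage` must list exactly 16 channels", call. = FALSE)
  with_seed(profile$seed, {
    ann <- build_schedule(protocol)
    total_s <- sum(ann$duration_s)
    n <- round(total_s * fs)
    samples <- matrix(0, nrow = 16L, ncol = n)
    for (ch in seq_len(16L)) {
      is_erd <- montage[ch] %in% profile$erd_channels
      env <- phase_envelopes(ann, n, fs, is_erd, profile$effect_size,
                             profile$rest_alpha_gain)
      sig <- profile$noise_scale * pink_noise(n) +
        profile$alpha_amp * env$alpha * narrowband(n, fs, 10, 1) +
        profile$beta_amp * env$beta * narrowband(n, fs, 20, 2)
      samples[ch, ] <- sig
    }
    eeg_recording(samples, fs, montage, ann)
  })
}

#' Generate a balanced batch of labeled 1-second epochs
#'
#' Shortcut for unit and end-to-end tests: produces `n_per_class` epochs of
#' each class (`fist` = motor imagery, `rest`) directly, using the same
#' signal model as [generate_recording()]. Consecutive epochs are grouped
#' into pseudo-trials (10 epochs per trial) so leakage-safe grouped splits
#' can be exercised on batches.
#'
#' @param profile a [subject_profile()].
#' @param n_per_class epochs per class (>= 1).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed for the batch (defaults to the profile seed).
#' @param montage channel labels (16).
#' @return An [epoch_set()] with `2 * n_per_class` epochs.
#' @export
generate_epoch_batch <- function(profile, n_per_class, fs = 125,
                                 seed = profile$seed,
                                 montage = default_montage()) {
  stopifnot(inherits(profile, "subject_profile"))
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L)
    stop("`n_per_class` must be >= 1", call. = FALSE)
  stopifnot_scalar(fs, "fs")
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  montage <- as.character(montage)
  if (length(montage) != 16L)
    stop("`montage` must list exactly 16 channels", call. = FALSE)
  len <- round(fs)  # 1-second epochs
  with_seed(seed, {
    n_total <- 2L * n_per_class
    windows <- array(0, dim = c(n_total, 16L, len))
    labels <- rep(c("fist", "rest"), each = n_per_class)
    for (cls in c("fist", "rest")) {
      idx <- which(labels == cls)
      dur <- n_per_class * len
      for (ch in seq_len(16L)) {
        is_erd <- montage[ch] %in% profile$erd_channels
        g_alpha <- if (cls == "fist" && is_erd) 1 - profile$effect_size
                   else if (cls == "rest") profile$rest_alpha_gain else 1
        g_beta <- if (cls == "fist" && is_erd) 1 - profile$effect_size else 1
        sig <- profile$noise_scale * pink_noise(dur) +
          profile$alpha_amp * g_alpha * narrowband(dur, fs, 10, 1) +
          profile$beta_amp * g_beta * narrowband(dur, fs, 20, 2)
        for (j in seq_along(idx))
          windows[idx[j], ch, ] <- sig[((j - 1L) * len + 1L):(j * len)]
      }
    }
    prov <- data.frame(trial = ((seq_len(n_total) - 1L) %/% 10L) + 1L,
                       session = 1L,
                       phase = ifelse(labels == "fist", "motor_imagery",
                                      "rest"),
                       onset_s = (seq_len(n_total) - 1L) * 1.0,
                       stringsAsFactors = FALSE)
    epoch_set(windows, labels, fs, montage, prov)
  })
}

#' Inject a power-line-like sinusoid into a recording
#'
#' Adds a pure sinusoid at `line_freq` to every channel, emulating mains
#' interference so the notch filter can be tested against a known
#' contaminant. The input recording is not modified.
#'
#' @param recording an [eeg_recording()].
#' @param line_freq interference frequency, Hz (must be below Nyquist).
#' @param amplitude peak amplitude in microvolts.
#' @return A new `eeg_recording` with the sinusoid added.
#' @export
inject_artifacts <- function(recording, line_freq = 60, amplitude = 50) {
  stopifnot(inherits(recording, "eeg_recording"))
  stopifnot_scalar(line_freq, "line_freq")
  stopifnot_scalar(amplitude, "amplitude")
  if (line_freq <= 0 || line_freq >= recording$fs / 2)
    stop(sprintf("line_freq = %g Hz would alias: need 0 < f < fs/2 = %g Hz",
                 line_freq, recording$fs / 2), call. = FALSE)
  n <- ncol(recording$samples)
  tone <- amplitude * sin(2 * pi * line_freq * (seq_len(n) - 1) / recording$fs)
  out <- recording
  out$samples <- recording$samples +
    matrix(tone, nrow = nrow(recording$samples), ncol = n, byrow = TRUE)
  out
}
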