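#' Annotated multichannel EEG recording
#'
#' The central data container of the package: a continuous multichannel EEG
#' signal in microvolts, with its sampling rate, 10-20 channel labels, and a
#' phase-annotation table marking motor-execution / motor-imagery / rest
#' intervals together with their trial and session indices.
#'
#' @param samples numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of 10-20 labels, one per row of
#'   `samples`.
#' @param annotations data frame with columns `onset_s`, `duration_s`,
#'   `phase`, `trial`, `session`. Onsets are seconds from recording start;
#'   sample indices derived from them are half-open `[start, end)`.
#'
#' @return An object of class `eeg_recording`.
#' @seealso [read_recording()], [write_recording()], [select_channels()]
#' @export
eeg_recording <- function(samples, fs, channel_names,
                          annotations = empty_annotations()) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` contains non-finite values", call. = FALSE)
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples))
    stop(sprintf("channel count mismatch: %d names for %d signal rows",
                 length(channel_names), nrow(samples)), call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("duplicate channel names", call. = FALSE)
  annotations <- validate_annotations(annotations, ncol(samples) / fs)
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         annotations = annotations),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$fs
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$samples), ncol(x$samples), dur, x$fs))
  cat("  channels:", paste(x$channel_names, collapse = " "), "\n")
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$phase)
    cat(sprintf("  annotations: %d intervals (%s)\n", nrow(x$annotations),
                paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  } else cat("  annotations: none\n")
  invisible(x)
}

#' Phase labels recognised in annotation tables
#' @return Character vector of the three valid phase labels.
#' @export
phase_labels <- function() c("motor_execution", "motor_imagery", "rest")

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             phase = character(0), trial = integer(0), session = integer(0),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, total_s) {
  needed <- c("onset_s", "duration_s", "phase", "trial", "session")
  if (!is.data.frame(ann) || !all(needed %in% names(ann)))
    stop("annotations must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  ann <- ann[, needed, drop = FALSE]
  if (!nrow(ann)) return(ann)
  ann$phase <- as.character(ann$phase)
  bad <- setdiff(unique(ann$phase), phase_labels())
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(phase_labels(), collapse = ", "), ")",
         call. = FALSE)
  if (any(ann$duration_s <= 0)) stop("annotation durations must be positive",
                                     call. = FALSE)
  if (any(ann$onset_s < -1e-9) ||
      any(ann$onset_s + ann$duration_s > total_s + 1e-9))
    stop("annotations extend outside the recording [0, ",
         signif(total_s, 6), "] s", call. = FALSE)
  # non-overlap within a trial (same session + trial id)
  key <- paste(ann$session, ann$trial)
  for (k in unique(key)) {
    a <- ann[key == k, , drop = FALSE]
    a <- a[order(a$onset_s), , drop = FALSE]
    if (nrow(a) > 1) {
      ends <- a$onset_s + a$duration_s
      if (any(a$onset_s[-1] < ends[-nrow(a)] - 1e-9))
        stop("overlapping annotations within session ", a$session[1],
             " trial ", a$trial[1], call. = FALSE)
    }
  }
  ann$trial <- as.integer(ann$trial)
  ann$session <- as.integer(ann$session)
  rownames(ann) <- NULL
  ann
}

#' Restrict a recording to a subset of channels
#'
#' @param recording an [eeg_recording()].
#' @param names channel labels to keep, in the requested order.
#' @return An `eeg_recording` containing only the named channels;
#'   annotations are preserved unchanged.
#' @examples
#' rec <- generate_recording(subject_profile(seed = 1),
#'                           protocol_spec(n_trials_per_session = 1,
#'                                         n_sessions = 1))
#' frontal <- select_channels(rec, c("F7", "F8", "F3"))
#' @export
select_channels <- function(recording, names) {
  stopifnot(inherits(recording, "eeg_recording"))
  names <- as.character(names)
  missing <- setdiff(names, recording$channel_names)
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(recording$channel_names, collapse = ", "),
         call. = FALSE)
  idx <- match(names, recording$channel_names)
  eeg_recording(recording$samples[idx, , drop = FALSE], recording$fs,
                names, recording$annotations)
}

#' Default 16-channel 10-20 montage
#'
#' The standard 16-electrode layout used by common consumer/research EEG
#' amplifiers with a 10-20 cap.
#' @return Character vector of 16 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "C3", "C4", "P7", "P8", "O1", "O2",
    "F7", "F8", "F3", "F4", "T7", "T8", "P3", "P4")
}
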