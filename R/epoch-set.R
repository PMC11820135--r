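#' Labeled EEG epoch set
#'
#' Fixed-length analysis windows cut from continuous EEG, each carrying a
#' class label (`fist` for motor imagery, `rest` for baseline) and its
#' provenance (session, trial, phase, onset). Windows all share one length
#' and sampling rate so they can be featurized as a batch.
#'
#' @param windows numeric array `n_epochs x n_channels x n_samples` (microvolts).
#' @param labels character/factor vector of length `n_epochs` with values in
#'   `{"fist", "rest"}`.
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels (length = `dim(windows)[2]`).
#' @param provenance data frame with one row per epoch and columns
#'   `trial`, `session`, `phase`, `onset_s`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(windows, labels, fs, channel_names, provenance) {
  if (!is.array(windows) || length(dim(windows)) != 3L)
    stop("`windows` must be a 3-d array (epochs x channels x samples)",
         call. = FALSE)
  n <- dim(windows)[1]
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("`labels` length does not match epoch count", call. = FALSE)
  bad <- setdiff(unique(labels), c("fist", "rest"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot_scalar(fs, "fs")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(windows)[2])
    stop("`channel_names` length does not match channel dimension", call. = FALSE)
  needed <- c("trial", "session", "phase", "onset_s")
  if (!is.data.frame(provenance) || nrow(provenance) != n ||
      !all(needed %in% names(provenance)))
    stop("`provenance` must have one row per epoch and columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  structure(list(windows = windows, labels = labels, fs = fs,
                 channel_names = channel_names,
                 provenance = provenance[, needed, drop = FALSE]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$windows)
  tab <- table(x$labels)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  if (d[1]) cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.epoch_set <- function(x) dim(x$windows)[1]

#' Subset an epoch set by epoch index
#' @param x an [epoch_set()].
#' @param i integer or logical index over epochs.
#' @param ... unused.
#' @return An `epoch_set` restricted to the selected epochs.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$windows[i, , , drop = FALSE], x$labels[i], x$fs,
            x$channel_names, x$provenance[i, , drop = FALSE])
}
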