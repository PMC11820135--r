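#' Crop phase transitions from the annotations
#'
#' Shortens every phase annotation by `trim_s` seconds at both ends, removing
#' the transitional activity around task onsets/offsets from epoch
#' eligibility. The crop is annotation-level: the continuous signal is left
#' untouched (so filters see continuous data and their edge transients stay
#' outside the eligible intervals).
#'
#' @param recording an [eeg_recording()].
#' @param trim_s seconds removed from each end of every phase (default 3).
#' @return The recording with shortened annotations.
#' @export
crop_phases <- function(recording, trim_s = 3) {
  stopifnot(inherits(recording, "eeg_recording"))
  stopifnot_scalar(trim_s, "trim_s")
  if (trim_s < 0) stop("`trim_s` must be >= 0", call. = FALSE)
  if (trim_s == 0) return(recording)
  ann <- recording$annotations
  short <- ann$duration_s <= 2 * trim_s
  if (any(short)) {
    i <- which(short)[1]
    stop(sprintf(
      "phase '%s' of session %d trial %d lasts %.3g s; cannot trim %.3g s from each end",
      ann$phase[i], ann$session[i], ann$trial[i], ann$duration_s[i], trim_s),
      call. = FALSE)
  }
  ann$onset_s <- ann$onset_s + trim_s
  ann$duration_s <- ann$duration_s - 2 * trim_s
  recording$annotations <- ann
  recording
}

#' Cut labeled overlapping epochs from the eligible phase intervals
#'
#' Slides a `length_s` window with hop `length_s - overlap_s` over every
#' annotated interval whose phase is mapped to a class, producing
#' `floor((T - length_s)/hop) + 1` epochs from an interval of duration `T`
#' (zero if `T < length_s`). No epoch ever crosses an interval boundary.
#'
#' @param recording an [eeg_recording()] (typically after [crop_phases()]).
#' @param length_s epoch length in seconds (default 1).
#' @param overlap_s overlap between consecutive epochs (default 0.75, i.e.
#'   a 0.25 s hop).
#' @param label_map named character vector mapping phase labels to class
#'   labels; phases mapped to `"exclude"` (or absent) yield no epochs. The
#'   default keeps motor imagery (as class `fist`) and rest, and excludes
#'   motor execution.
#' @return An [epoch_set()].
#' @export
make_epochs <- function(recording, length_s = 1, overlap_s = 0.75,
                        label_map = c(motor_imagery = "fist", rest = "rest",
                                      motor_execution = "exclude")) {
  stopifnot(inherits(recording, "eeg_recording"))
  stopifnot_scalar(length_s, "length_s")
  stopifnot_scalar(overlap_s, "overlap_s")
  if (length_s <= 0) stop("`length_s` must be positive", call. = FALSE)
  if (overlap_s < 0 || overlap_s >= length_s)
    stop("need 0 <= overlap_s < length_s", call. = FALSE)
  bad <- setdiff(setdiff(unique(names(label_map)), phase_labels()),
                 character(0))
  if (length(bad))
    stop("label_map names unknown phase(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  fs <- recording$fs
  hop <- length_s - overlap_s
  n_len <- round(length_s * fs)
  ann <- recording$annotations
  win_list <- list(); lab <- character(0)
  prov <- list()
  k <- 0L
  for (i in seq_len(nrow(ann))) {
    cls <- unname(label_map[ann$phase[i]])
    if (is.na(cls) || cls == "exclude") next
    T_i <- ann$duration_s[i]
    if (T_i < length_s - 1e-9) next
    n_ep <- floor((T_i - length_s) / hop + 1e-9) + 1L
    starts <- ann$onset_s[i] + (seq_len(n_ep) - 1L) * hop
    for (s0 in starts) {
      a <- round(s0 * fs) + 1L
      k <- k + 1L
      win_list[[k]] <- recording$samples[, a:(a + n_len - 1L), drop = FALSE]
      lab[k] <- cls
      prov[[k]] <- data.frame(trial = ann$trial[i], session = ann$session[i],
                              phase = ann$phase[i], onset_s = s0,
                              stringsAsFactors = FALSE)
    }
  }
  n_ch <- nrow(recording$samples)
  windows <- array(0, dim = c(k, n_ch, n_len))
  for (j in seq_len(k)) windows[j, , ] <- win_list[[j]]
  provenance <- if (k) do.call(rbind, prov) else
    data.frame(trial = integer(0), session = integer(0),
               phase = character(0), onset_s = numeric(0))
  epoch_set(windows, lab, fs, recording$channel_names, provenance)
}

#' Leakage-safe grouped train/test split
#'
#' Overlapping windows share up to 75% of their samples with their
#' neighbours, so any within-trial split leaks test information into
#' training. This splitter therefore assigns whole groups (trials or
#' sessions) to one partition, stratifying at the group level so both
#' classes appear on both sides.
#'
#' @param epochs an [epoch_set()].
#' @param group `"trial"` (session x trial, the default) or `"session"`.
#' @param test_fraction fraction of groups assigned to the test partition.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return A list with elements `train` and `test`, both [epoch_set()]s.
#' @export
split_by_group <- function(epochs, group = c("trial", "session"),
                           test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  group <- match.arg(group)
  stopifnot_scalar(test_fraction, "test_fraction")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  prov <- epochs$provenance
  key <- if (group == "trial") paste(prov$session, prov$trial, sep = ":")
         else as.character(prov$session)
  groups <- unique(key)
  if (length(groups) < 2L)
    stop("need at least 2 groups to split (found ", length(groups), ")",
         call. = FALSE)
  # stratify groups by their class composition
  sig <- vapply(groups, function(g)
    paste(sort(unique(epochs$labels[key == g])), collapse = "+"), "")
  test_groups <- with_seed(seed, {
    out <- character(0)
    for (s in unique(sig)) {
      g_s <- groups[sig == s]
      # round, but keep at least one group on each side of the split
      n_test <- max(1L, min(round(test_fraction * length(g_s)),
                            length(g_s) - 1L))
      out <- c(out, sample(g_s, n_test))
    }
    out
  })
  in_test <- key %in% test_groups
  train <- epochs[!in_test]
  test <- epochs[in_test]
  for (part in list(train, test))
    if (length(unique(part$labels)) < 2L)
      stop("impossible stratification: a partition ended up single-class",
           call. = FALSE)
  list(train = train, test = test)
}
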