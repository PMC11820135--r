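#' Write an annotated recording to CSV or EDF+
#'
#' CSV dialect: one header row of channel names, one column per channel,
#' samples in rows, microvolts; annotations go to a sidecar
#' `<name>.annotations.csv` with columns
#' `onset_s,duration_s,phase,trial,session`. EDF writes a 16-bit EDF+C file
#' with the annotations in the standard `EDF Annotations` signal and the
#' physical range set per channel from the data (so amplitudes survive
#' within 16-bit quantization). EDF requires an integer sampling rate and
#' pads the final data record with zeros to a whole second.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = infer_format(path)) {
  stopifnot(inherits(recording, "eeg_recording"))
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") {
    df <- as.data.frame(t(recording$samples))
    names(df) <- recording$channel_names
    utils::write.csv(df, path, row.names = FALSE)
    ann <- recording$annotations
    names(ann) <- c("onset_s", "duration_s", "phase", "trial", "session")
    utils::write.csv(ann, annotation_sidecar(path), row.names = FALSE)
  } else {
    write_edf(recording, path)
  }
  invisible(path)
}

#' Read an annotated recording from CSV or EDF+
#'
#' Validates rather than repairs: inconsistent CSV row lengths, a column
#' count that disagrees with the header, or an unknown phase label raise a
#' format error naming the offending line or record.
#'
#' @param path input file path (for CSV the sidecar
#'   `<name>.annotations.csv` is read if present).
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @param fs sampling rate in Hz; required for CSV (the dialect does not
#'   store it), ignored for EDF.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = infer_format(path), fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format, c("csv", "edf"))
  if (format == "edf") return(read_edf(path))
  if (is.null(fs))
    stop("`fs` must be given when reading the CSV dialect", call. = FALSE)
  counts <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("malformed CSV: line %d has %d fields, expected %d",
                 bad, counts[bad], counts[1]), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- gsub('^"|"$', "", header)
  if (length(header) != counts[1])
    stop(sprintf("header names %d channels but rows have %d fields",
                 length(header), counts[1]), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE,
                        colClasses = rep("numeric", length(header)))
  ann_path <- annotation_sidecar(path)
  ann <- if (file.exists(ann_path)) {
    a <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
    names(a)[names(a) == "phase"] <- "phase"
    a
  } else empty_annotations()
  eeg_recording(t(as.matrix(df)), fs, header, ann)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "edf")) ext else "csv"
}

annotation_sidecar <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path) |> paste0(".annotations.csv")
}

#' Save / load an epoch set
#'
#' Lossless round trip of windows, labels, and provenance via a versioned
#' RDS archive.
#'
#' @param epochs an [epoch_set()].
#' @param path file path.
#' @return `load_epochs` returns the [epoch_set()].
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(list(format = "mibci_epochs", version = 1L,
               payload = unclass(epochs)), path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read epoch archive ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "mibci_epochs"))
    stop("not an epoch archive: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("unsupported epoch archive version: ", obj$version, call. = FALSE)
  p <- obj$payload
  epoch_set(p$windows, p$labels, p$fs, p$channel_names, p$provenance)
}

# ---- minimal EDF+C implementation -----------------------------------------
# 256-byte main header + 256 bytes per signal, then 16-bit little-endian
# data records of 1 s each; annotations live in the standard
# "EDF Annotations" signal as TALs (one time-keeping TAL per record).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  for (d in seq(width - 1, 1)) {
    s <- as.character(signif(x, d))
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("cannot format ", x, " into ", width, " bytes", call. = FALSE)
}

tal_phase <- function(phase, trial, session)
  sprintf("%s@t%ds%d", phase, trial, session)

write_edf <- function(recording, path) {
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  x <- recording$samples
  nch <- nrow(x)
  n_records <- as.integer(ceiling(ncol(x) / fs))
  if (ncol(x) < n_records * fs)                      # pad to whole seconds
    x <- cbind(x, matrix(0, nch, n_records * fs - ncol(x)))
  # physical scaling per channel
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  # annotation TALs per record; every TAL is nul-terminated
  ann <- recording$annotations
  tal_records <- lapply(seq_len(n_records) - 1L, function(r) {
    tals <- sprintf("+%d\x14\x14", r)                # time-keeping TAL
    rows <- which(ann$onset_s >= r & ann$onset_s < r + 1)
    for (i in rows)
      tals <- c(tals, sprintf("+%.6g\x15%.6g\x14%s\x14",
                              ann$onset_s[i], ann$duration_s[i],
                              tal_phase(ann$phase[i], ann$trial[i],
                                        ann$session[i])))
    do.call(c, lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
  })
  ann_bytes <- max(vapply(tal_records, length, 0L))
  ann_bytes <- ann_bytes + ann_bytes %% 2L           # even byte count
  ann_samples <- ann_bytes %/% 2L
  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(edf_pad("0", 8))
  put(edf_pad("X X X X", 80))                        # local patient id
  put(edf_pad("Startdate 01-JAN-2026 X X X", 80))    # local recording id
  put(edf_pad("01.01.26", 8)); put(edf_pad("00.00.00", 8))
  put(edf_pad(header_bytes, 8))
  put(edf_pad("EDF+C", 44))
  put(edf_pad(n_records, 8))
  put(edf_pad("1", 8))                               # record duration, s
  put(edf_pad(ns, 4))
  labels <- c(recording$channel_names, "EDF Annotations")
  for (l in labels) put(edf_pad(l, 16))
  for (i in seq_len(ns)) put(edf_pad("", 80))        # transducer
  for (i in seq_len(ns)) put(edf_pad(if (i <= nch) "uV" else "", 8))
  for (i in seq_len(ns)) put(edf_num(if (i <= nch) pmin[i] else -1, 8))
  for (i in seq_len(ns)) put(edf_num(if (i <= nch) pmax[i] else 1, 8))
  for (i in seq_len(ns)) put(edf_pad(-32768L, 8))
  for (i in seq_len(ns)) put(edf_pad(32767L, 8))
  for (i in seq_len(ns)) put(edf_pad("", 80))        # prefiltering
  for (i in seq_len(ns)) put(edf_pad(if (i <= nch) fs else ann_samples, 8))
  for (i in seq_len(ns)) put(edf_pad("", 32))
  # data records
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((x[ch, cols] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                     65535 - 32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
    raw_tal <- tal_records[[r]]
    raw_tal <- c(raw_tal, raw(ann_bytes - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(n) {
    s <- rawToChar(readBin(con, "raw", n))
    trimws(s)
  }
  get(8)                                             # version
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8))
  get(44)
  n_records <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  if (is.na(ns) || ns < 1L)
    stop("malformed EDF header in ", path, call. = FALSE)
  field <- function(w) vapply(seq_len(ns), function(i) get(w), "")
  labels <- field(16)
  field(80)
  field(8)                                           # physical dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  nsamp <- as.integer(field(8))
  field(32)
  seek(con, header_bytes)
  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  fs <- nsamp[sig_idx[1]] / rec_dur
  samples <- matrix(0, length(sig_idx), n_records * nsamp[sig_idx[1]])
  tal_raw <- list()
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        tal_raw[[length(tal_raw) + 1L]] <- readBin(con, "raw", 2L * nsamp[i])
      } else {
        dig <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                       endian = "little")
        if (length(dig) < nsamp[i])
          stop(sprintf("EDF record %d truncated in %s", r, path),
               call. = FALSE)
        k <- match(i, sig_idx)
        cols <- ((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])
        samples[k, cols] <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
          (pmax[i] - pmin[i]) + pmin[i]
      }
    }
  }
  ann <- parse_tals(do.call(c, c(tal_raw, list(raw(0)))))
  eeg_recording(samples, fs, labels[sig_idx], ann)
}

# `bytes` is the raw annotation stream; TALs are separated by nul bytes.
parse_tals <- function(bytes) {
  if (!length(bytes)) return(empty_annotations())
  zero <- bytes == as.raw(0)
  grp <- cumsum(c(FALSE, zero[-length(zero)]))  # id advances after each nul
  tals <- vapply(split(bytes[!zero], grp[!zero]), rawToChar, "")
  rows <- list(); k <- 0L
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2L || !nzchar(parts[2])) next # time-keeping TAL
    od <- strsplit(parts[1], "\x15")[[1]]
    onset <- as.numeric(od[1])
    dur <- if (length(od) > 1) as.numeric(od[2]) else 0
    for (lab in parts[-1]) {
      if (!nzchar(lab)) next
      m <- regmatches(lab, regexec("^(.*)@t(\\d+)s(\\d+)$", lab))[[1]]
      if (length(m) == 4L) {
        k <- k + 1L
        rows[[k]] <- data.frame(onset_s = onset, duration_s = dur,
                                phase = m[2], trial = as.integer(m[3]),
                                session = as.integer(m[4]),
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(empty_annotations())
  do.call(rbind, rows)
}
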