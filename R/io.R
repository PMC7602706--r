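#' Write a recording to CSV/TSV
#'
#' One column per channel with a header row of labels and a
#' `# sampling_rate=<Hz>` comment line, so the file is self-describing.
#'
#' @param rec an `eeg_recording`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sampling_rate=", rec$sampling_rate), con)
  write.table(rec$samples, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a recording from CSV/TSV or EDF
#'
#' Tabular files must have a header row of unique channel labels and may
#' carry a `# sampling_rate=` comment (otherwise `sampling_rate` is
#' required).  EDF files are read with the built-in minimal reader (16-bit,
#' continuous).
#'
#' @param path input path.
#' @param sampling_rate sampling rate in Hz, overriding / replacing file
#'   metadata.
#' @param format `"csv"`, `"tsv"`, `"edf"`, or `NULL` to infer from the
#'   extension.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, sampling_rate = NULL, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("csv", "tsv", "edf"))
    stop("unsupported format: ", format)
  if (format == "edf") {
    ed <- read_edf(path)
    if (!is.null(sampling_rate)) ed$sampling_rate <- sampling_rate
    return(ed)
  }
  sep <- if (format == "tsv") "\t" else ","
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*sampling_rate=", first)) {
    fs_file <- suppressWarnings(as.numeric(sub("^#\\s*sampling_rate=", "", first)))
    if (!is.finite(fs_file)) stop("malformed sampling_rate header")
    if (is.null(sampling_rate)) sampling_rate <- fs_file
  }
  if (is.null(sampling_rate))
    stop("sampling rate missing: not in file header and not supplied")
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric sample values in ", path)
  eeg_recording(as.matrix(df), sampling_rate, names(df))
}

#' Write an event table to TSV
#' @param events an `event_table`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Read an event table from TSV
#'
#' Expects columns `onset_s`, `hand`, `cue_duration_s` and optionally
#' `unclench_s` (default `onset_s + 4.5`) and `keep` (default `TRUE`).
#'
#' @param path input path.
#' @return an `event_table`.
#' @export
read_events <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("onset_s", "hand") %in% names(df)))
    stop("events file must have onset_s and hand columns")
  event_table(onset_s = df$onset_s, hand = df$hand,
              cue_duration_s = if (is.null(df$cue_duration_s)) NA_real_
                               else df$cue_duration_s,
              unclench_s = if (is.null(df$unclench_s)) df$onset_s + 4.5
                           else df$unclench_s,
              keep = if (is.null(df$keep)) TRUE else df$keep)
}

#' Write / read a pipeline config as JSON
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), path)
}

#' @rdname write_config
#' @return `read_config` returns a validated `pipeline_config`; unknown keys
#'   are rejected.
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(pipeline_config, vals)
}

#' Save a cohort to disk / load it back
#'
#' Writes `<id>_recording.csv` and `<id>_events.tsv` per subject plus a
#' `manifest.json` with the ground truth.  `load_cohort` reconstructs a
#' cohort-shaped list (without generator internals) from such a directory;
#' group labels are taken from the id prefix before the first underscore.
#'
#' @param cohort a `windfa_cohort`.
#' @param dir directory (created if missing).
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (su in cohort$subjects) {
    write_recording(su$recording, file.path(dir, paste0(su$id, "_recording.csv")))
    write_events(su$events, file.path(dir, paste0(su$id, "_events.tsv")))
  }
  man <- cohort$manifest
  man$calibration <- cohort$calibration
  man$spec <- lapply(unclass(cohort$spec), function(x)
    if (is.data.frame(x)) x else unclass(x))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "rows"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  recs <- sort(list.files(dir, pattern = "_recording\\.(csv|tsv)$"))
  if (length(recs) == 0L) stop("no *_recording.csv files in ", dir)
  subjects <- lapply(recs, function(f) {
    id <- sub("_recording\\.(csv|tsv)$", "", f)
    evf <- file.path(dir, paste0(id, "_events.tsv"))
    if (!file.exists(evf)) stop("missing events file for ", id)
    list(id = id, group = sub("_.*$", "", id),
         recording = read_recording(file.path(dir, f)),
         events = read_events(evf))
  })
  man <- if (file.exists(file.path(dir, "manifest.json")))
    jsonlite::fromJSON(file.path(dir, "manifest.json")) else NULL
  structure(list(spec = NULL, subjects = subjects, manifest = man),
            class = "windfa_cohort")
}

# --- minimal EDF (16-bit, continuous) ---------------------------------------

pad_field <- function(x, width) {
  s <- substr(sprintf("%-*s", width, x), 1, width)
  s
}

#' Minimal EDF writer / reader
#'
#' Continuous 16-bit EDF with one data-record per second and a common
#' sampling rate across channels; physical units are microvolts.  Intended
#' for interchange of synthetic recordings, not as a general EDF
#' implementation.  The recording is truncated to whole seconds.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(rec$samples)
  n_rec <- nrow(rec$samples) %/% fs
  if (n_rec < 1) stop("recording shorter than one data record (1 s)")
  X <- rec$samples[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(X, 2, min); pmax_ <- apply(X, 2, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X synthetic windfa EDF", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (l in rec$channel_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("synthetic EEG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmin_[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmax_[i]), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((X[rows, i] - pmin_[i]) / scale[i]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @return `read_edf` returns an `eeg_recording` (values in microvolts).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!is.finite(n_rec) || !is.finite(ns) || ns < 1)
    stop("malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp)) != 1L)
    stop("EDF reader supports a common sampling rate only")
  fs <- nsamp[1] / dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  X <- matrix(0, n_rec * nsamp[1], ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * nsamp[1] + 1):(r * nsamp[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[i], size = 2, endian = "little")
      X[rows, i] <- pmin_[i] + (dig - dmin[i]) * scale[i]
    }
  }
  eeg_recording(X, fs, labels)
}
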