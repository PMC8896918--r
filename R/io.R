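#' Read one Bonn-layout EEG segment file
#'
#' Bonn-layout files are plain ASCII, one numeric sample per line (the
#' published benchmark distributes 4096-line files, digitized at 173.61 Hz).
#' Trailing whitespace and a final blank line are tolerated; any other
#' non-numeric content is an error naming the offending line.
#'
#' @param path Path to the segment file.
#' @param fs Sampling frequency in Hz. The files carry no header, so the
#'   caller must supply it (173.61 for Bonn-style data).
#' @param set_label Set label to attach (`"A"`..`"E"` for Bonn sets).
#' @return An [eeg_signal] with samples in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("12", "-7", "3"), f)
#' read_bonn_segment(f, fs = 173.61, set_label = "A")
read_bonn_segment <- function(path, fs, set_label = NA_character_) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) stop("segment file is empty: ", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1]]
    stop("non-numeric sample on line ", bad, " of ", path, ": '",
         trimws(lines[bad]), "'")
  }
  eeg_signal(vals, fs = fs, source_id = basename(path), set_label = set_label)
}

#' Load a directory of Bonn-layout segments as one labeled set
#'
#' Reads every regular file in `dir` (lexicographic order, so load order is
#' deterministic across runs) as a Bonn-layout segment and tags all of them
#' with one set label.
#'
#' @param dir Directory containing segment files.
#' @inheritParams read_bonn_segment
#' @param pattern Optional regular expression restricting which file names
#'   are read (default: all files).
#' @return A [labeled_dataset] with one signal per file.
#' @export
load_set_directory <- function(dir, set_label, fs, pattern = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no segment files in directory: ", dir)
  signals <- lapply(files, function(f) {
    tryCatch(
      read_bonn_segment(f, fs = fs, set_label = set_label),
      error = function(e) stop("failed reading '", f, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  labeled_dataset(signals)
}

#' Write a signal (or dataset) to Bonn-layout ASCII
#'
#' One sample per line, full double precision (`%.17g`) so that a written
#' signal re-reads bit-identically. For a dataset, one file per signal named
#' `<set_label><index>.txt` is written into `path`.
#'
#' @param x An [eeg_signal] or [labeled_dataset].
#' @param path Output file ([eeg_signal]) or directory ([labeled_dataset]).
#' @return The path(s) written, invisibly.
#' @export
write_bonn_layout <- function(x, path) {
  if (inherits(x, "eeg_signal")) {
    writeLines(sprintf("%.17g", x$samples), path)
    return(invisible(path))
  }
  if (inherits(x, "labeled_dataset")) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    labs <- set_labels(x)
    idx <- as.integer(stats::ave(seq_along(labs), labs, FUN = seq_along))
    out <- file.path(path, sprintf("%s%03d.txt", labs, idx))
    for (i in seq_along(x$signals)) {
      writeLines(sprintf("%.17g", x$signals[[i]]$samples), out[i])
    }
    return(invisible(out))
  }
  stop("x must be an eeg_signal or labeled_dataset")
}

#' Read a clinical-style multichannel CSV recording
#'
#' Thin adapter for clinical-style exports: one column per channel, one row
#' per time point, with a header row of channel names. Yields one
#' [eeg_signal] per channel; montage and referencing are out of scope.
#'
#' @param path CSV file path.
#' @param fs Sampling frequency in Hz (commonly 256 for clinical EEG).
#' @param set_label Label attached to every channel signal.
#' @return A [labeled_dataset] with one signal per channel.
#' @export
read_multichannel_csv <- function(path, fs, set_label = NA_character_) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 0L || nrow(df) < 2L) stop("CSV has no usable channel data: ", path)
  signals <- lapply(seq_len(ncol(df)), function(j) {
    v <- df[[j]]
    if (!is.numeric(v)) stop("channel '", names(df)[j], "' is not numeric")
    eeg_signal(v, fs = fs,
               source_id = paste0(basename(path), ":", names(df)[j]),
               set_label = set_label)
  })
  labeled_dataset(signals)
}

#' Read an EDF (European Data Format) recording
#'
#' Minimal EDF reader for the thin multichannel adapter: parses the fixed
#' 256-byte header plus per-signal headers, decodes the 16-bit little-endian
#' data records, and applies the per-channel physical calibration
#' `(physical range)/(digital range)`. Annotation channels
#' (`EDF Annotations`) are skipped. Discontinuous (EDF+D) files and
#' per-channel sampling rates other than a common one are not supported.
#'
#' @param path EDF file path.
#' @param set_label Label attached to every channel signal.
#' @return A [labeled_dataset] with one signal per data channel; the
#'   sampling frequency is taken from the file header.
#' @export
read_edf <- function(path, set_label = NA_character_) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  if (version != "0") stop("not an EDF file (version field '", version, "'): ", path)
  hdr_txt(80); hdr_txt(80); hdr_txt(8); hdr_txt(8)   # patient, recording, date, time
  hdr_txt(8)                                          # header byte count
  hdr_txt(44)                                         # reserved
  n_records <- as.integer(hdr_txt(8))
  record_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1L) stop("EDF header reports no signals: ", path)
  field <- function(width) vapply(seq_len(ns), function(i) hdr_txt(width), character(1))
  labels <- field(16)
  field(80); field(8)                                 # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                           # prefiltering
  nsamp <- as.integer(field(8))
  field(32)                                           # reserved
  if (is.na(n_records) || n_records < 1L) stop("EDF file has no data records: ", path)

  chans <- vector("list", ns)
  for (i in seq_len(ns)) chans[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      chans[[i]][[r]] <- readBin(con, "integer", n = nsamp[i], size = 2,
                                 signed = TRUE, endian = "little")
    }
  }
  keep <- which(labels != "EDF Annotations")
  if (length(keep) == 0L) stop("EDF file contains only annotation channels: ", path)
  signals <- lapply(keep, function(i) {
    dig <- unlist(chans[[i]], use.names = FALSE)
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- phys_min[i] + gain * (dig - dig_min[i])
    eeg_signal(phys, fs = nsamp[i] / record_dur,
               source_id = paste0(basename(path), ":", labels[i]),
               set_label = set_label)
  })
  labeled_dataset(signals)
}

#' Write an evaluation results table to CSV
#'
#' Writes one row per evaluation result with the fixed header
#' `case,subband,feature,classifier,accuracy,sensitivity,specificity,ppv,npv,mcc`.
#' Percentages are printed to 2 decimals, MCC to 3, mirroring the layout of
#' published per-case/per-feature benchmark tables.
#'
#' @param results An `eval_grid` (see [grid_evaluate]) or a data frame with
#'   the corresponding columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  df <- as.data.frame(results)
  if (nrow(df) == 0L) stop("results table is empty; nothing to write")
  need <- c("case", "subband", "feature", "classifier", "accuracy",
            "sensitivity", "specificity", "ppv", "npv", "mcc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("results are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  fmt_pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  out <- data.frame(
    case = df$case, subband = df$subband, feature = df$feature,
    classifier = df$classifier,
    accuracy = fmt_pct(df$accuracy), sensitivity = fmt_pct(df$sensitivity),
    specificity = fmt_pct(df$specificity), ppv = fmt_pct(df$ppv),
    npv = fmt_pct(df$npv),
    mcc = ifelse(is.na(df$mcc), "NA", sprintf("%.3f", df$mcc)),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
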