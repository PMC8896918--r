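#' Construct an EEG signal object
#'
#' A signal is one single-channel EEG segment: an ordered numeric vector of
#' amplitudes (conventionally microvolts) together with its sampling
#' frequency and provenance labels.
#'
#' @param samples Numeric vector of amplitudes, length >= 2, all finite.
#' @param fs Sampling frequency in Hz (positive scalar). The Bonn benchmark
#'   uses 173.61 Hz; clinical-style multichannel recordings typically 256 Hz.
#' @param source_id Character scalar identifying the segment (e.g. file name).
#' @param set_label Optional character label: one of the Bonn set names
#'   `"A"`..`"E"` or a synthetic class name such as `"H"`/`"S"`/`"I"`.
#'
#' @return An object of class `eeg_signal`: a list with elements `samples`,
#'   `fs`, `source_id`, `set_label`.
#' @export
#' @examples
#' s <- eeg_signal(sin(seq_len(256) / 10), fs = 173.61, source_id = "demo")
#' s
eeg_signal <- function(samples, fs, source_id = "", set_label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("an EEG signal needs at least 2 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) {
    stop("signal '", source_id, "' contains non-finite samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive finite scalar (Hz)")
  }
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      source_id = as.character(source_id),
      set_label = as.character(set_label)
    ),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf(
    "<eeg_signal> %s: %d samples @ %.5g Hz (%.2f s)%s\n",
    if (nzchar(x$source_id)) x$source_id else "(unnamed)",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    if (!is.na(x$set_label)) paste0(", set ", x$set_label) else ""
  ))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

#' Construct a labeled dataset of EEG signals
#'
#' Bundles signals (all sharing one sampling frequency, each carrying a set
#' label) for feature extraction and classification.
#'
#' @param signals List of [eeg_signal] objects, each with a non-missing
#'   `set_label`.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `signals` and `fs`.
#' @export
labeled_dataset <- function(signals) {
  if (!is.list(signals) || length(signals) == 0L) {
    stop("signals must be a non-empty list of eeg_signal objects")
  }
  ok <- vapply(signals, inherits, logical(1), what = "eeg_signal")
  if (!all(ok)) stop("element ", which(!ok)[1], " is not an eeg_signal")
  labs <- vapply(signals, function(s) s$set_label, character(1))
  if (anyNA(labs)) {
    stop("every signal in a labeled dataset must carry a set_label; signal ",
         which(is.na(labs))[1], " has none")
  }
  fss <- vapply(signals, function(s) s$fs, numeric(1))
  if (length(unique(fss)) != 1L) {
    stop("all signals in a dataset must share one sampling frequency; found: ",
         paste(unique(fss), collapse = ", "))
  }
  structure(list(signals = signals, fs = fss[1]), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  labs <- set_labels(x)
  tab <- table(labs)
  cat(sprintf("<labeled_dataset> %d signals @ %.5g Hz\n", length(x$signals), x$fs))
  cat("  per set:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$signals)

#' Set labels of a labeled dataset
#'
#' @param dataset A [labeled_dataset].
#' @return Character vector of per-signal set labels.
#' @export
set_labels <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  vapply(dataset$signals, function(s) s$set_label, character(1))
}
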