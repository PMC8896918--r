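#' Specification for the synthetic EEG generator
#'
#' Describes a seeded generator of class-separable EEG-like segments:
#' a band-limited background rhythm plus 1/f-shaped noise ("H", healthy-like),
#' and the same background overlaid with high-amplitude low-frequency
#' spike-wave discharges ("S", seizure-like). An optional third class "I"
#' (interictal-like) adds sporadic isolated spikes of intermediate amplitude
#' at `spike_rate` events per second.
#'
#' Defaults emulate a Bonn-style benchmark: 100 segments per class of 4096
#' samples at 173.61 Hz, an 8-13 Hz alpha-band background of ~50 uV, and
#' 2.5-5 Hz spike-wave discharges of ~300 uV (inside the level-5 detail band
#' at this sampling rate, where seizure energy concentrates).
#'
#' @param n_segments_per_class Segments per class (default 100).
#' @param segment_length Samples per segment (default 4096, >= 64 and
#'   divisible by 32 so a 5-level periodized DWT applies).
#' @param fs Sampling frequency in Hz (default 173.61).
#' @param background_band `c(lo, hi)` Hz of the background rhythm
#'   (default 8-13 Hz).
#' @param background_amp Background rhythm amplitude in uV (default 50).
#' @param seizure_freq_band `c(lo, hi)` Hz of the spike-wave discharge
#'   repetition frequency (default 2.5-5 Hz).
#' @param seizure_amp Spike-wave amplitude in uV (default 300).
#' @param spike_rate Isolated-spike event rate (events/s) for the optional
#'   interictal class (default 1).
#' @param noise_sd Standard deviation of the 1/f-shaped noise in uV
#'   (default 10).
#' @param seed Integer base seed; every segment is reproducible in
#'   isolation from `(seed, class, index)`.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_segments_per_class = 100L,
                       segment_length = 4096L,
                       fs = 173.61,
                       background_band = c(8, 13),
                       background_amp = 50,
                       seizure_freq_band = c(2.5, 5),
                       seizure_amp = 300,
                       spike_rate = 1,
                       noise_sd = 10,
                       seed = 1L) {
  spec <- list(
    n_segments_per_class = as.integer(n_segments_per_class),
    segment_length = as.integer(segment_length),
    fs = as.numeric(fs),
    background_band = as.numeric(background_band),
    background_amp = as.numeric(background_amp),
    seizure_freq_band = as.numeric(seizure_freq_band),
    seizure_amp = as.numeric(seizure_amp),
    spike_rate = as.numeric(spike_rate),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop("not a synth_spec")
  with(spec, {
    if (n_segments_per_class < 1L) stop("n_segments_per_class must be >= 1")
    if (segment_length < 64L) stop("segment_length must be >= 64")
    if (fs <= 0) stop("fs must be positive")
    for (band in list(background_band, seizure_freq_band)) {
      if (length(band) != 2L || !(0 < band[1]) || !(band[1] < band[2]) ||
          !(band[2] < fs / 2)) {
        stop("frequency bands must satisfy 0 < lo < hi < fs/2; got (",
             paste(band, collapse = ", "), ") at fs = ", fs)
      }
    }
    if (background_amp < 0 || seizure_amp < 0 || spike_rate < 0 ||
        noise_sd < 0) {
      stop("amplitudes, spike_rate and noise_sd must be >= 0")
    }
  })
  invisible(spec)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<synth_spec> %d segments/class, %d samples @ %.5g Hz\n",
           "  background %.3g uV in %.3g-%.3g Hz; seizure %.3g uV at ",
           "%.3g-%.3g Hz; noise sd %.3g uV; seed %d\n"),
    x$n_segments_per_class, x$segment_length, x$fs,
    x$background_amp, x$background_band[1], x$background_band[2],
    x$seizure_amp, x$seizure_freq_band[1], x$seizure_freq_band[2],
    x$noise_sd, x$seed))
  invisible(x)
}

# Derive a per-segment seed from (base seed, class, index) so each segment
# has its own reproducible pseudo-random stream. Kept below 2^31.
segment_seed <- function(seed, class_code, index) {
  s <- (as.double(seed) * 48271 + class_code * 69621 + index * 16807)
  as.integer(s %% 2147483587) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1/f-shaped ("pink") Gaussian noise rescaled to a target SD.
pink_noise <- function(n, sd_target) {
  if (sd_target == 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))               # avoid dividing the DC bin by 0
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  s <- stats::sd(shaped)
  if (s == 0) return(numeric(n))
  shaped * (sd_target / s)
}

# One spike-wave complex sampled on t in [0, 1) of its period: a sharp
# biphasic spike followed by a slow half-sine wave, zero-mean-ish and
# normalized to unit peak.
spike_wave_shape <- function(phase) {
  spike <- exp(-((phase - 0.12) / 0.025)^2) - 0.5 * exp(-((phase - 0.18) / 0.05)^2)
  wave <- 0.55 * sin(pi * pmin(pmax((phase - 0.25) / 0.6, 0), 1))
  spike + wave
}

generate_one <- function(spec, index, class_code) {
  validate_synth_spec(spec)
  n <- spec$segment_length
  with_local_seed(segment_seed(spec$seed, class_code, index), {
    t <- (seq_len(n) - 1) / spec$fs
    f_bg <- stats::runif(1, spec$background_band[1], spec$background_band[2])
    phase <- stats::runif(1, 0, 2 * pi)
    x <- spec$background_amp * sin(2 * pi * f_bg * t + phase) +
      pink_noise(n, spec$noise_sd)
    if (class_code == 2L) {                # seizure: periodic spike-wave train
      f_sz <- stats::runif(1, spec$seizure_freq_band[1],
                           spec$seizure_freq_band[2])
      ph0 <- stats::runif(1)
      x <- x + spec$seizure_amp * spike_wave_shape((t * f_sz + ph0) %% 1)
    } else if (class_code == 3L) {         # interictal: sporadic spikes
      n_ev <- stats::rpois(1, spec$spike_rate * n / spec$fs)
      if (n_ev > 0) {
        centers <- stats::runif(n_ev, 0, n / spec$fs)
        amp <- (spec$background_amp + spec$seizure_amp) / 2
        for (c0 in centers) {
          x <- x + amp * exp(-((t - c0) / 0.03)^2)
        }
      }
    }
    x
  })
}

#' Generate one background (healthy-like) synthetic segment
#'
#' A band-limited sinusoidal rhythm (frequency and phase drawn per segment
#' from `background_band`) plus 1/f-shaped Gaussian noise scaled to
#' `noise_sd`. Deterministic given `(spec$seed, index)`.
#'
#' @param spec A [synth_spec].
#' @param index Segment index (1-based) within the class.
#' @return An [eeg_signal] with `set_label = "H"`.
#' @export
generate_background <- function(spec, index = 1L) {
  eeg_signal(generate_one(spec, index, 1L), fs = spec$fs,
             source_id = sprintf("synthH%03d", index), set_label = "H")
}

#' Generate one seizure-like synthetic segment
#'
#' Background as in [generate_background] plus a periodic spike-wave
#' discharge: biphasic sharp transients followed by a slow wave, repeating
#' at a frequency drawn from `seizure_freq_band` (default 2.5-5 Hz) with
#' amplitude `seizure_amp`. Deterministic given `(spec$seed, index)`.
#'
#' @inheritParams generate_background
#' @return An [eeg_signal] with `set_label = "S"`.
#' @export
generate_seizure <- function(spec, index = 1L) {
  eeg_signal(generate_one(spec, index, 2L), fs = spec$fs,
             source_id = sprintf("synthS%03d", index), set_label = "S")
}

#' Generate one interictal-like synthetic segment
#'
#' Background plus sporadic isolated spikes (Poisson events at
#' `spike_rate`/s) of intermediate amplitude — the optional third class for
#' three-class experiments.
#'
#' @inheritParams generate_background
#' @return An [eeg_signal] with `set_label = "I"`.
#' @export
generate_interictal <- function(spec, index = 1L) {
  eeg_signal(generate_one(spec, index, 3L), fs = spec$fs,
             source_id = sprintf("synthI%03d", index), set_label = "I")
}

#' Generate a labeled synthetic dataset
#'
#' `n_segments_per_class` segments per class. Two-class mode yields labels
#' `"H"` and `"S"`; three-class mode adds the interictal `"I"` class.
#'
#' @param spec A [synth_spec].
#' @param classes Character vector of class labels to generate, a subset of
#'   `c("H", "I", "S")` (default `c("H", "S")`).
#' @return A [labeled_dataset].
#' @export
#' @examples
#' ds <- generate_dataset(synth_spec(n_segments_per_class = 3,
#'                                   segment_length = 512))
#' length(ds)  # 6
generate_dataset <- function(spec, classes = c("H", "S")) {
  validate_synth_spec(spec)
  if (!all(classes %in% c("H", "I", "S")) || anyDuplicated(classes)) {
    stop("classes must be distinct labels from H, I, S")
  }
  gens <- list(H = generate_background, I = generate_interictal,
               S = generate_seizure)
  signals <- list()
  for (cl in classes) {
    for (i in seq_len(spec$n_segments_per_class)) {
      signals[[length(signals) + 1L]] <- gens[[cl]](spec, i)
    }
  }
  labeled_dataset(signals)
}
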