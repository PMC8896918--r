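# Daubechies-4 (8-tap, 4 vanishing moments) orthonormal scaling filter.
# The high-pass quadrature mirror filter is derived as g[n] = (-1)^n h[L-1-n].
DB4_LO <- c(
   0.2303778133088965,
   0.7148465705529157,
   0.6308807679298589,
  -0.027983769416859854,
  -0.18703481171909309,
   0.030841381835560764,
   0.0328830116668852,
  -0.010597401785069032
)

db4_filters <- function() {
  h <- DB4_LO
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(lo = h, hi = g)
}

# One analysis step of the periodized orthogonal filter bank:
# a[k] = sum_n h[n] x[(2k + n) mod N], likewise d with the high-pass filter.
# Circular (periodic) extension keeps the transform orthonormal, so
# coefficient counts halve exactly and energy is conserved.
dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L != 0L) stop("periodized DWT step needs an even-length input, got ", n)
  half <- n / 2L
  starts <- 2L * (seq_len(half) - 1L)         # 0-based start of each window
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_along(filt$lo)) {
    idx <- (starts + (k - 1L)) %% n + 1L
    a <- a + filt$lo[k] * x[idx]
    d <- d + filt$hi[k] * x[idx]
  }
  list(approx = a, detail = d)
}

# Transpose of dwt_step (exact inverse, since the transform is orthonormal):
# x[m] = sum_k a[k] h[(m - 2k) mod N] + d[k] g[(m - 2k) mod N].
idwt_step <- function(approx, detail, filt) {
  half <- length(approx)
  if (length(detail) != half) {
    stop("approximation and detail lengths differ (", half, " vs ",
         length(detail), ")")
  }
  n <- 2L * half
  x <- numeric(n)
  starts <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(filt$lo)) {
    idx <- (starts + (k - 1L)) %% n + 1L
    contrib <- filt$lo[k] * approx + filt$hi[k] * detail
    # accumulate; idx values are distinct within one k (stride-2 shifts)
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Decompose an EEG signal into DWT subbands
#'
#' Runs a multi-level discrete wavelet transform with the Daubechies-4
#' quadrature-mirror filter pair and periodic (circular) boundary handling.
#' Each level splits its input into a half-length approximation (low-pass)
#' and detail (high-pass) band; the approximation is split again at the next
#' level. A 5-level decomposition of a 4096-sample Bonn segment yields the
#' six subbands D1 (2048), D2 (1024), D3 (512), D4 (256), D5 (128) and
#' A5 (128) coefficients.
#'
#' Periodization is used because it keeps the filter bank orthonormal:
#' coefficient counts halve exactly at every level, reconstruction is exact
#' and total energy is conserved (Parseval). Signals are used raw; no
#' detrending or normalization is applied first.
#'
#' @param signal An [eeg_signal] (or bare numeric vector, in which case `fs`
#'   must be given).
#' @param levels Decomposition depth (default 5).
#' @param wavelet Wavelet name; only `"db4"` is provided.
#' @param boundary_mode Boundary handling; only `"periodization"` is provided.
#' @param fs Sampling frequency, required when `signal` is a bare vector.
#' @return An object of class `subband_decomposition`: list with
#'   `coefficients` (named list `D1`..`D<levels>`, `A<levels>`), `bands`
#'   (named list of `(lo, hi)` Hz, see [subband_bands]), `fs`,
#'   `wavelet_name`, `boundary_mode`, and `n` (original signal length).
#' @export
#' @examples
#' x <- eeg_signal(rnorm(512), fs = 173.61)
#' d <- dwt_decompose(x)
#' lengths(d$coefficients)
dwt_decompose <- function(signal, levels = 5L, wavelet = "db4",
                          boundary_mode = "periodization", fs = NULL) {
  if (inherits(signal, "eeg_signal")) {
    x <- signal$samples
    fs <- signal$fs
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("fs must be supplied when signal is a bare vector")
  }
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (!identical(wavelet, "db4")) {
    stop("only the db4 wavelet is provided (requested '", wavelet, "')")
  }
  if (!identical(boundary_mode, "periodization")) {
    stop("only periodization boundary handling is provided (requested '",
         boundary_mode, "')")
  }
  n <- length(x)
  max_depth <- 0L
  m <- n
  while (m %% 2L == 0L && m >= 2L) { max_depth <- max_depth + 1L; m <- m / 2L }
  if (n < 2^levels || max_depth < levels) {
    stop("signal of length ", n, " supports at most ", max_depth,
         " periodized decomposition level(s); requested ", levels)
  }
  filt <- db4_filters()
  coefs <- vector("list", levels + 1L)
  names(coefs) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  approx <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(approx, filt)
    coefs[[paste0("D", j)]] <- st$detail
    approx <- st$approx
  }
  coefs[[paste0("A", levels)]] <- approx
  structure(
    list(
      coefficients = coefs,
      bands = subband_bands(fs, levels),
      fs = fs,
      wavelet_name = wavelet,
      boundary_mode = boundary_mode,
      n = n
    ),
    class = "subband_decomposition"
  )
}

#' @export
print.subband_decomposition <- function(x, ...) {
  cat(sprintf("<subband_decomposition> %s, %s, %d-sample input @ %.5g Hz\n",
              x$wavelet_name, x$boundary_mode, x$n, x$fs))
  for (nm in names(x$coefficients)) {
    b <- x$bands[[nm]]
    cat(sprintf("  %-3s %4d coefficients, %.2f-%.2f Hz\n",
                nm, length(x$coefficients[[nm]]), b[1], b[2]))
  }
  invisible(x)
}

#' Nominal frequency band of each DWT subband
#'
#' At sampling frequency `fs`, level-`j` detail coefficients cover
#' `(fs/2^(j+1), fs/2^j)` Hz and the final approximation covers
#' `(0, fs/2^(levels+1))` Hz. At the Bonn rate of 173.61 Hz and 5 levels
#' this gives D1 43.40-86.80, D2 21.70-43.40, D3 10.85-21.70,
#' D4 5.43-10.85, D5 2.71-5.43 and A5 0-2.71 Hz. Values are returned at
#' full precision; round for display.
#'
#' @param fs Sampling frequency in Hz.
#' @param levels Decomposition depth.
#' @return Named list `D1`..`D<levels>`, `A<levels>` of numeric `c(lo, hi)`
#'   band edges in Hz; bands are contiguous and nested so that
#'   `A<levels>` and `D<levels>`..`D1` tile `(0, fs/2]`.
#' @export
#' @examples
#' lapply(subband_bands(173.61, 5), round, 2)
subband_bands <- function(fs, levels) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  for (j in seq_len(levels)) {
    out[[paste0("D", j)]] <- c(fs / 2^(j + 1), fs / 2^j)
  }
  out[[paste0("A", levels)]] <- c(0, fs / 2^(levels + 1))
  out
}

#' Reconstruct a signal from its subband decomposition
#'
#' Inverts [dwt_decompose] by running the synthesis filter bank from the
#' deepest approximation upward. Because the periodized db4 bank is
#' orthonormal the reconstruction is exact to floating-point round-off.
#'
#' @param decomp A `subband_decomposition` produced by [dwt_decompose].
#' @return Numeric vector of reconstructed samples (length `decomp$n`).
#' @export
dwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "subband_decomposition"))
  coefs <- decomp$coefficients
  levels <- length(coefs) - 1L
  filt <- db4_filters()
  approx <- coefs[[paste0("A", levels)]]
  for (j in rev(seq_len(levels))) {
    detail <- coefs[[paste0("D", j)]]
    if (length(detail) != length(approx)) {
      stop("inconsistent coefficient lengths at level ", j, ": A has ",
           length(approx), ", D", j, " has ", length(detail))
    }
    approx <- idwt_step(approx, detail, filt)
  }
  approx
}
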