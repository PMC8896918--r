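# Independent brute-force oracles used to pin the implementation.

# Pincus approximate entropy by direct template counting: build the
# (N - m + 1) x m template matrix and count, for every template, how many
# templates (self included) lie within Chebyshev distance r.
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1L
    tmpl <- matrix(0, nt, mm)
    for (i in seq_len(nt)) tmpl[i, ] <- x[i:(i + mm - 1L)]
    counts <- vapply(seq_len(nt), function(i) {
      diffs <- abs(sweep(tmpl, 2, tmpl[i, ], "-"))
      sum(apply(diffs, 1, max) <= r)
    }, numeric(1))
    mean(log(counts / nt))
  }
  phi(m) - phi(m + 1L)
}

# Single-level periodized DWT by explicit construction of the orthogonal
# analysis matrix from stride-2 circular shifts of the db4 filter pair.
dwt1_oracle <- function(x) {
  h <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
         -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
         0.0328830116668852, -0.010597401785069032)
  g <- (-1)^(seq_along(h) - 1) * rev(h)
  n <- length(x)
  half <- n / 2L
  row_for <- function(filt, k) {
    r <- numeric(n)
    pos <- ((2L * (k - 1L) + seq_along(filt) - 1L) %% n) + 1L
    for (j in seq_along(filt)) r[pos[j]] <- r[pos[j]] + filt[j]
    r
  }
  A <- t(vapply(seq_len(half), function(k) row_for(h, k), numeric(n)))
  D <- t(vapply(seq_len(half), function(k) row_for(g, k), numeric(n)))
  list(approx = as.numeric(A %*% x), detail = as.numeric(D %*% x))
}

# Shannon entropy of a given probability vector by direct summation.
entropy_oracle <- function(p) {
  tot <- 0
  for (pi in p) if (pi > 0) tot <- tot - pi * log(pi, base = 2)
  tot
}

# Small, fast synthetic spec for unit tests.
tiny_spec <- function(n = 6L, len = 512L, seed = 11L, ...) {
  synth_spec(n_segments_per_class = n, segment_length = len, seed = seed, ...)
}

# Dominant periodogram frequency (Hz) of a signal, by direct DFT.
peak_frequency <- function(sig) {
  x <- sig$samples - mean(sig$samples)
  n <- length(x)
  pw <- Mod(stats::fft(x))[2:floor(n / 2)]^2
  freqs <- (seq_len(floor(n / 2) - 1)) * sig$fs / n
  freqs[which.max(pw)]
}
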