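# Independent brute-force oracles used across test files. These deliberately
# use naive loops and base building blocks only, so they stay independent of
# the vectorized implementation paths they check.

# Literal triple-loop index-correlation map: for each unordered band pair,
# compute the normalized-difference index sample by sample, then cor.test.
brute_force_map <- function(S, y) {
  k <- ncol(S)
  n <- nrow(S)
  r <- matrix(NA_real_, k, k)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      v <- numeric(n)
      bad <- FALSE
      for (s in seq_len(n)) {
        den <- S[s, i] + S[s, j]
        if (!is.finite(den) || den <= 1e-9) { bad <- TRUE; break }
        v[s] <- (S[s, i] - S[s, j]) / den
      }
      if (bad || stats::sd(v) == 0) next
      ct <- suppressWarnings(stats::cor.test(v, y))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

# Naive Kennard-Stone max-min selection with explicit loops.
brute_force_ks <- function(X, k) {
  n <- nrow(X)
  d <- function(a, b) sqrt(sum((X[a, ] - X[b, ])^2))
  best <- c(1L, 2L); bestd <- -1
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (d(a, b) > bestd + 1e-12) { bestd <- d(a, b); best <- c(a, b) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    pick <- NA; pickd <- -1
    for (cc in cand) {
      dm <- min(vapply(sel, function(s) d(cc, s), 1))
      if (dm > pickd + 1e-12) { pickd <- dm; pick <- cc }
    }
    sel <- c(sel, pick)
  }
  sort(sel)
}

# Small spectra matrix with wavelength attribute for direct engine tests.
random_spectra_matrix <- function(n, wavelengths, seed) {
  set.seed(seed)
  S <- matrix(stats::runif(n * length(wavelengths), 0.05, 0.6),
              n, length(wavelengths))
  attr(S, "wavelength") <- wavelengths
  S
}

# tiny config for fast tests
tiny_config <- function(seed = 1, ...) {
  generator_config(seed = seed, cube_shape = c(24, 24), ...)
}

# config with every stochastic term silenced
silent_config <- function(seed = 1, ...) {
  generator_config(seed = seed, noise_sd_additive = 0,
                   noise_sd_multiplicative = 0, proxy_jitter_sd = 0,
                   structure_sd = 0, brightness_sd = 0,
                   spectral_texture_sd = 0,
                   cube_shape = c(24, 24), ...)
}
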