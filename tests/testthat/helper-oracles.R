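# Independent brute-force oracles, deliberately kept naive and separate
# from the implementation paths they check.

# Textbook Pearson correlation, written out term by term.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Cosine similarity computed by explicitly constructing the merged m/z
# axis: pool all m/z values of both spectra, split into bins wherever the
# ascending gap exceeds tol, sum each spectrum's intensity per bin, then
# take the cosine of the two binned vectors.
brute_cosine_merged_axis <- function(u, v, tol) {
  mz <- c(u$mz, v$mz)
  src <- rep(1:2, c(nrow(u), nrow(v)))
  int <- c(u$intensity, v$intensity)
  o <- order(mz)
  mz <- mz[o]; src <- src[o]; int <- int[o]
  bin <- cumsum(c(1, diff(mz) > tol))
  nb <- max(bin)
  vu <- vv <- numeric(nb)
  for (k in seq_along(mz)) {
    if (src[k] == 1) vu[bin[k]] <- vu[bin[k]] + int[k]
    else vv[bin[k]] <- vv[bin[k]] + int[k]
  }
  sum(vu * vv) / sqrt(sum(vu^2) * sum(vv^2))
}

# Random centroided stick spectrum with well-separated peaks.
random_spectrum <- function(n, mz_range = c(100, 500), min_gap = 0.05) {
  repeat {
    mz <- sort(runif(n, mz_range[1], mz_range[2]))
    if (n < 2 || min(diff(mz)) > min_gap) break
  }
  peaklist(mz, runif(n, 1, 100))
}

# Pair of spectra sharing some aligned peaks (within jitter << tol) plus
# unshared peaks on either side.
random_aligned_pair <- function(n_shared, n_only, tol) {
  base <- random_spectrum(n_shared + 2 * n_only)
  shared_idx <- sample(nrow(base), n_shared)
  rest <- setdiff(seq_len(nrow(base)), shared_idx)
  ua <- rest[seq_len(n_only)]
  va <- rest[n_only + seq_len(n_only)]
  u <- peaklist(c(base$mz[shared_idx] + runif(n_shared, -tol / 4, tol / 4),
                  base$mz[ua]),
                runif(n_shared + n_only, 1, 100))
  v <- peaklist(c(base$mz[shared_idx], base$mz[va]),
                runif(n_shared + n_only, 1, 100))
  list(u = u, v = v)
}

# Noise-free two-isobar simulation used by several suites.
clean_preset <- function(delta_mz, seed = 1, ...) {
  two_isobar_preset(delta_mz, noise_sd_rel = 0, noise_floor_rel = 0,
                    isotopologue_abundance = 0, shared_fragment = FALSE,
                    blank = FALSE, seed = seed, ...)
}
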