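#' Align a reconstructed spectrum with a reference spectrum
#'
#' Greedy one-to-one matching of reconstructed peaks to reference peaks by
#' ascending absolute m/z difference, capped at `tol` (default 3 mDa, the
#' maximum allowed mass error between theoretical and measured m/z).
#' Reference m/z values are the theoretical ones when available.
#'
#' @param recon a [reconstructed_spectrum()] (or plain peak list).
#' @param ref a [reference_spectrum()] (or plain peak list).
#' @param tol absolute m/z tolerance in Th (default 0.003).
#' @return an object of class `aligned_pair`: `matched` (data frame with
#'   `ref_mz`, `ref_intensity`, `recon_mz`, `recon_intensity`, `delta`),
#'   `unmatched_ref`, `unmatched_recon`, `tol`.
#' @export
align_spectra <- function(recon, ref, tol = 0.003) {
  rp <- spectrum_peaks(recon)
  fp <- spectrum_peaks(ref)
  if (!nrow(rp) || !nrow(fp))
    stop("align_spectra: both spectra must be non-empty")
  ref_mz <- if ("mz_theo" %in% names(fp)) fp$mz_theo else fp$mz
  m <- match_peaks_greedy(ref_mz, rp$mz, tol)
  matched <- data.frame(
    ref_mz = ref_mz[m[, "a"]], ref_intensity = fp$intensity[m[, "a"]],
    recon_mz = rp$mz[m[, "b"]], recon_intensity = rp$intensity[m[, "b"]])
  matched$delta <- matched$recon_mz - matched$ref_mz
  structure(
    list(matched = matched,
         unmatched_ref = fp[setdiff(seq_len(nrow(fp)), m[, "a"]), ,
                            drop = FALSE],
         unmatched_recon = rp[setdiff(seq_len(nrow(rp)), m[, "b"]), ,
                              drop = FALSE],
         tol = tol),
    class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "<aligned_pair> %d matched, %d ref-only, %d recon-only (tol %.4g Th)\n",
    nrow(x$matched), nrow(x$unmatched_ref), nrow(x$unmatched_recon), x$tol))
  invisible(x)
}

#' Recalibrate a reconstructed spectrum against theoretical m/z
#'
#' The median relative (ppm) offset of all matched peak pairs is removed
#' from every reconstructed m/z, transferring the reference library's
#' formula-derived mass accuracy onto the reconstruction before similarity
#' scoring.
#'
#' @param recon the [reconstructed_spectrum()] to recalibrate.
#' @param aligned its [align_spectra()] result against the reference.
#' @return the recalibrated `reconstructed_spectrum` (flag set).
#' @export
recalibrate <- function(recon, aligned) {
  stopifnot(inherits(aligned, "aligned_pair"))
  if (!nrow(aligned$matched))
    stop("recalibrate: no matched peaks to estimate the offset from")
  ppm <- (aligned$matched$recon_mz - aligned$matched$ref_mz) /
    aligned$matched$ref_mz * 1e6
  off <- stats::median(ppm)
  recon$peaks$mz <- recon$peaks$mz / (1 + off * 1e-6)
  if (!is.na(recon$precursor_mz))
    recon$precursor_mz <- recon$precursor_mz / (1 + off * 1e-6)
  recon$recalibrated <- TRUE
  recon
}

#' Cosine similarity of two spectra on a shared m/z axis
#'
#' Peaks of the two spectra are aligned greedily at `tol` (default 0.2 mDa,
#' appropriate after recalibration); unmatched peaks contribute zero to the
#' other spectrum's intensity vector. The score is the cosine
#' `<u,v> / sqrt(<u,u> <v,v>)` of the aligned intensity vectors, in
#' \[0, 1\] for non-negative intensities; it is symmetric and invariant to
#' scaling either spectrum.
#'
#' @param u,v spectra (any of the package's spectrum classes or plain peak
#'   lists).
#' @param tol absolute alignment tolerance in Th (default 2e-4).
#' @return similarity score in \[0, 1\].
#' @export
#' @examples
#' spectral_similarity(peaklist(c(100, 200), c(3, 4)),
#'                     peaklist(c(100, 200), c(4, 3)))  # 0.96
spectral_similarity <- function(u, v, tol = 2e-4) {
  up <- spectrum_peaks(u)
  vp <- spectrum_peaks(v)
  if (!nrow(up) || !nrow(vp))
    stop("spectral_similarity: both spectra must be non-empty")
  # reference spectra match on their theoretical m/z
  u_mz <- if ("mz_theo" %in% names(up)) up$mz_theo else up$mz
  v_mz <- if ("mz_theo" %in% names(vp)) vp$mz_theo else vp$mz
  nu <- sqrt(sum(up$intensity^2))
  nv <- sqrt(sum(vp$intensity^2))
  if (nu == 0 || nv == 0) {
    warning("spectral_similarity: zero-norm spectrum, score 0")
    return(0)
  }
  m <- match_peaks_greedy(u_mz, v_mz, tol)
  dot <- sum(up$intensity[m[, "a"]] * vp$intensity[m[, "b"]])
  dot / (nu * nv)
}

#' Intensity-weighted precision of a reconstruction
#'
#' Fraction of the reconstructed spectrum's total intensity carried by
#' correctly assigned peaks, i.e. peaks matching a reference peak within
#' `tol`. Precision stays high when peaks are merely missing from the
#' reconstruction; it drops only when peaks are assigned that the reference
#' does not contain.
#'
#' @param recon a [reconstructed_spectrum()] (or peak list).
#' @param ref the corresponding [reference_spectrum()].
#' @param tol alignment tolerance in Th (default 0.003).
#' @return precision in \[0, 1\].
#' @export
spectral_precision <- function(recon, ref, tol = 0.003) {
  rp <- spectrum_peaks(recon)
  if (!nrow(rp)) stop("spectral_precision: empty reconstructed spectrum")
  al <- align_spectra(recon, ref, tol = tol)
  sum(al$matched$recon_intensity) / sum(rp$intensity)
}

#' Intensity-weighted recall of a reconstruction
#'
#' Fraction of the reference spectrum's total intensity recovered in the
#' reconstruction (reference intensities weight both numerator and
#' denominator). Extra wrongly assigned peaks in the reconstruction do not
#' lower recall; only reference peaks missing from the reconstruction do.
#'
#' @inheritParams spectral_precision
#' @return recall in \[0, 1\].
#' @export
spectral_recall <- function(recon, ref, tol = 0.003) {
  fp <- spectrum_peaks(ref)
  if (!nrow(fp)) stop("spectral_recall: empty reference spectrum")
  al <- align_spectra(recon, ref, tol = tol)
  sum(al$matched$ref_intensity) / sum(fp$intensity)
}

#' NCE at which the precursor carries half the MS2 signal
#'
#' NCE50 summarises a compound's resistance to fragmentation: the
#' normalised collision energy at which the precursor ion accounts for 50%
#' of the total MS2 signal intensity. Points are sorted by ascending NCE
#' and the first downward crossing of 0.5 is linearly interpolated; a point
#' sitting exactly at 0.5 returns its own NCE.
#'
#' @param nce numeric vector of collision energies.
#' @param precursor_fraction precursor share of total MS2 intensity at each
#'   NCE, in \[0, 1\].
#' @return the interpolated NCE50.
#' @export
#' @examples
#' nce50(c(30, 40), c(0.8, 0.2))  # 35
nce50 <- function(nce, precursor_fraction) {
  if (length(nce) != length(precursor_fraction) || length(nce) < 2L)
    stop("nce50: need >= 2 (nce, fraction) points")
  if (any(precursor_fraction < 0 | precursor_fraction > 1))
    stop("nce50: fractions must be in [0, 1]")
  o <- order(nce)
  x <- nce[o]; f <- precursor_fraction[o]
  exact <- which(f == 0.5)
  for (i in seq_len(length(x) - 1L)) {
    if (f[i] == 0.5) return(x[i])
    if (f[i] > 0.5 && f[i + 1L] <= 0.5)
      return(x[i] + (f[i] - 0.5) / (f[i] - f[i + 1L]) * (x[i + 1L] - x[i]))
  }
  if (f[length(f)] == 0.5) return(x[length(x)])
  stop("nce50: precursor fraction never crosses 0.5 downward in the ",
       "sampled NCE range")
}

#' Max-normalised modulation profile of one template peak
#'
#' @param M an intensity matrix from [build_intensity_matrix()].
#' @param peak_id which row.
#' @return an object of class `modulation_profile`: `peak_id`,
#'   `scan_index`, `rel_intensity` (max = 1).
#' @export
modulation_profile <- function(M, peak_id) {
  if (!peak_id %in% rownames(M)) stop("unknown peak id: ", peak_id)
  prof <- M[peak_id, ]
  if (max(prof) == 0) stop("modulation_profile: all-zero profile")
  structure(
    list(peak_id = peak_id,
         scan_index = as.integer(colnames(M)),
         rel_intensity = unname(prof / max(prof))),
    class = "modulation_profile")
}

as_profile <- function(x) {
  if (inherits(x, "modulation_profile")) return(x)
  x <- as.numeric(x)
  if (max(x) <= 0) stop("profile has no positive intensity")
  structure(list(peak_id = NA_character_,
                 scan_index = seq_along(x) - 1L,
                 rel_intensity = x / max(x)),
            class = "modulation_profile")
}

#' Distance between two modulation profiles
#'
#' The number of scans separating the points where the two max-normalised
#' profiles reach relative intensity `level` (default 0.5), summed over the
#' rising and falling flanks: `|rise_a - rise_b| + |fall_a - fall_b|`. By
#' default rise and fall are the first and last integer scan indices at or
#' above `level`; `interpolate = TRUE` uses fractional linear-interpolated
#' crossings instead.
#'
#' @param a,b profiles: `modulation_profile` objects or plain intensity
#'   vectors (max-normalised internally).
#' @param level relative intensity level of the crossings.
#' @param interpolate use sub-scan linear interpolation of the crossings.
#' @return distance in scans.
#' @export
#' @examples
#' a <- ifelse(0:80 %in% 30:60, 1, 0)
#' b <- ifelse(0:80 %in% 35:65, 1, 0)
#' profile_distance(a, b)  # 10
profile_distance <- function(a, b, level = 0.5, interpolate = FALSE) {
  a <- as_profile(a); b <- as_profile(b)
  crossings <- function(p) {
    r <- p$rel_intensity
    idx <- p$scan_index
    at <- which(r >= level)
    if (!length(at))
      stop("profile_distance: profile never reaches level ", level)
    if (!interpolate) return(c(rise = idx[min(at)], fall = idx[max(at)]))
    i1 <- min(at); i2 <- max(at)
    rise <- if (i1 == 1L) idx[i1] else
      idx[i1 - 1L] + (level - r[i1 - 1L]) / (r[i1] - r[i1 - 1L]) *
        (idx[i1] - idx[i1 - 1L])
    fall <- if (i2 == length(r)) idx[i2] else
      idx[i2] + (r[i2] - level) / (r[i2] - r[i2 + 1L]) *
        (idx[i2 + 1L] - idx[i2])
    c(rise = rise, fall = fall)
  }
  ca <- crossings(a); cb <- crossings(b)
  unname(abs(ca["rise"] - cb["rise"]) + abs(ca["fall"] - cb["fall"]))
}

#' Score one reconstruction against its reference
#'
#' Standard evaluation chain: align at `align_tol` (3 mDa), recalibrate the
#' reconstruction onto the reference's theoretical m/z (unless
#' `recalibrate = FALSE`), then compute cosine similarity at `sim_tol`
#' (0.2 mDa) plus intensity-weighted precision and recall at `align_tol`.
#'
#' @param recon a [reconstructed_spectrum()].
#' @param ref its [reference_spectrum()].
#' @param align_tol alignment/recalibration tolerance in Th.
#' @param sim_tol similarity alignment tolerance in Th.
#' @param recalibrate apply median-ppm recalibration before scoring.
#' @return one-row data frame: `precursor_id`, `similarity`, `precision`,
#'   `recall`, `n_correct`, `n_incorrect`, `n_missing`.
#' @export
evaluate_reconstruction <- function(recon, ref, align_tol = 0.003,
                                    sim_tol = 2e-4, recalibrate = TRUE) {
  al <- align_spectra(recon, ref, tol = align_tol)
  if (recalibrate && nrow(al$matched)) {
    recon <- dims2::recalibrate(recon, al)
    al <- align_spectra(recon, ref, tol = align_tol)
  }
  data.frame(
    precursor_id = if (inherits(recon, "reconstructed_spectrum"))
      recon$precursor_id else NA_character_,
    similarity = spectral_similarity(recon, ref, tol = sim_tol),
    precision = spectral_precision(recon, ref, tol = align_tol),
    recall = spectral_recall(recon, ref, tol = align_tol),
    n_correct = nrow(al$matched),
    n_incorrect = nrow(al$unmatched_recon),
    n_missing = nrow(al$unmatched_ref))
}
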