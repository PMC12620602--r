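#' A single MS2 scan with its isolation-window metadata
#'
#' @param peaks a peak list ([peaklist()]), centroided.
#' @param isolation_center centre of the isolation window (Th).
#' @param isolation_width full width of the isolation window (Th, > 0).
#' @param nce normalised collision energy (unitless vendor percentage).
#' @param scan_index 0-based position of the scan in its series.
#' @return an object of class `ms2_scan`.
#' @export
ms2_scan <- function(peaks, isolation_center, isolation_width = 1,
                     nce = NA_real_, scan_index = 0L) {
  peaks <- as_peaklist(peaks)
  if (!is.numeric(isolation_center) || length(isolation_center) != 1L)
    stop("isolation_center must be a single number")
  if (isolation_width <= 0) stop("isolation_width must be > 0")
  scan_index <- as.integer(scan_index)
  if (scan_index < 0L) stop("scan_index must be >= 0")
  structure(
    list(peaks = peaks, isolation_center = isolation_center,
         isolation_width = isolation_width, nce = as.numeric(nce),
         scan_index = scan_index),
    class = "ms2_scan")
}

#' @export
print.ms2_scan <- function(x, ...) {
  cat(sprintf("<ms2_scan #%d> %d peaks, isolation %.4f +/- %.2f Th, NCE %s\n",
              x$scan_index, nrow(x$peaks), x$isolation_center,
              x$isolation_width / 2,
              ifelse(is.na(x$nce), "?", format(x$nce))))
  invisible(x)
}

#' An ordered series of stepped-isolation MS2 scans
#'
#' Scans must be ordered by strictly increasing scan index and strictly
#' increasing isolation centre: the acquisition steps the window from low to
#' high m/z, which is what produces the intensity modulation the
#' deconvolution relies on.
#'
#' @param scans a list of [ms2_scan()] objects.
#' @param plan the [build_plan()] the series was acquired under, or `NULL`.
#' @return an object of class `scan_series`.
#' @export
scan_series <- function(scans, plan = NULL) {
  if (!length(scans)) stop("scan_series: no scans")
  if (!all(vapply(scans, inherits, logical(1), "ms2_scan")))
    stop("all elements must be ms2_scan objects")
  idx <- vapply(scans, `[[`, integer(1), "scan_index")
  cen <- vapply(scans, `[[`, numeric(1), "isolation_center")
  if (any(diff(idx) <= 0)) stop("scan_index must be strictly increasing")
  if (any(diff(cen) <= 0)) stop("isolation_center must be strictly increasing")
  structure(list(scans = scans, plan = plan), class = "scan_series")
}

#' @export
length.scan_series <- function(x) length(x$scans)

#' @export
print.scan_series <- function(x, ...) {
  cen <- vapply(x$scans, `[[`, numeric(1), "isolation_center")
  cat(sprintf("<scan_series> %d MS2 scans, isolation centres %.4f .. %.4f Th\n",
              length(x$scans), min(cen), max(cen)))
  invisible(x)
}

#' Total ion current of every scan in a series
#' @param series a [scan_series()].
#' @return numeric vector of per-scan summed intensities.
#' @export
scan_tic <- function(series) {
  vapply(series$scans, function(s) sum(s$peaks$intensity), numeric(1))
}

#' A library reference spectrum of a pure compound
#'
#' Reference spectra carry formula-derived theoretical m/z values used for
#' alignment and recalibration. On construction the standard library cleanup
#' is applied: peaks with intensity strictly below `noise_frac` of the base
#' peak are discarded (peaks exactly at the threshold are kept).
#'
#' @param compound_id compound label.
#' @param precursor_mz theoretical precursor m/z (Th).
#' @param peaks a peak list; `mz` is taken as the measured m/z.
#' @param nce normalised collision energy the spectrum was recorded at.
#' @param mz_theo optional vector of theoretical m/z per peak (same order as
#'   the ascending-m/z peak list); defaults to the observed m/z.
#' @param noise_frac relative cleanup threshold (default 0.003 = 0.3%).
#' @param clean apply the cleanup rule (default `TRUE`).
#' @return an object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(compound_id, precursor_mz, peaks,
                               nce = NA_real_, mz_theo = NULL,
                               noise_frac = 0.003, clean = TRUE) {
  peaks <- as_peaklist(peaks)
  if (nrow(peaks) == 0L) stop("reference_spectrum: no peaks")
  if (is.null(mz_theo)) mz_theo <- peaks$mz
  if (length(mz_theo) != nrow(peaks))
    stop("mz_theo must have one value per peak")
  peaks$mz_theo <- as.numeric(mz_theo)
  if (clean) {
    keep <- peaks$intensity >= noise_frac * max(peaks$intensity)
    peaks <- peaks[keep, , drop = FALSE]
  }
  structure(
    list(compound_id = as.character(compound_id),
         precursor_mz = as.numeric(precursor_mz),
         peaks = peaks, nce = as.numeric(nce)),
    class = "reference_spectrum")
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %s: %d peaks, precursor %.4f Th, NCE %s\n",
              x$compound_id, nrow(x$peaks), x$precursor_mz,
              ifelse(is.na(x$nce), "?", format(x$nce))))
  invisible(x)
}

#' A reconstructed per-precursor MS2 spectrum
#'
#' The output of the deconvolution: the precursor (or substitute-fragment)
#' peak plus the fragments assigned to it, with template intensities.
#'
#' @param precursor_id precursor label (or substitute-fragment label).
#' @param peaks a peak list.
#' @param precursor_mz observed precursor m/z, or `NA` when substituted.
#' @param recalibrated has [recalibrate()] been applied?
#' @param is_substitute was the precursor peak replaced by its most intense
#'   known fragment?
#' @param nce normalised collision energy of the source series.
#' @return an object of class `reconstructed_spectrum`.
#' @export
reconstructed_spectrum <- function(precursor_id, peaks,
                                   precursor_mz = NA_real_,
                                   recalibrated = FALSE,
                                   is_substitute = FALSE,
                                   nce = NA_real_) {
  structure(
    list(precursor_id = as.character(precursor_id),
         peaks = as_peaklist(peaks),
         precursor_mz = as.numeric(precursor_mz),
         recalibrated = isTRUE(recalibrated),
         is_substitute = isTRUE(is_substitute),
         nce = as.numeric(nce)),
    class = "reconstructed_spectrum")
}

#' @export
print.reconstructed_spectrum <- function(x, ...) {
  cat(sprintf("<reconstructed_spectrum> %s%s: %d peaks%s\n",
              x$precursor_id,
              if (x$is_substitute) " (substitute precursor)" else "",
              nrow(x$peaks),
              if (x$recalibrated) ", recalibrated" else ""))
  invisible(x)
}

spectrum_peaks <- function(x) {
  if (inherits(x, c("reference_spectrum", "reconstructed_spectrum",
                    "ms2_scan"))) x$peaks
  else as_peaklist(x)
}
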