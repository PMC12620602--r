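#' Construct a peak list
#'
#' A peak list is the elementary container of the package: a data frame with
#' columns `mz` (Th) and `intensity` (arbitrary abundance units), sorted by
#' ascending m/z. All spectra handled here are centroided stick spectra.
#'
#' @param mz numeric vector of mass-to-charge ratios (Th), all > 0.
#' @param intensity numeric vector of abundances, all >= 0.
#' @return a `data.frame` with columns `mz`, `intensity`, sorted by `mz`.
#' @export
#' @examples
#' peaklist(c(200.1, 100.05), c(10, 50))
peaklist <- function(mz = numeric(), intensity = numeric()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (anyNA(mz) || anyNA(intensity))
    stop("peak lists may not contain NA")
  if (any(mz <= 0)) stop("all m/z values must be > 0")
  if (any(intensity < 0)) stop("all intensities must be >= 0")
  o <- order(mz)
  data.frame(mz = mz[o], intensity = intensity[o])
}

is_peaklist <- function(x) {
  is.data.frame(x) && all(c("mz", "intensity") %in% names(x))
}

as_peaklist <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is_peaklist(x)) stop("not a peak list (need mz and intensity columns)")
  peaklist(x$mz, x$intensity)
}

#' Base peak of a peak list
#'
#' Returns the single most intense peak; ties are broken towards the lower
#' m/z so that relative-intensity thresholds anchored on the base peak are
#' deterministic.
#'
#' @param peaks a peak list (see [peaklist()]).
#' @return a one-row peak list.
#' @export
base_peak <- function(peaks) {
  peaks <- as_peaklist(peaks)
  if (nrow(peaks) == 0L) stop("base_peak: peak list is empty")
  i <- which(peaks$intensity == max(peaks$intensity))
  i <- i[which.min(peaks$mz[i])]
  peaks[i, , drop = FALSE]
}

#' Merge several peak lists into a consensus list
#'
#' Peaks from all input lists falling within `tol` of each other (single
#' linkage on the ascending m/z axis: a gap larger than `tol` starts a new
#' consensus peak) are combined into one consensus peak. The consensus m/z is
#' the intensity-weighted mean of the member m/z values; the consensus
#' intensity combines member intensities by `combine`. This is the primitive
#' behind template construction, where the most intense scan is merged with
#' its neighbouring scans.
#'
#' The output never contains two peaks closer than `tol`, and merging a
#' merged list with itself (with `combine = "mean"`) is an identity up to
#' floating point.
#'
#' @param lists a list of peak lists.
#' @param tol absolute m/z tolerance in Th (> 0); all tolerances in this
#'   package are absolute (mDa-scale), not ppm.
#' @param combine how member intensities form the consensus intensity.
#' @return a consensus peak list.
#' @export
#' @examples
#' a <- peaklist(100.000, 40)
#' b <- peaklist(100.0005, 60)
#' merge_peaklists(list(a, b), tol = 0.001)  # one peak at 100.0003, I = 50
merge_peaklists <- function(lists, tol, combine = c("mean", "sum", "max")) {
  combine <- match.arg(combine)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("tol must be a single positive number")
  lists <- lapply(lists, as_peaklist)
  lists <- Filter(function(p) nrow(p) > 0L, lists)
  if (length(lists) == 0L) return(peaklist())
  all <- do.call(rbind, lists)
  all <- all[order(all$mz), , drop = FALSE]
  grp <- cumsum(c(1, diff(all$mz) > tol))
  mzs <- vapply(split(all, grp), function(g) {
    tot <- sum(g$intensity)
    if (tot > 0) sum(g$mz * g$intensity) / tot else mean(g$mz)
  }, numeric(1))
  fun <- switch(combine, mean = mean, sum = sum, max = max)
  ints <- vapply(split(all$intensity, grp), fun, numeric(1))
  peaklist(mzs, ints)
}

# Greedy one-to-one matching of two m/z vectors by ascending |delta|,
# capped at `tol`. Returns a two-column matrix of (i, j) index pairs.
match_peaks_greedy <- function(mz_a, mz_b, tol) {
  if (length(mz_a) == 0L || length(mz_b) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  d <- abs(outer(mz_a, mz_b, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_a <- logical(length(mz_a))
  used_b <- logical(length(mz_b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[k] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("a", "b")
  out
}
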