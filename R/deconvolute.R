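#' Build the template spectrum of a chimeric scan series
#'
#' The template is the master peak list defining the peak universe of the
#' deconvolution. The scan with the highest intensity (by default total ion
#' current; base-peak intensity via `seed_mode`) is picked and merged with
#' its `n_neighbors` neighbouring scans (half before, half after, truncated
#' at the series boundaries). Each contributing scan is first filtered at
#' the ground-noise threshold of `noise_frac` of its base peak; the merged
#' template is filtered at `noise_frac` of the template base peak. Template
#' peaks matching a blank peak whose intensity exceeds `blank_frac` of the
#' blank base peak are then removed.
#'
#' @param series a [scan_series()].
#' @param blank peak list of a blank MS2 spectrum, or `NULL` to skip blank
#'   subtraction.
#' @param noise_frac ground-noise threshold relative to the base peak
#'   (default 0.003 = 0.3%).
#' @param blank_frac relative blank intensity above which a blank peak
#'   knocks out matching template peaks (default 0.01 = 1%).
#' @param n_neighbors number of neighbouring scans merged with the seed
#'   scan (default 10: five before, five after).
#' @param match_tol m/z tolerance (Th) for merging peaks across scans and
#'   matching blank peaks.
#' @param seed_mode how the seed scan's "highest intensity" is measured.
#' @return an object of class `template_spectrum`: `peaks` (with stable
#'   `peak_id`), `source_scan_index`, `noise_floor`, `merged_scan_indices`.
#' @export
build_template <- function(series, blank = NULL, noise_frac = 0.003,
                           blank_frac = 0.01, n_neighbors = 10L,
                           match_tol = 0.002,
                           seed_mode = c("tic", "base_peak")) {
  stopifnot(inherits(series, "scan_series"))
  seed_mode <- match.arg(seed_mode)
  if (!length(series$scans)) stop("build_template: empty scan series")
  score <- switch(seed_mode,
    tic = scan_tic(series),
    base_peak = vapply(series$scans, function(s)
      if (nrow(s$peaks)) max(s$peaks$intensity) else 0, numeric(1)))
  seed_pos <- which.max(score)
  before <- floor(n_neighbors / 2)
  after <- n_neighbors - before
  window <- max(1L, seed_pos - before):min(length(series$scans),
                                           seed_pos + after)
  member <- lapply(series$scans[window], function(s) {
    p <- s$peaks
    if (!nrow(p)) return(p)
    p[p$intensity >= noise_frac * max(p$intensity), , drop = FALSE]
  })
  tpl <- merge_peaklists(member, tol = match_tol, combine = "mean")
  if (!nrow(tpl)) stop("build_template: all peaks filtered away")
  floor_abs <- noise_frac * max(tpl$intensity)
  tpl <- tpl[tpl$intensity >= floor_abs, , drop = FALSE]
  if (!is.null(blank)) {
    blank <- as_peaklist(blank)
    if (nrow(blank)) {
      strong <- blank$mz[blank$intensity > blank_frac * max(blank$intensity)]
      if (length(strong)) {
        hit <- vapply(tpl$mz, function(m) any(abs(strong - m) <= match_tol),
                      logical(1))
        tpl <- tpl[!hit, , drop = FALSE]
      }
    }
  }
  if (!nrow(tpl)) stop("build_template: template empty after blank subtraction")
  tpl$peak_id <- sprintf("P%03d", seq_len(nrow(tpl)))
  tpl <- tpl[, c("peak_id", "mz", "intensity")]
  structure(
    list(peaks = tpl,
         source_scan_index = series$scans[[seed_pos]]$scan_index,
         noise_floor = floor_abs,
         merged_scan_indices = vapply(series$scans[window], `[[`,
                                      integer(1), "scan_index"),
         match_tol = match_tol),
    class = "template_spectrum")
}

#' @export
print.template_spectrum <- function(x, ...) {
  cat(sprintf("<template_spectrum> %d peaks (seed scan #%d, %d scans merged)\n",
              nrow(x$peaks), x$source_scan_index,
              length(x$merged_scan_indices)))
  invisible(x)
}

#' Per-scan intensities of every template peak
#'
#' @param template a [build_template()] result.
#' @param series the [scan_series()] the template came from.
#' @param match_tol m/z tolerance (Th) for matching template peaks in a
#'   scan; defaults to the template's own tolerance.
#' @return numeric matrix, template peaks (rows, named by `peak_id`) by
#'   scans (columns, named by `scan_index`). A peak absent from a scan
#'   contributes 0 — absence is informative of transmission, not missing
#'   data.
#' @export
build_intensity_matrix <- function(template, series,
                                   match_tol = template$match_tol) {
  stopifnot(inherits(template, "template_spectrum"),
            inherits(series, "scan_series"))
  tpl <- template$peaks
  M <- matrix(0, nrow = nrow(tpl), ncol = length(series$scans),
              dimnames = list(tpl$peak_id,
                              vapply(series$scans, `[[`, integer(1),
                                     "scan_index")))
  for (s in seq_along(series$scans)) {
    sp <- series$scans[[s]]$peaks
    if (!nrow(sp)) next
    M[, s] <- vapply(tpl$mz, function(m)
      sum(sp$intensity[abs(sp$mz - m) <= match_tol]), numeric(1))
  }
  M
}

#' All-pairs correlation of template peak intensity profiles
#'
#' Pearson (default) or Spearman correlation between the per-scan intensity
#' profiles of every pair of template peaks. Peaks with zero profile
#' variance or with fewer than `min_support` non-zero scans get an
#' undefined (`NA`) correlation rather than a silent 0.
#'
#' @param M an intensity matrix from [build_intensity_matrix()].
#' @param method correlation type.
#' @param min_support minimum number of non-zero scans for a defined
#'   correlation (default 3; Pearson needs variance to mean anything).
#' @return square symmetric matrix over template peak ids, diagonal 1 for
#'   defined rows, `NA` for undefined ones.
#' @export
correlation_matrix <- function(M, method = c("pearson", "spearman"),
                               min_support = 3L) {
  method <- match.arg(method)
  if (ncol(M) < 3L)
    stop("correlation_matrix: need at least 3 scans")
  C <- suppressWarnings(stats::cor(t(M), method = method))
  bad <- apply(M, 1L, stats::sd) == 0 | rowSums(M > 0) < min_support
  C[bad, ] <- NA_real_
  C[, bad] <- NA_real_
  diag(C)[!bad] <- 1
  C
}

#' Assign each template fragment to a precursor
#'
#' The deconvolution step proper: every non-precursor template peak is
#' assigned to the precursor with which its intensity profile correlates
#' best — a hard assignment, so a fragment shared by two precursors goes
#' only to the one with the higher correlation score. Undefined
#' correlations are excluded from the argmax; a fragment with no defined
#' correlation to any precursor lands in the unassigned pool.
#'
#' Exact correlation ties are broken deterministically: the fragment goes
#' to the precursor whose intensity-weighted profile centroid (mean scan
#' index weighted by intensity, from `M`) is nearest the fragment's own
#' profile centroid; without `M`, to the lower-m/z precursor. Ties are
#' recorded in the returned table.
#'
#' @param corr a [correlation_matrix()].
#' @param precursors data frame with columns `precursor_id`, `peak_id`,
#'   `mz`, `is_substitute` (see [deconvolute()]).
#' @param M optional intensity matrix enabling the profile-centroid
#'   tie-break.
#' @return list with `assignments` (data frame `peak_id`, `precursor_id`,
#'   `correlation`, `tie`) and `unassigned` (character vector of peak ids).
#' @export
assign_fragments <- function(corr, precursors, M = NULL) {
  if (is.null(precursors) || nrow(precursors) == 0L)
    stop("assign_fragments: empty precursor set")
  if (!all(precursors$peak_id %in% rownames(corr)))
    stop("assign_fragments: precursor peak id missing from correlation matrix")
  frag_ids <- setdiff(rownames(corr), precursors$peak_id)
  centroid <- function(id) {
    prof <- M[id, ]
    if (sum(prof) == 0) return(NA_real_)
    sum(seq_along(prof) * prof) / sum(prof)
  }
  res <- lapply(frag_ids, function(fid) {
    r <- corr[fid, precursors$peak_id]
    ok <- !is.na(r)
    if (!any(ok)) return(NULL)
    best <- max(r[ok])
    cand <- which(ok & r == best)
    tie <- length(cand) > 1L
    if (tie) {
      if (!is.null(M)) {
        cf <- centroid(fid)
        cp <- vapply(precursors$peak_id[cand], centroid, numeric(1))
        cand <- cand[which.min(abs(cp - cf))]
      } else {
        cand <- cand[which.min(precursors$mz[cand])]
      }
      message(sprintf(
        "assign_fragments: correlation tie for %s broken towards %s",
        fid, precursors$precursor_id[cand]))
    } else cand <- cand[1L]
    data.frame(peak_id = fid,
               precursor_id = precursors$precursor_id[cand],
               correlation = best, tie = tie)
  })
  keep <- !vapply(res, is.null, logical(1))
  unassigned <- frag_ids[!keep]
  if (length(unassigned))
    message("assign_fragments: ", length(unassigned),
            " peak(s) with undefined correlations left unassigned")
  assignments <- if (any(keep)) do.call(rbind, res[keep]) else
    data.frame(peak_id = character(), precursor_id = character(),
               correlation = numeric(), tie = logical())
  list(assignments = assignments, unassigned = unassigned)
}

#' Substitute a missing precursor by its most intense known fragment
#'
#' When a precursor ion is absent from the MS2 scans (fully fragmented, or
#' unresolved at low resolving power), its most intense known fragment that
#' is present in the template stands in for it in the correlation analysis.
#' Reference peaks are searched in descending intensity order; peaks within
#' `match_tol` of the reference precursor m/z are not considered fragments.
#'
#' @param template a [build_template()] result.
#' @param reference the compound's [reference_spectrum()].
#' @param match_tol m/z tolerance (Th) for locating the fragment in the
#'   template.
#' @return the substitute's template `peak_id`.
#' @export
substitute_precursor <- function(template, reference, match_tol = 0.003) {
  stopifnot(inherits(template, "template_spectrum"),
            inherits(reference, "reference_spectrum"))
  ref <- reference$peaks
  ref <- ref[abs(ref$mz - reference$precursor_mz) > match_tol, , drop = FALSE]
  if (!nrow(ref)) stop("substitute_precursor: reference has no fragments")
  ref <- ref[order(ref$intensity, decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(ref))) {
    d <- abs(template$peaks$mz - ref$mz[k])
    if (any(d <= match_tol))
      return(template$peaks$peak_id[which.min(d)])
  }
  stop("substitute_precursor: no reference fragment found in template; ",
       "precursor '", reference$compound_id, "' cannot be resolved")
}

#' Deconvolute a chimeric scan series into per-precursor spectra
#'
#' End-to-end composition of the processing chain: template construction,
#' intensity matrix, all-pairs correlation, and correlation-based hard
#' assignment of fragments to precursors. Each reconstructed spectrum holds
#' its precursor (or substitute) peak plus its assigned fragments, with
#' template intensities.
#'
#' @param series a [scan_series()].
#' @param precursor_mzs named numeric vector of precursor ion m/z values
#'   (names become precursor ids; unnamed values are labelled by m/z).
#' @param blank blank MS2 peak list, or `NULL`.
#' @param references optional named list of [reference_spectrum()] objects
#'   (by precursor id) used to substitute precursors missing from the
#'   template.
#' @param params list overriding processing defaults: `noise_frac` (0.003),
#'   `blank_frac` (0.01), `n_neighbors` (10), `match_tol` (0.002 Th),
#'   `cor_method` ("pearson"), `seed_mode` ("tic"), `precursor_tol`
#'   (m/z tolerance for locating precursor peaks in the template, default
#'   0.005 Th).
#' @return list of [reconstructed_spectrum()] objects (one per precursor),
#'   with attributes `template`, `intensity_matrix`, `correlation`,
#'   `assignments`, `unassigned`, `precursors`.
#' @export
#' @examples
#' cfg <- two_isobar_preset(0.048, noise_sd_rel = 0, seed = 3)
#' sim <- simulate_series(cfg)
#' out <- deconvolute(sim$series,
#'                    precursor_mzs = c(A = 342.076, B = 342.124))
#' out[["A"]]
deconvolute <- function(series, precursor_mzs, blank = NULL,
                        references = NULL, params = list()) {
  if (!length(precursor_mzs)) stop("deconvolute: no precursor m/z given")
  p <- utils::modifyList(
    list(noise_frac = 0.003, blank_frac = 0.01, n_neighbors = 10L,
         match_tol = 0.002, cor_method = "pearson", seed_mode = "tic",
         precursor_tol = 0.005),
    params)
  if (is.null(names(precursor_mzs)))
    names(precursor_mzs) <- sprintf("prec_%.4f", precursor_mzs)
  tpl <- build_template(series, blank = blank, noise_frac = p$noise_frac,
                        blank_frac = p$blank_frac,
                        n_neighbors = p$n_neighbors,
                        match_tol = p$match_tol, seed_mode = p$seed_mode)
  M <- build_intensity_matrix(tpl, series, match_tol = p$match_tol)
  corr <- correlation_matrix(M, method = p$cor_method)

  prec <- do.call(rbind, lapply(names(precursor_mzs), function(id) {
    d <- abs(tpl$peaks$mz - precursor_mzs[[id]])
    if (min(d) <= p$precursor_tol)
      return(data.frame(precursor_id = id,
                        peak_id = tpl$peaks$peak_id[which.min(d)],
                        mz = tpl$peaks$mz[which.min(d)],
                        is_substitute = FALSE))
    if (!is.null(references[[id]])) {
      pid <- substitute_precursor(tpl, references[[id]],
                                  match_tol = p$precursor_tol)
      message("deconvolute: precursor '", id,
              "' missing from template; substituting fragment ", pid)
      return(data.frame(precursor_id = id, peak_id = pid,
                        mz = tpl$peaks$mz[match(pid, tpl$peaks$peak_id)],
                        is_substitute = TRUE))
    }
    stop("deconvolute: precursor '", id, "' not found in template and no ",
         "reference spectrum available for substitution")
  }))
  if (anyDuplicated(prec$peak_id))
    stop("deconvolute: two precursors map to the same template peak; ",
         "increase resolution or adjust precursor_tol")

  asg <- assign_fragments(corr, prec, M = M)
  nce <- series$scans[[1L]]$nce
  out <- lapply(seq_len(nrow(prec)), function(i) {
    ids <- c(prec$peak_id[i],
             asg$assignments$peak_id[asg$assignments$precursor_id ==
                                       prec$precursor_id[i]])
    rows <- tpl$peaks[match(ids, tpl$peaks$peak_id), ]
    reconstructed_spectrum(prec$precursor_id[i],
                           peaklist(rows$mz, rows$intensity),
                           precursor_mz = prec$mz[i],
                           is_substitute = prec$is_substitute[i],
                           nce = nce)
  })
  names(out) <- prec$precursor_id
  attr(out, "template") <- tpl
  attr(out, "intensity_matrix") <- M
  attr(out, "correlation") <- corr
  attr(out, "assignments") <- asg$assignments
  attr(out, "unassigned") <- asg$unassigned
  attr(out, "precursors") <- prec
  out
}
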