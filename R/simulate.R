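#' Isolation-window transmission efficiency
#'
#' Models the imperfect band-pass behaviour of the low-resolution analyser
#' selecting ions for fragmentation: ions near the window centre are
#' transmitted fully, ions near the edges only partially. The default shape
#' is a symmetric trapezoid — efficiency 1 for `|mz - center| <=
#' 0.25 * width`, falling linearly to 0 at `0.5 * width * width_scale`. The
#' `widened_bandpass` model is the same trapezoid with `width_scale > 1`
#' stretching the edges, a phenomenological stand-in for the broadened
#' modulation profiles seen on linear ion-trap analysers; `width_scale` may
#' be length 2 `(left, right)` for an asymmetric stretch. A smooth
#' `gaussian` alternative (sd `width * width_scale / 4`, truncated at
#' `width * width_scale`) is available.
#'
#' @param mz ion m/z (Th); vectorised.
#' @param center isolation window centre (Th); vectorised.
#' @param width full isolation window width (Th, > 0).
#' @param model transmission shape.
#' @param width_scale edge stretch factor (> 0.5 for the trapezoid models;
#'   1 = nominal window).
#' @return transmission efficiency in \[0, 1\].
#' @export
#' @examples
#' transmission(342.5, 342.5, 1)            # 1 at the centre
#' transmission(342.875, 342.5, 1)          # 0.5 mid-edge
#' transmission(343.1, 342.5, 1)            # 0 outside
transmission <- function(mz, center, width,
                         model = c("shifted_bandpass", "widened_bandpass",
                                   "gaussian"),
                         width_scale = 1) {
  model <- match.arg(model)
  if (width <= 0) stop("width must be > 0")
  ws <- rep_len(width_scale, 2L)
  if (any(ws <= 0)) stop("width_scale must be > 0")
  d <- mz - center
  side_ws <- ifelse(d < 0, ws[1L], ws[2L])
  ad <- abs(d)
  if (model == "gaussian") {
    sd <- width * side_ws / 4
    eff <- exp(-0.5 * (ad / sd)^2)
    eff[ad > width * side_ws] <- 0
    return(eff)
  }
  flat <- 0.25 * width
  edge <- 0.5 * width * side_ws
  if (any(edge <= flat))
    stop("width_scale must exceed 0.5 for trapezoidal transmission")
  eff <- (edge - ad) / (edge - flat)
  eff[ad <= flat] <- 1
  eff[ad >= edge] <- 0
  eff
}

#' Define a simulated precursor
#'
#' @param id precursor label.
#' @param mz precursor ion m/z (Th).
#' @param base_intensity intensity of the precursor at full transmission,
#'   before fragmentation losses.
#' @param fragments data frame with columns `mz` and `branching` giving each
#'   fragment's m/z (< precursor m/z) and the fraction of the transmitted
#'   intensity it carries; the remainder (`1 - sum(branching)`) stays on the
#'   surviving precursor ion.
#' @param profile_model transmission shape for this precursor (see
#'   [transmission()]).
#' @param profile_width_scale edge stretch factor (1 = nominal window).
#' @return an object of class `precursor_model`.
#' @export
precursor_model <- function(id, mz, base_intensity, fragments,
                            profile_model = "shifted_bandpass",
                            profile_width_scale = 1) {
  fragments <- as.data.frame(fragments)
  if (!all(c("mz", "branching") %in% names(fragments)))
    stop("fragments needs columns mz and branching")
  if (any(fragments$branching < 0)) stop("branching fractions must be >= 0")
  if (sum(fragments$branching) > 1 + 1e-12)
    stop("branching fractions must sum to <= 1")
  if (any(fragments$mz >= mz)) stop("fragment m/z must be below precursor m/z")
  structure(
    list(id = as.character(id), mz = as.numeric(mz),
         base_intensity = as.numeric(base_intensity),
         fragments = fragments[order(fragments$mz), , drop = FALSE],
         profile_model = profile_model,
         profile_width_scale = profile_width_scale),
    class = "precursor_model")
}

#' Simulator configuration
#'
#' @param plan a [build_plan()] acquisition plan.
#' @param precursors list of [precursor_model()] objects. Fragments listed
#'   with identical m/z under two precursors are shared fragments and
#'   receive summed contributions.
#' @param isotopologue_abundance relative abundance of each precursor's
#'   first heavy isotopologue (0 disables isotopologue simulation).
#' @param isotopologue_offset m/z spacing of the isotopologue (Th; default
#'   the carbon isotope spacing 1.00336).
#' @param noise_sd_rel sd of the multiplicative log-normal intensity noise
#'   (0 = noiseless).
#' @param noise_floor_rel detection floor relative to the strongest
#'   noiseless signal of the series; peaks below it are dropped, mimicking
#'   low-intensity peaks going missing in individual scans.
#' @param blank_peaks peak list of solvent/background ions added to every
#'   scan at constant intensity, or `NULL`.
#' @param nce normalised collision energy recorded in scan metadata.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(plan, precursors, isotopologue_abundance = 0,
                       isotopologue_offset = 1.00336, noise_sd_rel = 0,
                       noise_floor_rel = 0, blank_peaks = NULL, nce = 35,
                       seed = 1L) {
  stopifnot(inherits(plan, "scan_plan"))
  if (!length(precursors) ||
      !all(vapply(precursors, inherits, logical(1), "precursor_model")))
    stop("precursors must be a non-empty list of precursor_model objects")
  if (isotopologue_abundance < 0 || noise_sd_rel < 0 || noise_floor_rel < 0)
    stop("noise and abundance parameters must be >= 0")
  if (!is.null(blank_peaks)) blank_peaks <- as_peaklist(blank_peaks)
  structure(
    list(plan = plan, precursors = precursors,
         isotopologue_abundance = isotopologue_abundance,
         isotopologue_offset = isotopologue_offset,
         noise_sd_rel = noise_sd_rel, noise_floor_rel = noise_floor_rel,
         blank_peaks = blank_peaks, nce = nce, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a stepped-isolation DI-MS2 scan series
#'
#' For every isolation-window position of the plan, each precursor
#' contributes `base_intensity * transmission(...)`, split between the
#' surviving precursor ion and its fragments according to the branching
#' fractions. Isotopologue ions (precursor m/z + offset) contribute the same
#' fragment ions with scaled abundance, which is what degrades
#' precursor-fragment correlation near the end of a cycle with wide
#' windows. Multiplicative log-normal noise, a relative detection floor and
#' constant blank peaks complete the scan. All randomness derives from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with components `series` (a [scan_series()]) and `truth`
#'   (a `ground_truth` object: `assignments` maps every non-blank simulated
#'   m/z to its owning precursor id, `"shared"`, or an isotopologue label;
#'   `intensities` holds the noiseless peaks-by-scans matrix;
#'   `contributions` holds each precursor's own noiseless per-scan signal).
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- config$plan
  cen <- plan_centers(plan)
  n_scan <- length(cen)
  iso_ab <- config$isotopologue_abundance

  # registry of all true peaks: precursor ions, isotopologue ions, fragments
  rows <- list()
  for (p in config$precursors) {
    rows[[length(rows) + 1L]] <- data.frame(
      mz = p$mz, owner = p$id, kind = "precursor")
    if (nrow(p$fragments))
      rows[[length(rows) + 1L]] <- data.frame(
        mz = p$fragments$mz, owner = p$id, kind = "fragment")
    if (iso_ab > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        mz = p$mz + config$isotopologue_offset,
        owner = paste0(p$id, "+1"), kind = "isotopologue")
  }
  reg <- do.call(rbind, rows)
  # collapse exact-m/z duplicates; fragments listed by several precursors
  # become shared
  key <- sprintf("%.6f", reg$mz)
  owner <- tapply(reg$owner, key, function(o)
    if (length(unique(o)) > 1L) "shared" else o[[1L]])
  kind <- tapply(reg$kind, key, `[[`, 1L)
  mz_all <- as.numeric(names(owner))
  o <- order(mz_all)
  mz_all <- mz_all[o]; owner <- owner[o]; kind <- kind[o]
  key <- sprintf("%.6f", mz_all)

  noiseless <- matrix(0, nrow = length(mz_all), ncol = n_scan,
                      dimnames = list(key, seq_len(n_scan) - 1L))
  contributions <- list()
  for (p in config$precursors) {
    tr <- transmission(p$mz, cen, plan$isolation_width, p$profile_model,
                       p$profile_width_scale)
    total <- p$base_intensity * tr
    surv <- 1 - sum(p$fragments$branching)
    own_mz <- c(p$mz, p$fragments$mz)
    own <- rbind(surv * total,
                 outer(p$fragments$branching, total))
    rownames(own) <- sprintf("%.6f", own_mz)
    colnames(own) <- colnames(noiseless)
    if (iso_ab > 0) {
      iso_mz <- p$mz + config$isotopologue_offset
      tr_i <- transmission(iso_mz, cen, plan$isolation_width,
                           p$profile_model, p$profile_width_scale)
      total_i <- iso_ab * p$base_intensity * tr_i
      own <- rbind(own, surv * total_i)
      rownames(own)[nrow(own)] <- sprintf("%.6f", iso_mz)
      # isotopologues fragment into the same product ions
      own[seq(2L, 1L + nrow(p$fragments)), ] <-
        own[seq(2L, 1L + nrow(p$fragments)), , drop = FALSE] +
        outer(p$fragments$branching, total_i)
    }
    contributions[[p$id]] <- own
    noiseless[rownames(own), ] <- noiseless[rownames(own), ] + own
  }

  floor_abs <- config$noise_floor_rel * max(noiseless)
  scans <- vector("list", n_scan)
  for (s in seq_len(n_scan)) {
    int <- noiseless[, s]
    if (config$noise_sd_rel > 0)
      int <- int * exp(stats::rnorm(length(int), 0, config$noise_sd_rel))
    keep <- int > floor_abs & int > 0
    mzs <- mz_all[keep]; ints <- int[keep]
    if (!is.null(config$blank_peaks) && nrow(config$blank_peaks)) {
      mzs <- c(mzs, config$blank_peaks$mz)
      ints <- c(ints, config$blank_peaks$intensity)
    }
    scans[[s]] <- ms2_scan(peaklist(mzs, ints), isolation_center = cen[s],
                           isolation_width = plan$isolation_width,
                           nce = config$nce, scan_index = s - 1L)
  }

  truth <- structure(
    list(assignments = data.frame(mz = mz_all, owner = unname(owner),
                                  kind = unname(kind)),
         intensities = noiseless,
         contributions = contributions,
         precursor_ids = vapply(config$precursors, `[[`, character(1), "id"),
         precursor_mzs = vapply(config$precursors, `[[`, numeric(1), "mz"),
         plan = plan, nce = config$nce),
    class = "ground_truth")
  list(series = scan_series(scans, plan = plan), truth = truth)
}

#' Ground-truth reference spectrum of one simulated precursor
#'
#' Builds the spectrum an ideal single-compound measurement of this
#' precursor would give: its precursor ion and owned fragments (shared
#' fragments included), with that precursor's own noiseless contribution at
#' the scan where its precursor ion transmits best.
#'
#' @param truth the `ground_truth` component of [simulate_series()].
#' @param precursor_id which precursor.
#' @return a [reference_spectrum()].
#' @export
truth_reference_spectrum <- function(truth, precursor_id) {
  stopifnot(inherits(truth, "ground_truth"))
  own <- truth$contributions[[precursor_id]]
  if (is.null(own)) stop("unknown precursor id: ", precursor_id)
  p_mz <- truth$precursor_mzs[match(precursor_id, truth$precursor_ids)]
  p_key <- sprintf("%.6f", p_mz)
  best <- which.max(own[p_key, ])
  int <- own[, best]
  keep <- int > 0
  reference_spectrum(precursor_id, precursor_mz = p_mz,
                     peaks = peaklist(as.numeric(rownames(own))[keep],
                                      int[keep]),
                     nce = truth$nce, clean = FALSE)
}

#' Ready-made two-isobar simulation preset
#'
#' Mirrors the study conditions of the isobaric mixtures used throughout:
#' two co-isolated precursors at `nominal + 0.1 +/- delta_mz / 2` Th, four
#' unique fragments each plus one optional shared fragment, first heavy
#' isotopologues, mild multiplicative noise, a relative detection floor and
#' three constant solvent blank peaks.
#'
#' @param delta_mz m/z separation of the two precursor ions (Th, > 0); the
#'   studied mixtures span 0.006-0.048 Th.
#' @param intensity_ratio base-intensity ratio A:B (e.g. 20 gives a 20:1
#'   mixture).
#' @param model_pair transmission models for precursors A and B.
#' @param width_scales edge stretch factors for A and B (used by the
#'   widened model).
#' @param nominal_mass nominal m/z the plan targets.
#' @param shared_fragment include a fragment produced by both precursors?
#' @param isotopologue_abundance relative isotopologue abundance (default
#'   0.2, typical of C15-C20 compounds).
#' @param noise_sd_rel multiplicative noise sd (default 0.1).
#' @param noise_floor_rel relative detection floor (default 0.002).
#' @param blank include the solvent blank peaks?
#' @param plan acquisition plan (default: the 81-event default method).
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
#' @examples
#' cfg <- two_isobar_preset(0.048, seed = 7)
#' sim <- simulate_series(cfg)
#' sim$series
two_isobar_preset <- function(delta_mz, intensity_ratio = 1,
                              model_pair = c("shifted_bandpass",
                                             "shifted_bandpass"),
                              width_scales = c(1, 1), nominal_mass = 342,
                              shared_fragment = TRUE,
                              isotopologue_abundance = 0.2,
                              noise_sd_rel = 0.1, noise_floor_rel = 0.002,
                              blank = TRUE,
                              plan = build_plan(nominal_mass), seed = 1L) {
  if (delta_mz <= 0) stop("delta_mz must be > 0")
  center <- nominal_mass + 0.1
  frag_a <- data.frame(
    mz = c(98.0600, 152.0706, 210.1121, 270.0766),
    branching = c(0.15, 0.20, 0.15, 0.10))
  frag_b <- data.frame(
    mz = c(110.0713, 165.0546, 228.0421, 285.0892),
    branching = c(0.20, 0.15, 0.15, 0.10))
  if (shared_fragment) {
    shared <- data.frame(mz = 135.0441, branching = 0.10)
    frag_a <- rbind(frag_a, shared)
    frag_b <- rbind(frag_b, shared)
  }
  pa <- precursor_model("A", center - delta_mz / 2,
                        base_intensity = 1e6, fragments = frag_a,
                        profile_model = model_pair[[1L]],
                        profile_width_scale = width_scales[[1L]])
  pb <- precursor_model("B", center + delta_mz / 2,
                        base_intensity = 1e6 / intensity_ratio,
                        fragments = frag_b,
                        profile_model = model_pair[[2L]],
                        profile_width_scale = width_scales[[2L]])
  blank_peaks <- if (blank)
    peaklist(c(83.0604, 120.0808, 301.1410), c(5e4, 2e4, 1e4))
  sim_config(plan, list(pa, pb),
             isotopologue_abundance = isotopologue_abundance,
             noise_sd_rel = noise_sd_rel,
             noise_floor_rel = noise_floor_rel,
             blank_peaks = blank_peaks, seed = seed)
}
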