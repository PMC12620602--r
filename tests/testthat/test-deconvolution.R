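make_series <- function(peaklists, centers = NULL, width = 1) {
  if (is.null(centers)) centers <- 342 + seq_along(peaklists) * 0.02
  scan_series(lapply(seq_along(peaklists), function(i)
    ms2_scan(peaklists[[i]], isolation_center = centers[i],
             isolation_width = width, nce = 35, scan_index = i - 1L)))
}

test_that("template of a single scan is that scan minus sub-noise peaks", {
  # 2 is 0.2% of 1000: below the ground-noise threshold; 3 (0.3%) survives
  s <- make_series(list(peaklist(c(100, 150, 200, 342), c(1000, 2, 3, 800))))
  tpl <- build_template(s, n_neighbors = 0L)
  expect_equal(tpl$peaks$mz, c(100, 150, 200, 342)[-2])
  expect_equal(tpl$source_scan_index, 0L)
})

test_that("template merges the seed scan with its neighbours", {
  pls <- c(replicate(3, peaklist(c(100, 342), c(10, 20)), simplify = FALSE),
           list(peaklist(c(100, 250, 342), c(100, 50, 200))),
           replicate(3, peaklist(c(100, 342), c(10, 20)), simplify = FALSE))
  tpl <- build_template(make_series(pls), n_neighbors = 2L)
  # seed is scan 4 (highest TIC); 250 only there, averaged over its members
  expect_equal(tpl$source_scan_index, 3L)
  expect_equal(sort(tpl$peaks$mz), c(100, 250, 342))
  expect_equal(sort(tpl$merged_scan_indices), 2:4)
})

test_that("strong blank peaks knock out matching template peaks", {
  s <- make_series(list(peaklist(c(100, 150, 342), c(500, 400, 1000))))
  blank <- peaklist(c(150.0005, 200), c(50, 5))  # 5% and 0.5% of blank base
  tpl <- build_template(s, blank = blank, match_tol = 0.002)
  expect_false(any(abs(tpl$peaks$mz - 150) < 0.01))
  # the weak blank peak (0.5% < 1%) does not remove anything
  s2 <- make_series(list(peaklist(c(100, 200, 342), c(500, 400, 1000))))
  blank2 <- peaklist(c(200, 150), c(5, 1000))
  tpl2 <- build_template(s2, blank = blank2)
  expect_true(any(abs(tpl2$peaks$mz - 200) < 0.01))
  expect_error(build_template(make_series(list(peaklist(150, 10))),
                              blank = peaklist(150, 100)), "empty")
})

test_that("intensity matrix reproduces noiseless simulated intensities", {
  cfg <- clean_preset(0.048, seed = 2)
  sim <- simulate_series(cfg)
  tpl <- build_template(sim$series)
  M <- build_intensity_matrix(tpl, sim$series)
  truthM <- sim$truth$intensities
  for (i in seq_len(nrow(tpl$peaks))) {
    key <- sprintf("%.6f", tpl$peaks$mz[i])
    expect_true(key %in% rownames(truthM))
    expect_equal(unname(M[tpl$peaks$peak_id[i], ]),
                 unname(truthM[key, ]), tolerance = 1e-9)
  }
  # a template row never corresponds to a removed blank peak
  cfgB <- two_isobar_preset(0.048, noise_sd_rel = 0, noise_floor_rel = 0,
                            isotopologue_abundance = 0, blank = TRUE,
                            seed = 2)
  simB <- simulate_series(cfgB)
  tplB <- build_template(simB$series, blank = cfgB$blank_peaks)
  expect_false(any(outer(tplB$peaks$mz, cfgB$blank_peaks$mz,
                         function(a, b) abs(a - b) < 0.002)))
})

test_that("correlation matrix matches the textbook Pearson oracle", {
  set.seed(101)
  for (r in 1:10) {
    M <- matrix(rexp(10 * 20, rate = 1e-4), nrow = 10,
                dimnames = list(sprintf("P%03d", 1:10), 0:19))
    C <- correlation_matrix(M)
    for (k in 1:20) {
      i <- sample(10, 1); j <- sample(10, 1)
      expect_equal(C[i, j], brute_pearson(M[i, ], M[j, ]),
                   tolerance = 1e-10)
    }
    expect_equal(C, t(C))
  }
})

test_that("degenerate profiles give undefined, never silent, correlations", {
  M <- rbind(P001 = c(1, 2, 3, 4), P002 = c(2, 2, 2, 2),
             P003 = c(0, 0, 1, 0))
  colnames(M) <- 0:3
  C <- correlation_matrix(M)
  expect_true(is.na(C["P002", "P001"]))      # zero variance
  expect_true(is.na(C["P003", "P001"]))      # < 3 non-zero scans
  expect_equal(C["P001", "P001"], 1)
  expect_error(correlation_matrix(M[, 1:2]), "3 scans")
})

test_that("fragments go to the precursor with the higher correlation", {
  corr <- matrix(c(1, 0.1, 0.9, 0.1, 1, 0.3, 0.9, 0.3, 1), 3, 3,
                 dimnames = list(c("P001", "P002", "P003"),
                                 c("P001", "P002", "P003")))
  prec <- data.frame(precursor_id = c("A", "B"),
                     peak_id = c("P001", "P002"), mz = c(342.1, 342.15),
                     is_substitute = FALSE)
  asg <- assign_fragments(corr, prec)
  expect_equal(asg$assignments$precursor_id, "A")
  expect_equal(asg$assignments$correlation, 0.9)
  expect_error(assign_fragments(corr, prec[0, ]), "empty")
})

test_that("exact correlation ties break towards the nearest profile centroid", {
  # two precursors with identical correlation to the fragment
  corr <- matrix(1, 3, 3, dimnames = list(c("P001", "P002", "P003"),
                                          c("P001", "P002", "P003")))
  prec <- data.frame(precursor_id = c("A", "B"),
                     peak_id = c("P001", "P002"), mz = c(342.1, 342.15),
                     is_substitute = FALSE)
  # fragment centroid sits at scan 8, like B's; A's sits at scan 2
  M <- rbind(P001 = c(0, 5, 10, 5, rep(0, 6)),
             P002 = c(rep(0, 6), 5, 10, 5, 0),
             P003 = c(rep(0, 6), 6, 12, 6, 0))
  colnames(M) <- 0:9
  expect_message(asg <- assign_fragments(corr, prec, M = M), "tie")
  expect_equal(asg$assignments$precursor_id, "B")
  expect_true(asg$assignments$tie)
})

test_that("fragments with undefined correlations land in the unassigned pool", {
  corr <- matrix(NA_real_, 3, 3,
                 dimnames = list(c("P001", "P002", "P003"),
                                 c("P001", "P002", "P003")))
  corr[1:2, 1:2] <- c(1, 0.2, 0.2, 1)
  prec <- data.frame(precursor_id = c("A", "B"),
                     peak_id = c("P001", "P002"), mz = c(1, 2),
                     is_substitute = FALSE)
  expect_message(asg <- assign_fragments(corr, prec), "unassigned")
  expect_equal(asg$unassigned, "P003")
  expect_equal(nrow(asg$assignments), 0L)
})

test_that("a missing precursor is substituted by its best template fragment", {
  s <- make_series(list(peaklist(c(98.06, 152.07, 200.1),
                                 c(300, 800, 100))))
  tpl <- build_template(s)
  ref <- reference_spectrum("A", 342.1,
                            peaklist(c(98.06, 152.07, 342.1),
                                     c(40, 90, 100)), clean = FALSE)
  # most intense reference fragment (152.07) is present in the template
  expect_equal(substitute_precursor(tpl, ref),
               tpl$peaks$peak_id[abs(tpl$peaks$mz - 152.07) < 0.01])
  # none of the reference fragments present -> unresolvable
  ref2 <- reference_spectrum("B", 342.1, peaklist(c(120.5, 342.1),
                                                  c(50, 100)),
                             clean = FALSE)
  expect_error(substitute_precursor(tpl, ref2), "cannot be resolved")
})

test_that("noiseless two-isobar deconvolution recovers the ground truth", {
  cfg <- clean_preset(0.048, seed = 2)
  sim <- simulate_series(cfg)
  pm <- sim$truth$precursor_mzs
  names(pm) <- sim$truth$precursor_ids
  out <- deconvolute(sim$series, precursor_mzs = pm)
  expect_named(out, c("A", "B"))
  expect_equal(assignment_accuracy(out, sim$truth), 1)
  # peak sets equal the ground-truth partition
  for (id in c("A", "B")) {
    own <- sim$truth$assignments
    want <- sort(own$mz[own$owner == id])
    expect_equal(sort(out[[id]]$peaks$mz), want, tolerance = 1e-6)
  }
})

test_that("every template peak is assigned exactly once or pooled unassigned", {
  cfg <- two_isobar_preset(0.02, noise_sd_rel = 0.15, seed = 13)
  sim <- simulate_series(cfg)
  pm <- sim$truth$precursor_mzs
  names(pm) <- sim$truth$precursor_ids
  out <- suppressMessages(
    deconvolute(sim$series, precursor_mzs = pm, blank = cfg$blank_peaks))
  tpl <- attr(out, "template")
  asg <- attr(out, "assignments")
  prec <- attr(out, "precursors")
  covered <- c(asg$peak_id, attr(out, "unassigned"), prec$peak_id)
  expect_setequal(covered, tpl$peaks$peak_id)
  expect_false(anyDuplicated(covered) > 0)
  # reconstructed peak sets partition the template
  n_recon <- sum(vapply(out, function(x) nrow(x$peaks), integer(1)))
  expect_equal(n_recon + length(attr(out, "unassigned")),
               nrow(tpl$peaks))
})

test_that("a single-precursor series yields one spectrum with every peak", {
  plan <- build_plan(342)
  p <- precursor_model("solo", 342.1, 1e6,
    fragments = data.frame(mz = c(98.06, 152.07, 210.11),
                           branching = c(0.2, 0.3, 0.2)))
  sim <- simulate_series(sim_config(plan, list(p), seed = 6))
  out <- deconvolute(sim$series, precursor_mzs = c(solo = 342.1))
  expect_length(out, 1L)
  expect_equal(nrow(out[["solo"]]$peaks),
               nrow(attr(out, "template")$peaks))
})

test_that("missing precursor in deconvolute falls back to substitution", {
  plan <- build_plan(342)
  # precursor fully fragmented: no surviving precursor ion
  p <- precursor_model("gone", 342.1, 1e6,
    fragments = data.frame(mz = c(98.06, 152.07), branching = c(0.6, 0.4)))
  sim <- simulate_series(sim_config(plan, list(p), seed = 6))
  ref <- reference_spectrum("gone", 342.1,
                            peaklist(c(98.06, 152.07, 342.1),
                                     c(60, 90, 10)), clean = FALSE)
  expect_error(deconvolute(sim$series, precursor_mzs = c(gone = 342.1)),
               "not found in template")
  out <- suppressMessages(
    deconvolute(sim$series, precursor_mzs = c(gone = 342.1),
                references = list(gone = ref)))
  expect_true(out[["gone"]]$is_substitute)
  expect_equal(nrow(out[["gone"]]$peaks),
               nrow(attr(out, "template")$peaks))
})
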