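test_that("alignment matches within 3 mDa, greedily and one-to-one", {
  ref <- reference_spectrum("R", 342.1,
                            peaklist(c(100.000, 200.000), c(50, 100)),
                            clean = FALSE)
  # +2 mDa: inside the window
  al <- align_spectra(peaklist(100.002, 40), ref)
  expect_equal(nrow(al$matched), 1L)
  expect_equal(al$matched$delta, 0.002, tolerance = 1e-9)
  # +4 mDa: outside
  al <- align_spectra(peaklist(100.004, 40), ref)
  expect_equal(nrow(al$matched), 0L)
  expect_equal(nrow(al$unmatched_recon), 1L)
  # two reconstructed peaks near one reference peak: closer one wins
  al <- align_spectra(peaklist(c(99.9985, 100.0005), c(10, 20)), ref)
  expect_equal(nrow(al$matched), 1L)
  expect_equal(al$matched$recon_mz, 100.0005)
  expect_equal(nrow(al$unmatched_recon), 1L)
})

test_that("recalibration removes the median relative mass offset", {
  ref <- reference_spectrum("R", 342.102,
    peaklist(c(150.000, 250.000, 342.100), c(30, 60, 100)), clean = FALSE)
  # constant +2 mDa offset at every peak
  rec <- reconstructed_spectrum("R", peaklist(
    c(150.000, 250.000, 342.100) * (1 + 2e-3 / 342.1), c(30, 60, 100)),
    precursor_mz = 342.102)
  al <- align_spectra(rec, ref)
  out <- recalibrate(rec, al)
  expect_true(out$recalibrated)
  expect_equal(out$peaks$mz, c(150.000, 250.000, 342.100),
               tolerance = 1e-9)
  # offsets symmetric around zero leave the spectrum unchanged
  rec2 <- reconstructed_spectrum("R", peaklist(
    c(150.000 * (1 - 1e-6), 250.000, 342.100 * (1 + 1e-6)),
    c(30, 60, 100)))
  out2 <- recalibrate(rec2, align_spectra(rec2, ref))
  expect_equal(out2$peaks$mz, rec2$peaks$mz, tolerance = 1e-12)
  # a single match defines the offset exactly
  rec3 <- reconstructed_spectrum("R", peaklist(250.001, 60))
  out3 <- recalibrate(rec3, align_spectra(rec3, ref))
  expect_equal(out3$peaks$mz, 250.000, tolerance = 1e-9)
  expect_error(recalibrate(rec3, align_spectra(peaklist(999, 1), ref,
                                               tol = 0.003)),
               "no matched")
})

test_that("cosine similarity handles identity, disjointness and hand cases", {
  u <- peaklist(c(100, 200, 300), c(10, 50, 20))
  expect_equal(spectral_similarity(u, u), 1)
  expect_equal(spectral_similarity(u, peaklist(c(150, 250), c(5, 5))), 0)
  # (3*4 + 4*3) / (5 * 5)
  expect_equal(spectral_similarity(peaklist(c(100, 200), c(3, 4)),
                                   peaklist(c(100, 200), c(4, 3))), 0.96)
})

test_that("similarity is symmetric and scale invariant", {
  set.seed(55)
  for (i in 1:10) {
    pair <- random_aligned_pair(6, 3, tol = 2e-4)
    s1 <- spectral_similarity(pair$u, pair$v)
    expect_equal(spectral_similarity(pair$v, pair$u), s1, tolerance = 1e-12)
    scaled <- pair$u
    scaled$intensity <- scaled$intensity * 37.5
    expect_equal(spectral_similarity(scaled, pair$v), s1,
                 tolerance = 1e-12)
    expect_true(s1 >= 0 && s1 <= 1)
  }
})

test_that("similarity agrees with the merged-axis brute-force oracle", {
  set.seed(77)
  for (i in 1:25) {
    pair <- random_aligned_pair(sample(3:8, 1), sample(1:4, 1), tol = 2e-4)
    expect_equal(spectral_similarity(pair$u, pair$v, tol = 2e-4),
                 brute_cosine_merged_axis(pair$u, pair$v, tol = 2e-4),
                 tolerance = 1e-10)
  }
})

test_that("precision ignores missing peaks, recall ignores wrong extras", {
  ref <- reference_spectrum("R", 342.1,
    peaklist(c(100, 150, 200, 342.1), c(70, 10, 20, 100)), clean = FALSE)
  # matched 90, unmatched 10 by intensity
  rec <- peaklist(c(100, 250), c(90, 10))
  expect_equal(spectral_precision(rec, ref), 0.9)
  # one correct peak, everything else missing: precision still 1
  expect_equal(spectral_precision(peaklist(100, 5), ref), 1)
  # recall weights by reference intensity: 70 of 200 found
  expect_equal(spectral_recall(peaklist(100, 999), ref), 0.35)
  # wrong extra peaks do not lower recall
  full <- peaklist(c(100, 150, 200, 342.1, 400, 450),
                   c(70, 10, 20, 100, 500, 600))
  expect_equal(spectral_recall(full, ref), 1)
  expect_lt(spectral_precision(full, ref), 1)
  # recon == ref gives all three metrics 1
  same <- peaklist(ref$peaks$mz, ref$peaks$intensity)
  expect_equal(spectral_precision(same, ref), 1)
  expect_equal(spectral_recall(same, ref), 1)
  expect_equal(spectral_similarity(same, ref), 1)
})

test_that("nce50 interpolates the downward 0.5 crossing", {
  expect_equal(nce50(c(30, 40), c(0.8, 0.2)), 35.0)
  expect_equal(nce50(c(20, 35, 50), c(0.9, 0.5, 0.1)), 35)  # exact point
  expect_equal(nce50(c(20, 30, 40, 50), c(0.95, 0.9, 0.3, 0.05)),
               30 + (0.9 - 0.5) / 0.6 * 10)
  expect_error(nce50(c(30, 40), c(0.9, 0.7)), "never crosses")
  expect_error(nce50(30, 0.4), "points")
  expect_error(nce50(c(30, 40), c(1.2, 0.3)), "fractions")
})

test_that("profile distance sums rise and fall scan differences", {
  a <- ifelse(0:80 %in% 30:60, 1, 0)
  b <- ifelse(0:80 %in% 35:65, 1, 0)
  expect_equal(profile_distance(a, b), 10)
  expect_equal(profile_distance(a, a), 0)
  # max-normalised profiles always reach 0.5; a higher level can fail
  expect_error(profile_distance(a, b, level = 1.1), "never reaches")
})

test_that("a simulated k-scan translation gives profile distance 2k", {
  cfg <- clean_preset(0.06, seed = 3)  # 3 steps apart
  sim <- simulate_series(cfg)
  keyA <- sprintf("%.6f", cfg$precursors[[1]]$mz)
  keyB <- sprintf("%.6f", cfg$precursors[[2]]$mz)
  pa <- sim$truth$intensities[keyA, ]
  pb <- sim$truth$intensities[keyB, ]
  expect_equal(profile_distance(pa, pb), 2 * 3)
  expect_equal(profile_distance(pa, pb, interpolate = TRUE), 2 * 3,
               tolerance = 1e-9)
})

test_that("modulation profiles are max-normalised over scan indices", {
  cfg <- clean_preset(0.02, seed = 4)
  sim <- simulate_series(cfg)
  tpl <- build_template(sim$series)
  M <- build_intensity_matrix(tpl, sim$series)
  prof <- modulation_profile(M, tpl$peaks$peak_id[1])
  expect_equal(max(prof$rel_intensity), 1)
  expect_true(all(prof$rel_intensity >= 0 & prof$rel_intensity <= 1))
  expect_equal(length(prof$rel_intensity), 81L)
})

test_that("evaluate_reconstruction recalibrates before scoring", {
  ref <- reference_spectrum("R", 342.102,
    peaklist(c(150.000, 250.000, 342.100), c(30, 60, 100)), clean = FALSE)
  # constant +1.5 mDa offset: matched at 3 mDa, hopeless at 0.2 mDa
  shift <- 1 + 1.5e-3 / 342.1
  rec <- reconstructed_spectrum("R",
    peaklist(c(150.000, 250.000, 342.100) * shift, c(30, 60, 100)),
    precursor_mz = 342.102 * shift)
  res <- evaluate_reconstruction(rec, ref)
  expect_equal(res$similarity, 1, tolerance = 1e-9)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  raw <- evaluate_reconstruction(rec, ref, recalibrate = FALSE)
  expect_lt(raw$similarity, 0.5)
})
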