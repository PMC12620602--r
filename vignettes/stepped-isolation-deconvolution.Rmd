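---
title: "Deconvoluting chimeric DI-MS2 spectra with a stepped isolation window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting chimeric DI-MS2 spectra with a stepped isolation window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dims2)
```

## The problem

In direct-infusion tandem MS there is no chromatographic separation: every
ionised compound is present at once, and any two precursors closer in m/z
than the narrowest usable isolation window (0.1–0.4 Th on common Orbitrap
front-ends) co-fragment. The resulting chimeric MS2 spectrum mixes the
fragments of all co-isolated isobars and defeats library matching and
structure elucidation.

The acquisition trick this package implements exploits the *imperfection*
of the band-pass filter that selects ions for fragmentation. Instead of one
MS2 scan, a cycle of scans is recorded while the isolation window centre
steps in small increments (default 0.02 Th) across the precursor region,
from `nominal − 0.7` to `nominal + 0.9` Th — 81 fragmentation events with
the defaults. Transmission is highest for ions near the window centre, so
as the window moves each precursor's intensity — and therefore that of its
fragments — rises and falls with a characteristic *modulated intensity
profile*. Two isobars separated by Δm/z have profiles shifted by roughly
Δm/z / step scans; fragments inherit their precursor's profile. Correlating
profiles over the cycle therefore reveals which fragment belongs to which
precursor, independent of the analyser's resolution.

## The processing chain

`deconvolute()` composes four stages, each exposed on its own:

1. **Template** (`build_template()`). The scan with the highest total ion
   current is merged with its 10 neighbouring scans (five before, five
   after; the base-peak criterion is available via `seed_mode`). Peaks
   below the ground-noise threshold of 0.3% of the base peak are removed,
   and template peaks matching a blank peak whose intensity exceeds 1% of
   the blank's base peak are subtracted. The template defines the peak
   universe: a stable `peak_id` per consensus m/z.
2. **Intensity matrix** (`build_intensity_matrix()`). For every template
   peak and every scan, the summed intensity of scan peaks within
   `match_tol` (default 0.002 Th) of the template m/z. A peak absent from
   a scan counts as 0, not as missing data — absence *is* the modulation
   signal.
3. **Correlation matrix** (`correlation_matrix()`). Pearson correlation of
   all row pairs (Spearman via `cor_method`). Rows with zero variance or
   present in fewer than 3 scans get an `NA` marker, never a silent 0.
4. **Assignment** (`assign_fragments()`). Each non-precursor peak goes to
   the precursor with the highest correlation — a hard assignment, so a
   fragment produced by both precursors is credited only to the better
   correlated one, which is the known cost of the simple correlation
   method: the other precursor's recall drops while precision is
   untouched. When a precursor ion is absent from the scans (fully
   fragmented, or unresolved), `substitute_precursor()` replaces it by its
   most intense library fragment present in the template.

Evaluation follows the same conventions used to benchmark the method:
greedy one-to-one alignment of reconstruction and reference at 3 mDa,
median-ppm recalibration onto the reference's formula-derived theoretical
m/z, cosine similarity on a 0.2 mDa-aligned axis, and intensity-weighted
precision (reconstruction intensities) and recall (reference intensities).
Two auxiliary statistics characterise modulation behaviour: `nce50()`, the
collision energy at which the precursor retains half of the total MS2
intensity, and `profile_distance()`, the scan-count separation of two
profiles' rising and falling 0.5-crossings.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `step` | 0.02 | Th | window movement per event; sets profile sampling density |
| `isolation_width` | 1 | Th | full window width; wider windows co-isolate isotopologues |
| `start_offset`, `end_offset` | −0.7, +0.9 | Th | scanned centre range around the nominal mass |
| `noise_frac` | 0.003 | – | ground-noise threshold, fraction of base peak |
| `blank_frac` | 0.01 | – | blank peaks above this fraction of the blank base peak are subtracted |
| `n_neighbors` | 10 | scans | neighbours merged into the template |
| `match_tol` | 0.002 | Th | cross-scan template matching tolerance |
| `align_tol` | 0.003 | Th | reconstruction–reference alignment window |
| `sim_tol` | 0.0002 | Th | cosine-similarity alignment window (post-recalibration) |

All m/z tolerances are absolute (mDa scale), not ppm, matching how the
processing thresholds are customarily stated for this method. Event counts
follow `floor((end − start)/step) + 1`; offsets for non-default widths are
plain configuration values rather than being derived from the width, since
no single arithmetic rule reproduces all printed event counts for wider
and narrower windows (the 2.0 Th window's −1.7..+1.9 range at 0.02 Th
steps is 181 events by this arithmetic, the 0.4 Th window's −0.3..+0.4
range 36).

## What the simulator emulates — and what it does not

`simulate_series()` generates a scan series with known ground truth. Each
precursor contributes `base_intensity × transmission(mz, center, ...)` per
scan, split between the surviving precursor ion and its fragments by fixed
branching fractions. The transmission curve is a trapezoid — flat top over
the central half-width, linear edges reaching zero at half the width —
because the true band-pass shape of a quadrupole or LIT is not published
for these instruments; a Gaussian alternative is available. The observed
ion-trap "widening" behaviour, where one isobar's signal appears first and
disappears last, is modelled phenomenologically by stretching the edges
(`width_scale > 1`), without claiming a physical mechanism; the link
between fragmentation resistance (NCE50) and profile width is left
uncoupled for the same reason.

The simulator also reproduces the known confounders: shared fragments
(identical product m/z listed under two precursors), first heavy
isotopologues at +1.00336 Th producing the same fragments late in the
cycle, multiplicative log-normal intensity noise, a relative detection
floor below which peaks vanish from individual scans, and constant solvent
blank peaks. `two_isobar_preset()` bundles these into the conditions the
benchmark mixtures represent: precursor separations of 0.006–0.048 Th on a
nominal mass of 342, roughly equal MS1 intensities (ratios up to 20:1 via
`intensity_ratio`), four unique fragments each plus one shared fragment,
20% isotopologue abundance, 10% multiplicative noise and a 0.2% floor.

What it does *not* emulate: ion statistics (shot noise, AGC-dependent
injection), resolution-dependent peak coalescence (all spectra are stick
spectra — so unresolved isobaric *fragments* never occur), space-charge
mass-error drift, and electrospray fluctuation. Passing tests on synthetic
data therefore demonstrate the correctness of the processing chain and its
qualitative degradation behaviour, not instrument-grade performance.

## Numerical choices

* **Peak merging** is single-linkage on the sorted m/z axis with a gap
  threshold of `tol`; consensus m/z is the intensity-weighted mean. This
  makes merging idempotent and guarantees no two output peaks lie within
  `tol`.
* **Greedy alignment** matches peak pairs by ascending |Δm/z|, one-to-one.
  Ties in intensity for the base peak resolve to the lower m/z.
* **Seed-scan choice**: "highest intensity" is read as highest total ion
  current, the more robust criterion when one precursor dominates;
  base-peak mode is a flag. Noise filtering precedes blank subtraction.
* **Correlation ties** (exact equality, which arises in symmetric
  synthetic cases) break towards the precursor whose intensity-weighted
  profile centroid is nearest the fragment's; every tie is logged.
* **Recall's numerator** uses reference intensities, so that recall
  measures the recovered fraction of the reference's signal; the
  alternative (reconstruction intensities) would let intensity errors leak
  into a coverage metric.
* **NCE50** linearly interpolates the first downward 0.5-crossing in
  ascending NCE order; **profile distance** uses integer first/last scans
  at the level by default, with sub-scan interpolation behind a flag.
* Degenerate inputs fail loudly: empty templates, all-filtered peak lists,
  fewer than 3 scans, profiles never reaching the crossing level, and
  unresolvable precursors (no reference fragment in the template) are all
  errors, not warnings.

## Problem sizes used in the test suite

The packaged tests and the acceptance script run entirely on simulated
data at desk scale: 81-scan cycles, two precursors, 9–13 template peaks,
50-replicate oracle comparisons, and a 2 × 20-seed noise study for the
Δm/z degradation property. A full suite run takes well under a minute on a
single core.

## Known limitations

* Hard assignment only: no regression/mixture unmixing, by design — the
  correlation method is the object of study, and shared fragments are
  knowingly credited to a single precursor.
* Two or more precursors closer than `precursor_tol` (0.005 Th) collapse
  onto one template peak and cannot be separated downstream; the tool
  refuses rather than guessing.
* The mzML writer records the isolation window and collision energy but no
  vendor-specific metadata (AGC, microscans are pass-through config
  values, not emulated physics).
* Reference libraries must be recorded at the NCE of the series being
  evaluated; no cross-energy matching is attempted.
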