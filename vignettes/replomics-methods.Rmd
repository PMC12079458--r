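---
title: "Models, estimators and design choices in replomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in replomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(replomics)
```

This vignette is the package's own account of the science it implements:
what is being modelled, which estimators were chosen where the design was
genuinely open, what the synthetic data generator does and does not emulate,
and what a green test therefore does and does not establish. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement being emulated

In real-time localization microscopy of protein aggregation, fluorophore-
labelled monomers bind to a growing aggregate; each binding event is
localized with sub-diffraction precision and time-stamped by its acquisition
frame (30 s waiting time per frame, acquisitions of 2–3 h). The accumulated
point cloud reconstructs each aggregate and — because events arrive over the
whole occupied footprint at a rate proportional to its area — the event
cloud's occupancy tracks the aggregate's projected area over time.

Three growth archetypes are modelled, each with a piecewise-linear area law
A(t):

* **anisotropic spherulite** — an elongating dendritic ellipse (areal rate
  `r1`, aspect ratio ≥ 1) until a changepoint `t_switch`, then radial
  branching (rate `r2`) modelled as an exact Minkowski dilation of the
  frozen phase-1 ellipse;
* **isotropic spherulite** — radial growth at a single rate `rx`;
* **small aggregate** — growth at rate `r_small` until a termination time
  `t_term`, after which only a residual 2% of the binding rate remains
  ("only a few monomers subsequently bind"). Small aggregates are defined
  by a final projected area below 10 µm².

The footprint is represented as a convex polygon plus a disc dilation, so
all areas are exact by the Steiner formula and uniform sampling on the
footprint decomposes exactly into polygon, edge rectangles and vertex
wedges. Default rates are the field-typical values for human insulin at low
pH and 45 °C: `r1` = 1599, `r2` = 8073, `rx` = 29,211, `r_small` = 1170
nm²/s, `t_term` = 127 min. `t_switch` is not established in the field; the
default 3600 s was chosen once so both phases are well sampled in a 2–3 h
acquisition.

## 2. The synthetic-data generator: what it emulates, what it does not

Per frame, the number of new localizations is Poisson with mean
`binding_rate_per_area × A(t)`; positions are uniform on the current
footprint, jittered by the localization precision (default σ = 20 nm).
A field of view adds several aggregates (including an intertwined pair),
uniform false positives at half the signal photon count, and cumulative
stage drift. Identical seed and configuration give byte-identical tables.

Choices that deserve justification:

* **Binding density.** Nothing in the emulated experiments states the
  localization density. The default, 2e-6 events/(nm²·frame), integrates to
  ≈ 240 localizations/µm² over a 2 h acquisition (≈ 65 nm mean spacing) —
  the low end of typical SMLM reconstruction densities. A density of a few
  hundred events per aggregate per *hour* (an earlier working guess) would
  give ~10 events/µm², far too sparse to reconstruct anything; no estimator
  in this package (nor any other) could track area growth at that fluence.
* **Binding-site texture.** Events are not fully independent across frames:
  60% land near static, randomly placed high-affinity sites (density
  2.5e-5 /nm², 25 nm jitter). Real aggregate reconstructions are strongly
  textured (fibrillar substructure). This matters for one estimator in
  particular: redundant cross-correlation drift estimation has no sharp
  feature to lock onto if every frame resamples a smooth disc
  independently — with texture it recovers an injected 2 nm/frame drift to
  a few percent, without it it fails by microns. Texture can be disabled
  (`site_fraction = 0`).
* **The intertwined pair.** Two isotropic aggregates (`rx` = 1700 nm²/s)
  nucleate 3 µm apart, sized so their footprints meet in the final third of
  a 2 h acquisition — distinct origins, merged footprints, the stress case
  for dissection. Their true final areas (~12 µm²) deliberately sit near
  the 10 µm² class boundary.
* **Turbidity.** Logistic curves with rate k and plateau P; the tangent at
  the inflection crosses the baseline at `t_mid − 2/k`, so the inflection
  is placed at `lag + 2/k` and the generating lag *is* the tangent lag by
  construction. Per-replicate lag jitter (default 6 min in the standard
  panel, matching reported condition SDs) models plate-to-plate scatter on
  top of absorbance read noise (0.01 AU).

What the generator does **not** emulate: camera frames and PSF fitting
(localizations are the input currency), photophysics (blinking,
photobleaching kinetics), z-structure, non-uniform illumination, sample-
stage vibration beyond smooth drift, and any chemistry — rates are inputs,
not outputs of a mechanistic model. A green pipeline test therefore
establishes that the estimators recover the *stated statistical structure*,
not that they would survive every artefact of a real microscope.

## 3. Preprocessing

**Intensity filter.** The emulated false positives are dim (half the signal
photon count). When no threshold is given, an Otsu split of the 256-bin
log-intensity histogram is applied *only if* the histogram has a genuine
valley at the split (smoothed density < 25% of the smaller neighbouring
peak) and neither class is vanishingly small. Otsu alone happily halves a
unimodal histogram — on realistic data with < 1% false positives that would
discard half the signal, which is why the guard exists. With few false
positives the filter deliberately keeps everything and leaves them to the
density clustering, which marks isolated points as noise anyway.

**Drift.** Time-binned 2D histograms are cross-correlated against the first
bin (FFT, zero-padded against wrap-around), the integer peak refined by
parabolic interpolation, displacements interpolated linearly between bin
centres and anchored to (0,0) at t = 0. Reference = first bin and linear
interpolation are the standard, testable choices.

## 4. Incremental spatiotemporal segmentation

The concept: process the acquisition in 10-frame windows; in each window run
a density-clustering pass over all not-yet-assigned localizations acquired
so far, with every previously assigned localization as a fixed seed.
Density accumulates over time, so sparse new events on an existing
aggregate reach core status through the structure beneath them; assignments
are never revoked. This is a re-derivation of the concept behind published
incremental SMLM segmentation frameworks, not a port of any code.

Three mechanisms, added after watching the naive version fail, carry the
method:

1. **Young aggregates merge.** The growth front of a fast aggregate is
   always marginally dense (new area needs ~35 frames of fluence to reach
   `min_pts` within `eps`), so it sheds satellite pockets that briefly
   become aggregates of their own. An aggregate younger than
   `establish_windows = 6` windows merges into whatever it becomes
   density-connected with.
2. **Established aggregates dissect — if externally tangent.** A dense
   component bridging two *established* aggregates is dissected point-by-
   point along nearest-seed pathways, but only if the two look externally
   tangent: centroid separation ≥ 0.7 × the sum of their equivalent
   (uniform-disc) radii. Shards of a single structure — centroids buried
   inside the union — fail this test and merge. This single geometric rule
   is what separates the intertwined pair (ratio ≈ 0.75–1.0 throughout)
   from same-structure fragments (ratio ≈ 0.3–0.5).
3. **Rim sweep.** After the last window, unassigned points within `eps` of
   an assigned point join the nearest one (2 passes): the trailing growth
   front is individually sub-critical but sits on the structure.

`eps` defaults to 150 nm (not 100): at the stated binding density an eps of
100 nm needs ~80 frames of cumulative fluence before a region can become
core, which keeps the entire advancing front permanently sub-critical and
shatters it. 150 nm reduces maturation to ~35 frames; `min_pts` = 5, window
= 10 frames and link radius = 500 nm are unchanged defaults. With a single
window spanning the acquisition and the sweep disabled, the algorithm
reduces exactly to plain DBSCAN (the test suite checks this against an
O(n²) reference implementation).

`split_intertwined()` applies the same temporal-pathway idea post hoc to a
single cluster: density modes in the first `k_windows` windows, merged by
single linkage below 1 µm, then nearest-seed-pathway propagation — the
split is accepted only if the group centroid tracks stay externally tangent
(same 0.7 rule) in every window.

## 5. Morphology and kinetics estimators

**Occupancy areas, and why two grid sizes.** The area at time t is the
count of grid cells containing ≥ 1 localization with time ≤ t, times the
cell area (robust to dendritic shapes, where convex hulls overestimate).
Occupancy has two opposing biases: boundary cells inflate the count by
roughly perimeter × cell-size, and finite per-cell fill time (1/(rate ×
cell area)) lags the advancing front. Calibration on the generator showed
the best split is:

* **curve grid 300 nm** for growth-*rate* slopes (fill lag ≈ 170 s, small
  against phase durations; slopes recover `rx` to ~1%, `r1`/`r2` to a few
  percent, changepoint to < 10%);
* **fine grid 100 nm** for *kink timing* (termination detection) and the
  *final area* entering the 10 µm² classification cut, where boundary
  inflation — not slope fidelity — is the enemy. The fine grid undercounts
  very large sparse aggregates; that never matters for the decision
  boundary (~10 µm², where event density saturates a 100 nm grid) and the
  absolute area of large spherulites plays no decision role.

**Classification.** Small iff final area < 10 µm²; otherwise anisotropic if
the median axis ratio (√ of the covariance eigenvalue ratio) over the first
30% of the growth phase (5–95% of final area) reaches 1.8, else isotropic.
The 10 µm² cut is the field's; the axis-ratio cut and early fraction have
no published values and are exposed configuration.

**Two-phase fits.** Continuous piecewise-linear least squares (area curves
are physically continuous), changepoint by exhaustive search over interior
observed time points — no sub-grid interpolation, since the cadence is
already 30 s. A relative SSE improvement below 5% flags the fit degenerate
(both rates = the single slope).

**Termination.** Rolling-window OLS slopes (default window 400 s) are
smoothed with a 3-window running mean — occupancy curves advance in whole-
cell steps and a single new cell would otherwise spike an otherwise flat
window above threshold. The earliest window after which all slopes stay
below 0.2 × the maximum marks the plateau onset; the kink is then refined
by a local continuous two-phase fit re-centred up to three times. The
fallback (degenerate local fit) adds the deterministic straddle correction
f*·window with f*²(3−2f*) = 0.2. On the generator, detected terminations
sit within one 30 s cadence step of the true `t_term` for almost every
seed.

**Condition statistics.** Per archetype: n, mean rate and SE = SD/√n (SE is
the convention for these tables; a single fit reports SE 0 with an
`se_defined = FALSE` flag). Welch's two-sided t-test is implemented from
the closed form; the standard library's `t.test` serves as the independent
oracle in the tests, never as the implementation.

## 6. Turbidity lag

Lag = intersection of the tangent at the point of maximum smoothed slope
(centred 3-point differences) with the baseline (mean of points within 5%
of the minimum). The tangent method is the default because no canonical lag
operator is established for these assays; a threshold-crossing alternative
(5% of amplitude) is available. The estimate is offset-invariant and
clamped to the observed time range. On ideal logistics the tangent lag
equals the generating lag by construction (Section 2), so recovery to
within one 10-min grid step is a property of the estimator, not a fit.

## 7. Numerical and degenerate-input policy

* Rates are clipped at 0 (they are areal growth rates).
* Empty tables, empty clusters and flat curves return empty/`NULL`/errors
  as documented rather than NaN: an all-flat curve "terminates" at its
  start; a strictly growing curve has no termination; a flat turbidity
  curve raises a no-growth error.
* Zero-variance Welch comparisons: equal means give t = 0, p = 1; unequal
  means give p = 0.
* Ties in cluster linkage go to the lower (older) aggregate id;
  determinism throughout is seed-driven, and each generator call restores
  the caller's RNG state.

## 8. Known limitations

* The 10 µm² small/large call is applied to the measured localization
  footprint; with borderline objects (the intertwined pair's ~12 µm² true
  area) the measured class can differ from the generating archetype.
* Only one changepoint per growth curve; multi-stage pathways beyond
  two-phase are out of scope.
* Drift estimation requires persistent spatial texture; on hypothetical
  texture-free data it degrades (and the pipeline then silently skips
  correction only when bins are under-filled, not when texture is absent).
* The >90% segmentation-accuracy benchmark is computed on this package's
  own stated simulation world (Section 2), analogous to — not a
  reproduction of — the accuracy reported for the published framework on
  its own simulations.
* Real acquisitions are not distributed with the package; measured mean
  rates and lag values from the literature enter only as
  simulation-generating parameters, and all parameter-recovery claims are
  relative to those inputs.
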