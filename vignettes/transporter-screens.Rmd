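---
title: "Methods: chemical-genomics screens for yeast drug-uptake transporters"
author: "carrierscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-genomics screens for yeast drug-uptake transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierscreen)
```

# The screening logic

If a cytotoxic drug requires a plasma-membrane carrier to enter the cell,
a strain deleted for that carrier is relatively resistant: it keeps
growing where importing strains are poisoned. `carrierscreen` implements
the analysis for two platforms built on this logic — quantified
robot-spotted colony arrays of transporter deletion mutants, and barcoded
deletion-pool competitions — plus the growth-curve validation and
competitive-protection experiments that confirm a candidate carrier, and
the aggregation of all evidence into per-drug records.

The corollary of carrier-mediated uptake is protection: a non-toxic
natural substrate of the same carrier, supplied in excess, competes with
the drug for the shared binding site and restores growth. Both effects
are modelled here, so planted truths propagate end to end.

# Colony-array quantification

A test plate carries a 24 × 32 grid of 768 spots. The image analysis
follows four steps:

1. **Blue channel.** Colony signal is quantified on the blue channel of
   the RGB photograph. Grayscale images pass through with a note; RGBA
   images drop alpha.
2. **Window size.** From the manually identified corners of the spot
   grid, the window size is `max(width / n_cols, length / n_rows)`, kept
   as a real number.
3. **Diamond partition.** Window centers are laid on a bilinear lattice
   between the corners; each window is the L1 ball (a 45°-rotated square)
   whose diagonals equal the window size. Diamonds tile the lattice
   without overlap, and the corners of each cell — where neighbouring
   colonies bleed — belong to no window. Membership is tested at pixel
   centers `(x + 0.5, y + 0.5)` in 0-based coordinates, x rightward, y
   downward.
4. **Colony size.** Within each window, the colony size is the count of
   pixels with intensity *strictly greater than* 1.25 × the window
   minimum. Strict inequality makes a perfectly uniform (empty) window
   score 0 even when its minimum is 0, and referencing the window's own
   minimum makes the count invariant under uniform dimming of the window.
   Windows that clip to nothing at the image border yield a missing
   measurement rather than an error.

Corners are configuration, matching manual identification practice;
sub-pixel corner positions are supported. Tests use lossless PNG so that
a brute-force per-pixel oracle can require exact equality on every
window; JPEG input is accepted as-is for real captures.

# Hit calling

Edge spots — the WT buffer ring, 108 of 768 — are excluded everywhere:
border colonies grow larger for lack of neighbours, which would bias
plate statistics. For each strain the median of its four replicate spots
is taken (robust to one suppressor colony or one failed spot; fewer
replicates are tolerated with a note). The drug-plate median is divided
by the control-plate median and scaled ×100, so 100 means unaffected
growth. Strains with a zero control median cannot be normalized and are
excluded and reported.

Calls are z-scores against the mean and sample SD (n − 1; panels are
small) of all included scores. The WT control's interior replicates are
included in the plate statistics — the plate average is an average over
the plate — but flagged so hit reports can drop them. Resistant means
z > 3 by default, with 2.5 and 2 available to compensate for extreme
outliers inflating the SD; sensitive means z < −2.5. Inequalities are
strict. Because z-scores are affine-invariant, calls are unchanged by
rescaling all scores; and the resistant sets nest as the threshold is
relaxed. The output records how many calls each of the three thresholds
would have produced.

# Pool enrichment

Each strain's abundance is read out in arbitrary fluorescence units
(AFU). In place of the external array-normalization protocol used with
physical barcode arrays, conditions are total-sum scaled to the
across-condition mean total (declared in output metadata); proportions
within a condition are untouched. A strain is enriched when the treated −
untreated difference exceeds the noise-band halfwidth **and** the
treated/untreated ratio reaches the threshold: the band is a noise
estimate and the ratio lines are effect-size thresholds, so both must be
cleared. The conventional band is ±1000 AFU; alternatively the band is
estimated as the smallest halfwidth covering 98% (configurable) of
strains in an untreated-vs-untreated comparison. Both modes exist because
printed fixed bands and observed coverage bands are both common
practice. When the untreated AFU is zero the ratio is undefined and is
not imputed; the band criterion alone governs, with a flag. Ranking is by
treated AFU, descending, ties broken by strain id.

Note one scale subtlety: with a *fixed* band the calls are not invariant
to rescaling both conditions (the band does not rescale); with a
data-derived band the whole workflow is scale-free, and that is the form
in which scale invariance is tested.

# Growth curves, IC90, protection

Growth rates come from ln(OD600) via least squares. The blank is
subtracted first — by default the first reading; preferably a measured
media blank from a medium-only well, because the first reading also
contains the inoculum, and subtracting it makes ln(OD − OD₀) steeper
than the true rate just above the detection floor. Blanked ODs are
floored at 1e−4, and only readings above a detection floor (default 0.02
OD) are used: below it, the signal is measurement noise.

Two window policies are offered:

- **Sliding windows** (default, 5 samples = 50 min at 10-min sampling):
  among eligible windows, the one maximizing slope − 2 × SE(slope) is
  selected and its slope reported. The lower-confidence-bound rule
  reduces to the plain maximum on noiseless data (SE = 0) but refuses
  windows whose steepness is a noise artefact.
- **`"auto"`**: one fit over the whole detected log-linear band — samples
  above the detection floor and, for curves saturating well clear of it,
  below a tenth of the saturation plateau. For strongly inhibited
  cultures, whose 50-minute windows contain almost no signal, this pools
  hundreds of samples and is the robust choice; it is what the noisy
  IC90-recovery analyses use. Its known limitation is a curve saturating
  only just above the detection floor, where no early-exponential band
  can be isolated.

Dose–response profiles average μmax per concentration over replicates
(SEM reported, n = 3 in the emulated design). The Hill model
μ(c) = μ0 / (1 + (c/IC50)^h) is fitted by Levenberg–Marquardt least
squares with μ0 fixed at the zero-concentration arm (stabilizing small
panels; start values from the log-linearized model), and inverted at the
requested level: IC90 = IC50 · 9^(1/h). If the fit fails, monotone
interpolation on log concentration is used. Estimates are never
extrapolated beyond the measured range — an unreachable level is an
error that names the gap. Protection is quantified as
μ(drug + competitor) / μ(untreated), clipped at 0; under the
competitive model c_eff = c/(1 + [S]/Ks) it rises monotonically to 1 as
the competitor saturates the carrier. Final OD (blank-subtracted last
reading) is reported alongside, since yield can reveal protection that
growth rate misses.

# The synthetic-data generators

The generators define the study conditions; all downstream tests measure
recovery of planted truth under them.

- **Layouts.** A 16 × 24 master plate with a full WT border and each of
  the 111 catalog strains in exactly two interior wells (spare interior
  wells are filled with WT, never left empty); the 24 × 32 test plate
  with a full WT border, each master interior well mapped to two
  consecutive interior spots in row-major order. The source protocol does
  not state the geometric arrangement of the two spotting passes, and a
  column-interleaved scheme cannot tile a 16 × 24 master into a 24 × 32
  grid, so the sequential mapping is this package's convention; it
  preserves every stated property (768 spots, WT border, quadruplicates =
  2 wells × 2 passes). The packaged catalog combines the 29 transporter
  genes named in the study with 82 further well-known plasma-membrane
  transporter genes — a synthetic stand-in, since the full original list
  is not recoverable.
- **Plate images.** One disc per spot, centred in its diamond, radius
  proportional to relative growth (treated: fitness × (1 − inhibition)),
  drawn at 200 on a background of 40 in the blue channel, with
  multiplicative Gaussian intensity noise (sd 0.05). Border colonies are
  boosted ×1.3 (magnitude unstated in the source; a visible but moderate
  edge effect). Suppressor colonies — spontaneous resistant mutants, the
  classic false-positive mode of agar screens — are planted as full-size
  discs on Poisson(1) randomly chosen susceptible spots per treated
  plate. Radii are capped so a boosted colony stays inside its own
  diamond. The renderer returns true per-spot pixel counts for oracle
  tests. The geometry default (14 px per window) keeps a full plate
  render + quantification around a quarter second, so hundreds of seeded
  replicates fit in a routine test run; the rendering model is scale-free,
  and the quantification rule is tested at exact pixel equality at this
  size.
- **Pools.** Strains grow exponentially, n_i(t) = n_i(0)·exp(μ_i t), from
  equal proportions; μ_i is the WT rate (0.35 h⁻¹, typical of yeast in
  minimal glucose medium) × fitness × (1 − inhibition) in the treated
  arm. Each arm is integrated until total biomass reaches 100 × the
  inoculum, emulating sampling at the exit from exponential phase; the
  stop time is found by root-finding on the monotone total-biomass
  function, and final proportions match the closed form (verified against
  independent ODE integration in tests). Readout: AFU = 5×10⁵ × p_i ×
  ε_i with log-normal ε (sdlog 0.1) — positive-valued noise for a
  positive-valued measurement.
- **Growth curves.** Three phases: lag (2 h) at the inoculum OD (0.01
  above a media blank of 0.08), *exactly* exponential growth at μ(conc)
  until biomass reaches a tenth of the carrying capacity (0.9 OD,
  matching the untreated yields reported for this medium), then logistic
  saturation. The exact exponential phase is deliberate: it lets rate
  estimators be validated to machine precision. Curves run 72 h at
  10-minute sampling so strongly inhibited cultures still clear the
  detection floor; optional multiplicative OD noise. Hill defaults
  IC50 = 10 μM, h = 1.5; protection Ks = 5 μM.

What the generators do *not* emulate: spatial agar/nutrient gradients and
illumination fields, colony morphology beyond a disc, array saturation
and probe effects, pH/aeration dynamics of the fermenter, or
between-replicate biological variance beyond the stated noise models.
Passing planted-truth tests therefore demonstrates that the analysis
recovers signals under the stated statistical conditions — not that it is
robust to every artefact of real plates and arrays.

# Numerical choices and degenerate inputs

- Strict ">" at the 1.25 × minimum threshold and strict inequalities at
  the SD thresholds.
- Sample SD (n − 1). A zero plate SD yields no calls and a warning; a
  plate with under three scored strains is an error.
- Float tolerance of 1e−6 when testing window overhang at image borders
  (the bilinear lattice produces dust-level excursions).
- Root-finding (`uniroot`, tol 1e−12) for the pool stop time; the
  bracket is grown geometrically from the fastest-strain bound.
- Hill fit start values from the log-linearized model; h bounded below
  at 0.05, IC50 at 1e−9; μ0 fixed from the zero arm.
- Derived RNG streams: every generator seeds its own substream from the
  master seed and a stream label, so treated/control arms and replicate
  runs are independently but reproducibly randomized; derived seeds stay
  below 2³¹.
- Thresholds outside the conventional menus (3/2.5/2 SD; ratio 2/3) are
  accepted with a warning, never silently.

# Test and acceptance design

Every operation carries unit tests with frozen expected values computed
independently (closed forms, brute-force pixel scans, exhaustive-sort
percentiles, ODE integration); invariants (determinism, conservation,
monotonicity, affine invariance, threshold nesting, scale freedom) run as
property-style loops over seeded cases. Planted-truth recovery is
measured over 200 seeded replicates of each platform: the planted
resistant strain must be recovered in at least 95% of robot screens (with
at most one false positive per plate on average) and enriched-and-ranked
first in at least 95% of pool competitions. The acceptance script
recomputes the headline quantities from scratch at those replicate
counts; problem sizes (768-spot plates at 14 px windows, 112-strain
pools, 8-concentration dose–response panels, 50-seed noise studies) were
chosen as representative desk-scale versions of the emulated experiments.

# Known limitations

- The quantification has no illumination-gradient correction and no
  morphology features; it is faithful to the stated window rule only.
- Direct vs indirect classification of new hits is annotation-driven by
  design: deciding that a resistance phenotype acts through the drug's
  target rather than its import is expert curation, not computation.
- The windowed μmax estimator degrades on noisy, strongly inhibited
  curves (see the `"auto"` alternative); neither policy handles curves
  saturating barely above the detection floor.
- Pool simulations model deterministic exponential competition with
  readout noise only — no drift, no lag heterogeneity, no
  density-dependent interactions.
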