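---
title: "Quantifying cerebral artery wall mechanics and elastin band gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral artery wall mechanics and elastin band gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arteryMech)
```

# Scope

`arteryMech` implements three analysis layers that together characterise
remodeling of small cerebral arteries (anterior-cerebral-artery scale,
outer diameters around 2-2.6 mm):

1. **Passive biaxial mechanics** from extension-inflation myography:
   stretch and stress computation, exponential stress-stretch fitting,
   tangent stiffness, and estimation of the in-vivo axial stretch.
2. **Empty-band quantification** of elastin multiphoton projections: a
   grid-based area-fraction profile across the wall and detection of the
   low-signal band that forms at the media-adventitia interface.
3. **Cohort statistics**: group summaries of donor dimension tables,
   two-sample t-tests, one-way ANOVA, Bonferroni correction, and relative
   collagen abundances from label-free proteomics.

Because raw myograph exports and multiphoton stacks for such cohorts are
not redistributable, a fourth layer generates every input synthetically
from known ground truth, which is how the package's claims are tested.

# The mechanics model

A vessel segment is idealised as a thin-walled incompressible cylinder.
The reference (traction-free) state is measured once per specimen: outer
and inner radii `Ro`, `Ri` from ring perimeters (`R = perimeter / 2π`) and
the unloaded suture-to-suture length `L`. During a test the myograph logs
transmural pressure `P` (mmHg), deformed outer diameter (so `ro`, mm) and
axial force `fT` (mN) at a fixed axial stretch `λz = l / L`.

* **Kinematics.** Incompressibility fixes the deformed inner radius:
  `ri = sqrt(ro² − (Ro² − Ri²)/λz)`. The circumferential stretch is the
  mid-wall mean-radius ratio `λθ = (ro + ri)/(Ro + Ri)`.
* **Stress.** Mean Laplace-type Cauchy stresses:
  `σθ = P·ri/(ro − ri)` and `σz = (fT + P·π·ri²)/(π(ro − ri)(ri + ro))`.
  Pressures are converted with 1 mmHg = 0.133322 kPa; with forces in mN
  and lengths in mm both stresses come out in kPa (mN/mm²). The unit
  conversion lives in exactly one place (`mmHgToKPa()`) and the file
  readers validate units from column names (`pressure_mmHg`), because a
  silent mmHg/kPa mix-up is the most dangerous failure mode of this kind
  of pipeline.
* **Normalization.** `processRecording()` re-orders the cycle by
  increasing pressure and divides `λθ` by its value at the 0 mmHg point of
  the same cycle, so every curve starts at (1, 0). The anchor is located
  within ±0.5 mmHg of zero by default (`anchorTol`), since instrument
  exports rarely log exactly 0. A recording without such a point is an
  error, not a silently shifted curve. Repeated protocols conventionally
  keep only the final unloading cycle; the package analyses whatever
  single cycle it is given and leaves cycle selection to the caller.

## Exponential fit and tangent stiffness

Arterial stress-stretch responses stiffen roughly exponentially, so the
normalized curve is fitted with

σ(λ) = a · (exp(b·(λ − 1)) − 1),

which passes through (1, 0) exactly as a normalized curve must. The fit is
Levenberg-Marquardt least squares with a fixed initial guess (a = 1 kPa,
b = 1) and tolerance 1e-10, making results bit-reproducible. The tangent
stiffness is the analytic derivative `a·b·exp(b(λ − 1))` of the fitted
form — derived from the fit, not by differentiating noisy raw data — and
`stiffnessAtPressure()` evaluates it at the stretch reached at a given
pressure (linear interpolation between recorded points; extrapolation
outside the recorded range is refused). Near-linear data are legitimate
and simply produce a small `b`.

Both stresses are fitted against the same normalized circumferential
stretch axis; `direction = "longitudinal"` switches the ordinate only.
This is one of the genuinely open conventions in this kind of analysis;
the shared axis keeps circumferential and longitudinal stiffening
comparable point by point.

## In-vivo axial stretch

At the in-vivo axial stretch an artery's axial force barely changes
during inflation. "Variation" could be read as variance, range, or
max−min; the package uses the **variance** of the axial-force series over
the pressure ramp (the standard flatness measure) and breaks exact ties
toward the smaller candidate stretch, which is the conservative choice
for a quantity that trends upward with disease. The alternatives are a
two-line change on the recordings if a user wants them.

# The empty-band algorithm

The input is a grayscale maximum-intensity projection of the elastin
channel of a z-stack crossing the wall, rotated so the wall runs
vertically (radial axis horizontal). The steps:

1. **Binarize** (`binarizeImage()`): Otsu's threshold by default, a fixed
   cutoff optionally. Foreground always means *signal* pixels, regardless
   of whether a display renders signal black or white.
2. **Grid profile** (`gridAreaFractions()`): the ROI is discretized into
   a 30 × 30 grid; remainder pixels when the ROI is not divisible by 30
   attach to the last row/column so that total area is conserved
   deterministically. Each cell's foreground fraction is averaged down
   columns into a 30-value radial profile. The physical column width is
   the ROI width divided by 30 — 14.2 µm for a full 425 µm field of view.
3. **Threshold** (`bandThreshold()`): the band cutoff is the media mean
   minus two SD, floored at zero. With the cohort-level elastin area
   fractions measured for such projections (media 31.8 ± 8.5 %) this
   gives the reference cutoff of 14.8 %. For a single image the profile's
   own media columns can supply the statistics instead
   (`detectBand(profile)` with no threshold), but note that per-image
   column SDs are typically much smaller than cohort SDs, which makes the
   per-image cutoff higher and more prone to flagging a sparse media
   column; cohort-level statistics are the recommended default and are
   what the recovery tests use.
4. **Detection** (`detectBand()`): columns below the cutoff are flagged
   within the window from the start of the media range to the end of the
   adventitia range. A band is contiguous by definition, so the longest
   contiguous flagged run is reported; equal-length runs are disambiguated
   toward the media-adventitia boundary, where the band biologically
   forms. Width = run length × column width. No flagged column means
   width 0, not an error.
5. **Aggregation** (`sampleBandWidth()`): a sample's band distance is the
   mean over measurement locations, conventionally four (fewer warns).
   Locations may be four images or four ROIs of one image; both work.

Media/adventitia column ranges are supplied by the caller (or by the
synthetic generator's ground truth): layer annotation is a manual step in
practice and automatic segmentation is out of scope, as is any fiber
tracing or collagen-channel analysis.

# Cohort statistics

`groupSummary()` reports n, mean, sample SD (n − 1) and SEM, because both
mean ± SD (tables) and mean ± SEM (text) conventions coexist in this
field. Dimension summaries average over *segments* while age averages
over *donors* — a donor contributing two segments contributes one age —
which is why `cohortSummary()` takes an explicit `unit` argument. The
bundled reference cohort (`acaCohort()`) reproduces its printed Average
rows at display precision for all four groups under exactly this
convention.

Hypothesis tests are the standard ones (`stats::t.test` with pooled
variance by default, Welch optional; `stats::oneway.test` with equal
variances, so two-group F equals pooled t²; `stats::p.adjust` for
Bonferroni). `bonferroni()` takes an explicit family size `m` because the
tested family is often larger than the p-values at hand; it defaults to
`length(p)` but is a deliberate user decision for published families.
`relativeCollagenAbundance()` re-expresses per-sample collagen LFQ values
as percentages of each sample's total collagen, summing to 100 within
1e-9. FDR pipelines and gene-set enrichment are out of scope.

# The synthetic generators

* `simulateInflation()` forward-models a loading cycle from a known
  material law (circumferential `aθ(exp(bθ(λθ−1))−1)`, axial
  `az(exp(bz(λz−1))−1) + c(λθ−1)`): for each pressure the deformed outer
  radius solves thin-wall equilibrium by a bracketed root-find
  (feasibility bound + ε up to 3·Ro, tolerance 1e-12 — the bracket is
  guaranteed to straddle a sign change for stiffening laws), and the
  axial force is back-computed so the analysis stress formulas invert it
  exactly. Defaults aθ = 5 kPa, bθ = 12 put ~36 kPa of circumferential
  stress at 80 mmHg, the right magnitude for these vessels. Noiseless
  output is an exact fixed point of the analysis chain, which is the
  package's strongest self-test; Gaussian noise on diameter and force
  emulates transducer noise.
* `simulateStretchSweep()` produces one recording per candidate axial
  stretch with the force engineered flat at `lambdaZStar` (default 1.12,
  within the 1.10-1.13 range measured for such arteries) and a
  pressure-proportional slope of 20 mN/kPa per unit stretch away from it,
  so the variance criterion is minimized at the candidate nearest the
  truth by construction.
* `simulateWallImage()` renders a z-stack of a vertical wall: elongated,
  roughly wall-parallel elliptical fiber blobs stamped into media and
  adventitia strips until their target area fractions (defaults 0.318 and
  0.478) are reached within 0.03, a zero-signal gap strip of specified
  width between them, and Gaussian background noise (SD 0.03). Pixel
  values are quantized to 16-bit levels so TIFF round trips are
  bit-exact. Default geometry: 512 px over a 425 µm field (0.83 µm/px),
  strips of 40/160/150 µm for intima margin/media/adventitia.
* `simulateCohort()` and `simulateAbundances()` draw dimension records
  (Gaussian, truncated at zero) and log-normal abundance tables around a
  baseline composition with optional per-group shifts; zero dispersion
  reproduces the composition exactly.

What the images do **not** emulate: real fiber waviness and branching,
depth-dependent attenuation, the internal elastic lamella, partial-volume
effects, or uneven illumination. Passing the band-recovery tests
therefore shows that the *algorithm* recovers a known gap under realistic
area fractions and noise — not that any particular cohort's measured
band widths (which require the raw images) are reproduced. The same
caveat applies to the mechanics: the exponential law is a phenomenological
test harness, not a constitutive claim; there is no thick-wall analysis,
residual stress, viscoelasticity or active smooth-muscle tone.

# Numerical choices and problem sizes

* Root-find tolerance 1e-12; fit tolerance 1e-10 with fixed start
  (a = 1, b = 1); both recorded here so results are reproducible bit for
  bit.
* Degenerate inputs fail loudly with typed conditions
  (`infeasibleGeometry`, `degenerateWall`, `normalizationAnchorMissing`,
  `roiTooSmall`, `parseError`, ...), never coerce.
* All generators take a `seed` and restore the caller's RNG state.
* The shipped test and acceptance problem sizes — 9-point pressure grids,
  100 noisy fit replicates, 50 sweep replicates, 512-px images with four
  locations per gap width, 2,000-replicate null calibrations, 1,000
  random kinematic states — were chosen as the smallest sizes at which
  the Monte-Carlo tolerances quoted in the tests are comfortably stable
  across seeds.

# Known limitations

* Layer ranges for the band algorithm are user-declared; a mis-declared
  media range shifts the detection window accordingly.
* The per-image band threshold is sensitive to the media's cross-column
  SD; prefer cohort-level statistics when available.
* `stiffnessAtPressure()` interpolates stretch linearly in pressure
  between recorded points; coarse pressure grids coarsen it.
* The thin-wall stress formulas average across the wall; transmural
  stress gradients are invisible to them.
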