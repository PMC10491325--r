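# arteryMech

Passive biomechanics and wall-structure quantification for small cerebral
arteries (anterior-cerebral-artery scale), for vascular biomechanics labs
analysing pressure-myograph extension-inflation exports and multiphoton
images of the arterial wall — for example when tracking how cerebral
arteries stiffen and their elastic fiber network degrades across disease
stages.

The package covers three layers, plus seeded synthetic-data generators
that make every layer testable without instrument data:

* **Mechanics.** A vessel segment is a thin-walled incompressible
  cylinder. From logged pressure *P*, outer diameter (so *r*<sub>o</sub>)
  and axial force *f*<sub>T</sub> at axial stretch
  λ<sub>z</sub> = *l*/*L*:

  - inner radius: *r*<sub>i</sub> = √( *r*<sub>o</sub>² − (*R*<sub>o</sub>² − *R*<sub>i</sub>²)/λ<sub>z</sub> ) (incompressibility)
  - circumferential stretch: λ<sub>θ</sub> = (*r*<sub>o</sub> + *r*<sub>i</sub>)/(*R*<sub>o</sub> + *R*<sub>i</sub>)
  - stresses (kPa, with 1 mmHg = 0.133322 kPa):
    σ<sub>θ</sub> = *P·r*<sub>i</sub>/(*r*<sub>o</sub> − *r*<sub>i</sub>),
    σ<sub>z</sub> = (*f*<sub>T</sub> + *P*·π·*r*<sub>i</sub>²)/(π(*r*<sub>o</sub> − *r*<sub>i</sub>)(*r*<sub>i</sub> + *r*<sub>o</sub>))

  Curves are normalized to λ = 1 at 0 mmHg, fitted with
  σ(λ) = *a*(e^{*b*(λ−1)} − 1), and the tangent stiffness
  *a·b·*e^{*b*(λ−1)} is evaluated at any recorded pressure. The in-vivo
  axial stretch is the candidate whose axial-force series has minimal
  variance during inflation.

* **Empty-band quantification.** Binarized elastin projections are
  discretized into a 30 × 30 grid; per-column foreground area fractions
  form a radial profile, columns below the cutoff
  (media mean − 2 SD, e.g. 31.8 % − 2 × 8.5 % = 14.8 %) are flagged, and
  the longest contiguous run between media and adventitia is the band,
  reported in µm and averaged over measurement locations.

* **Cohort statistics.** Group summaries (mean, sample SD, SEM; donor- or
  segment-level units), pooled/Welch t-tests, one-way ANOVA, Bonferroni
  correction, and per-sample collagen abundances as percent of total
  collagen. A reference donor cohort table ships with the package
  (`acaCohort()`).

## Worked example

```r
library(arteryMech)

## reference geometry from ring perimeters; simulate one loading cycle
geom  <- radiiFromPerimeters(outerPerimeter = 8.1681, innerPerimeter = 6.2832, L = 12)
rec   <- simulateInflation(geom, constitutiveParams(), lambdaZ = 1.10, seed = 7)
curve <- processRecording(rec, geom)
fit   <- fitExponential(curve)
fit
#> ExponentialFit (circumferential): a = 5 kPa, b = 12, RMSE = 1.16e-11 kPa
round(stiffnessAtPressure(curve, fit, 80), 1)
#> [1] 792.9

## in-vivo axial stretch from force flatness over a candidate sweep
sw <- simulateStretchSweep(geom, constitutiveParams(), c(1.05, 1.12, 1.20), seed = 7)
estimateInVivoStretch(sw)
#> [1] 1.12

## empty-band width on a synthetic wall image with a 30 um ground-truth gap
sim     <- simulateWallImage(imageSpec(gapWidth = 30), seed = 7)
proj    <- maxProjection(sim$stack, sim$pixelSize)
profile <- gridAreaFractions(binarizeImage(proj), sim$regions)
detectBand(profile, threshold = bandThreshold(0.318, 0.085))
#> BandCall: threshold 0.148, 2 flagged column(s), band width 28.3 um

## cohort summary of the bundled reference table
print(cohortSummary(acaCohort(), "inner_diameter_mm"), digits = 3)
#>          group  n mean    sd    sem
#> 3        early  6 1.80 0.222 0.0905
#> 4 intermediate  4 1.80 0.241 0.1205
#> 1     advanced 10 1.87 0.153 0.0484
#> 2      control  8 1.98 0.198 0.0699
```

The fit recovers the generating material law (a = 5 kPa, b = 12) to
machine precision because a noiseless simulated recording is an exact
fixed point of the analysis chain; the tangent stiffness 792.9 kPa is the
fitted slope at the stretch reached at 80 mmHg; the 30 µm gap is read out
as 28.3 µm = 2 grid columns of 14.2 µm, i.e. within one column width of
truth.

A thin command-line wrapper over the same functions is installed at
`inst/cli/arterymech.R` with subcommands `simulate`, `mechanics`, `band`,
`cohort`, `abundance`; every run writes a manifest JSON (config, seed,
versions) next to its outputs.

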