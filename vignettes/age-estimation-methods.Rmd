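---
title: "Methods: simulated bone vibrational spectroscopy and chemometric age estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated bone vibrational spectroscopy and chemometric age estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Bone is a composite of carbonated hydroxyapatite mineral and a collagenous
organic matrix. During growth and maturation the mineral fraction rises, the
organic fraction falls, carbonate substitutes into the apatite lattice,
crystals grow and order, and immature divalent collagen crosslinks convert
into mature trivalent ones. Vibrational spectroscopy reads these changes
nondestructively: FTIR and Raman band intensities quantify specific
functional groups, and band ratios serve as standard bone-quality outcomes.
Because the compositional trajectory is age-dependent, spectra of cranial
bone carry information about chronological age, which matters for forensic
identification when bone fragments are all that remains.

This package implements that analysis end to end — but on *simulated*
cohorts, because the underlying measurement campaign (40 male donors, three
cranial-vault structures, FPA imaging plus point Raman) has no public data.
The simulator is a first-class, tested component: it generates spectra with
known ground truth so that every downstream stage (preprocessing, outcome
extraction, statistics, regression) can be validated against set-points
rather than eyeballed.

# The synthetic cohort generator

## Cohort design

`make_cohort()` draws 40 donors aged 0–74 y, stratified over six
developmental stages — 0–3, 3–12, 12–19, 19–35, 35–60, >60 years — with the
reference stage sizes 8/2/3/5/17/5. Other cohort sizes are apportioned by
largest remainder on the same proportions; any cohort of at least six
donors populates every stage. Stage intervals are left-closed/right-open
(the labels "3–12" and "12–19" overlap verbally; a convention is
mandatory, and age 12 belongs to "12–19"). Each donor is acquired at the
lamina externa, diploe and lamina interna, with 2 FTIR FPA images
(32 × 32 = 1024 pixels, 3850–400 cm⁻¹ at 4 cm⁻¹) and 3 Raman point spectra
(2000–300 cm⁻¹ at 1 cm⁻¹) per structure.

## Band model

Spectra are sums of pseudo-Voigt bands (Lorentzian mixing fraction 0.5 for
broad envelopes, pure Gaussians for narrow diagnostic sub-bands) at the
standard bone assignments: the phosphate ν₁ν₃ envelope, carbonate ν₂,
amide I/II/III, CH₂ wags on the FTIR side; phosphate ν₁/ν₂/ν₄, the
carbonate ν₁–phosphate ν₃ composite, proline/hydroxyproline and
phenylalanine rings on the Raman side. Two deliberate constructions carry
the width- and sub-band-based outcomes:

* FTIR crystallinity (I₁₀₃₀/I₁₀₂₀) rides on two narrow sub-bands — a
  crystalline 1030 cm⁻¹ component that grows with age and a disordered
  1020 cm⁻¹ component that shrinks.
* The Raman phosphate ν₁ peak is a narrow (σ 6.5) plus broad (σ 11)
  component pair at 958 cm⁻¹ whose balance shifts toward the narrow
  component with age, so the composite FWHM falls and crystallinity
  (1/FWHM) rises, in the observed 0.050–0.058 range.

## Age responses

Band amplitudes are modulated by bounded logistic functions of age,

$$w(a) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})\,
  \sigma\!\big(s\,(a - \mathrm{midpoint})\big),$$

rising for mineral and carbonate bands and falling for organic bands. The
logistic shape encodes rapid compositional change during maturation
followed by an adult plateau. Distinct processes get distinct midpoints and
rates — primary mineralisation (midpoint 18 y, steep), carbonate
substitution (18 y), crystal perfection (30 y, shallow), collagen turnover
(35 y, shallow) — for two reasons: it reflects the staggered biology of
peak bone mass versus crystal maturation, and it leaves usable age gradient
in the spectra beyond the mineralisation plateau, without which no method
could resolve ages in the 35–74 range. The mature-crosslink (1660 cm⁻¹)
sub-band uses a double-logistic dip-then-rise response, mimicking the
transient contribution of infant-specific collagen, so collagen maturity
first falls and then climbs.

The magnitudes are modelling choices, not measured claims; they were fixed
once at values that give outcome ranges on the scale reported for real
cranial bone (FTIR mineral/matrix ≈ 3–7, carbonate/phosphate ≈ 0.01,
crystallinity ≈ 1.02–1.06; Raman mineral/matrix ≈ 0.5–1.4, crystallinity
≈ 0.047–0.058) and remain configurable.

## Noise and artifacts

`noise_model()` layers, per modality: additive Gaussian detector noise
(0.003 absorbance / 8 counts), a jittered order-2 polynomial baseline
(FTIR), a broad fluorescence background of mean amplitude 400 counts with a
decreasing cubic shape (Raman), Poisson cosmic spikes (rate 0.5 per
spectrum, 800–4000 counts), lognormal per-pixel (sdlog 0.08) and
per-replicate (0.03–0.04) intensity jitter emulating scatter, lognormal
per-donor per-band amplitude variation (sdlog 0.05) creating biological
spread, and a 2% default fraction of bad FPA pixels — half dead (all-zero
columns), half over-absorbing, the latter rescaled against the
*baseline-corrected* signal profile so they are guaranteed to breach the
0.3 ceiling after the preprocessing baseline fit. The generator records
ground truth (band amplitudes, spike positions, planted bad pixels) on
every object, which is what makes oracle testing possible.

Seeding is hierarchical: one master seed is split deterministically per
donor/structure/replicate (`derive_seed()`), so any subset of a cohort is
reproducible in isolation and identical seeds give bit-identical output.

What the simulator does **not** emulate: physically calibrated absorbance,
ATR penetration-depth and contact effects, instrument line-shape functions,
atmospheric compensation residuals, structure-specific composition (the
three laminae share one composition model, consistent with the finding that
structure hardly affects these outcomes), sex or pathology effects, and
correlated (pink) detector noise. Green tests therefore certify the
machinery — not that real occipital bone behaves this way.

# Preprocessing

FTIR images: per-pixel order-2 polynomial baseline correction (single fit),
quality filtering on the maximum absorbance in 1724–1475 cm⁻¹ with
thresholds lo = 0 (exclusive — a flat-zero pixel is a dead element) and
hi = 0.3 (inclusive), cropping to the 800–1800 cm⁻¹ fingerprint, per-pixel
SNV (sample sd, n − 1), then averaging all kept pixels of the structure's
two images.

Raman replicates: Savitzky–Golay smoothing (11 points, order 3; edge
transients handled by the fit-matrix rows so cubics pass exactly), SNV,
cosmic-spike removal (running-median residual, robust z > 8, linear
interpolation), iterative third-degree polynomial baseline subtraction
(clip-to-fit, tol 1e-6, max 100 iterations), then averaging the three
replicates.

Two deliberate deviations from naive expectations, both numerically
documented in the test suite:

* **Step order.** The Raman chain applies SNV *before* despiking and
  baseline subtraction. That ordering is unusual — SNV on
  fluorescence-contaminated spectra mixes the background into the scaling —
  but it is the order this pipeline standardises on; `preprocess_raman()`
  takes a `steps` argument so the order can be changed and its effect
  measured rather than silently "fixed". A side effect of smoothing before
  despiking is that cosmic spikes are smeared over the filter window and
  are then only partially removable; replicate averaging absorbs most of
  the residue.
* **Ratio distortion by baseline fitting.** Polynomial baseline fits
  provably absorb part of broad bands even on baseline-free input (a
  least-squares polynomial through a spectrum is pulled up under wide
  peaks). On artifact-free synthetic input the artifact-targeted steps
  (smoothing, SNV, despiking) preserve band-area ratios to ~2%, while the
  full chain including the cubic baseline shifts the Raman mineral/matrix
  ratio by up to ~8%. This is an inherent property of baseline estimation,
  not a bug; outcomes remain monotone in age and the distortion is shared
  across a cohort processed identically.

# Outcome extraction

The four outcomes per modality, in the field's standard conventions: FTIR mineral/matrix
= area(900–1200)/area(1592–1712), carbonate/phosphate =
area(850–890)/area(900–1200), crystallinity = I(1030)/I(1020), collagen
maturity = I(1660)/I(1690); Raman mineral/matrix =
area(410–460)/area(1215–1300), carbonate/phosphate =
area(1050–1100)/area(930–980), crystallinity = 1/FWHM of phosphate ν₁,
collagen maturity = I(1660)/I(1690). Areas are trapezoidal with window
endpoints snapped outward to the grid (windows never shrink on a discrete
axis); intensities are linearly interpolated (the 4 cm⁻¹ FTIR grid does not
contain 1030/1020/1660/1690); FWHM finds the in-window maximum and the two
half-maximum flank crossings by linear interpolation, measured above the
local base (flank-region minimum).

Because SNV leaves each spectrum mean-zero, small-band areas — the FTIR
carbonate window above all — become sign-indefinite on SNV-processed
spectra, and intensity ratios can blow up where the signal crosses zero.
`compute_outcomes(shift = "min")` re-anchors the spectrum minimum at zero
before quantification; since the true spectral floor in the fingerprint is
near zero, this approximately undoes the SNV offset while preserving scale
invariance, and it is the default for cohort outcome tables. The signed
signal (`shift = "none"`) remains available for sensitivity analysis.

# Group statistics

Donors map to the six age stages; outcomes are compared across structures
and stages by one-way ANOVA with Student–Newman–Keuls pairwise comparisons
when per-group Shapiro–Wilk and Levene (Brown–Forsythe) diagnostics pass at
α = 0.05, otherwise by Kruskal–Wallis with unadjusted pairwise
Mann–Whitney U tests. The SNK test is implemented from the studentized
range over ordered means with step-down blocking (a pair nested in a
non-significant range is declared non-significant), which makes conclusions
independent of group ordering. Groups too small for a normality test
(n < 3) or with zero variance route to the nonparametric branch. FTIR and
Raman outcomes are correlated by Pearson's test, paired on
(donor, structure). Exclusions of individual (structure, stage, outcome)
cells — the response to a demonstrated structure effect — are an explicit
user-supplied list, never an automatic rule. No multiplicity correction is
applied across the eight outcomes, matching the conventional reporting
style for this design.

# Chemometrics

* **PCA** is mean-centered, unscaled, via the SVD.
* **PLS** is univariate-y NIPALS with X-only deflation: the reference
  algorithm, testable against least squares (with as many latent variables
  as the rank of X the predictions equal the OLS fit to 1e-6).
* **Venetian-blind 20-fold CV** assigns sample *i* (in row order) to fold
  ((i − 1) mod 20) + 1. Row order is donor-major, structure-minor as the
  cohort is assembled, which fixes fold composition; this is documented
  because the fold assignment depends on it. The latent-variable count is
  the first local minimum of RMSECV within one standard error (over folds)
  of the global minimum, capped at min(15, n/10) — a parsimony-biased rule
  chosen because the selection rule behind reported LV counts is generally
  unstated.
* **Kennard–Stone** (70/30) seeds calibration with the globally farthest
  pair under Euclidean distance and grows it by max-min selection, ties to
  the lower index; on 120 samples this gives exactly 84/36.
* **VIP** uses the standard formula; mean(VIP²) = 1 is asserted to 1e-10
  for every fitted model.
* **GA-PLS** evolves bit-vectors over contiguous variable windows
  (width 1 FTIR / 8 Raman at full scale) with venetian-blind CV RMSECV of a
  PLS model on the selected channels as fitness. Reference configuration:
  population 50, 200 generations, mutation 0.01, double (two-point)
  crossover, 50 replicate runs. Internals the recipe leaves open are fixed
  as: tournament selection (size 2), elitism 1 (making the best fitness
  per generation non-increasing), early stop after 30 stagnant
  generations, a 10-LV fitness cap, 10 inner folds, initial bit
  probability 0.3, and fitness memoisation (fitness is deterministic given
  the chromosome). Per-window selection frequency aggregates the run-best
  chromosomes; the final subset takes the smallest decile frequency cut
  whose subset minimises calibration RMSECV. Whether a published GA fitness
  used RMSECV or RMSEC, and whether reported R² values are squared
  correlations or 1 − SS_res/SS_tot, is generally ambiguous; this package
  uses RMSECV and 1 − SS_res/SS_tot throughout and says so.
* **build_age_model()** chains Kennard–Stone → (GA on calibration only) →
  CV on calibration → final fit → prediction-set metrics, and asserts that
  prediction samples enter neither selection nor calibration.

# Problem sizes and runtimes

The defaults used by the analysis scripts and the test suite were chosen so
every stage runs comfortably on one core: the full simulated cohort (40
donors × 3 structures; 240 FPA images = 245,760 pixel spectra plus 360
Raman spectra) simulates and preprocesses in well under a minute because
image generation and baseline correction are single matrix operations per
image. GA runs in the scripts and tests use reduced settings (population
20, ≤ 50 generations, 3–10 replicate runs, window width 5 FTIR / 24 Raman)
— coarser selection frequencies than the reference configuration but stable
selected regions; the full-scale configuration is available through
`ga_config()`.

# Known limitations

* The simulation validates the machinery, not the biology: real-data
  headline numbers (specific outcome means, model errors, counts of
  GA-selected variables) are not reproducible without the original
  spectra, and none are claimed.
* On simulated cohorts the 8-outcome panel predicts age about as well as
  the full spectra — outcomes are clean summaries of the generative model —
  whereas on real data locally extracted ratios discard information and
  underperform; this is a known divergence between simulator and reality.
* Collagen maturity is by design the weakest, least monotone outcome
  (dip-then-rise, small sub-bands); its FTIR–Raman correlation is
  correspondingly weak.
* The despiker cannot fully remove spikes once smoothing has widened them
  (see step order above).
* SNK p-values are computed from the studentized range at the pair's span;
  with unequal group sizes the Tukey–Kramer-style standard error is an
  approximation.
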