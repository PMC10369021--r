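---
title: "Methods: quantifying egg mimicry, host rejection and signature defence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying egg mimicry, host rejection and signature defence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggsig)
```

`eggsig` asks a single question in three stages: how faithful is a brood
parasite's egg mimicry at the population level, what rule do hosts use to
reject foreign eggs, and how often does a parasite egg survive that rule
when every host female lays her own distinctive egg type? This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions taken where the underlying methods literature leaves
choices open.

## Visual modelling

Reflectance spectra are integrated against an illuminant and receptor
sensitivities by the trapezoid rule on the receptor set's wavelength grid
(default 300–700 nm at 1 nm; spectra and illuminants on other grids are
linearly interpolated, and integration error at 1 nm is negligible
relative to the ±1% measurement repeatability typical of field
spectrophotometry). Von Kries normalization divides each channel by the
catch of a perfect white so that catches are relative quantum catches.

The receptor-noise-limited distance uses log receptor signals and channel
noise `e_i = w * sqrt(d_max / d_i)`. Defaults: Weber fraction `w = 0.1`
on the most abundant cone, single-cone density ratios 1:2:2:4
(UV:SW:MW:LW), achromatic Weber fraction 0.34. These are the conventional
behavioural estimates used for passerine-viewer modelling; they are
deliberately exposed in `receptor_set()` (and echoed by its print method)
because published JNDs are only comparable conditional on these values.
The built-in receptor set approximates a violet-sensitive tetrachromat
with Govardovskii A1 pigment templates at λmax = 432, 477, 537, 605 nm
plus a 567 nm double cone. Template curves are a reproducible stand-in
for measured sensitivities, which can be supplied as CSV when exactness
matters; ocular-media transmission is not modelled.

Two open choices were resolved as follows. The achromatic contrast uses
the log form `|ln(Q_a/Q_b)| / w_ach` rather than a Michelson-type
contrast, for consistency with the chromatic log-signal model; the two
agree to first order for small contrasts. Colour-space centroids are
means of tetrahedral (barycentric) chromaticity coordinates mapped back
to relative catches — with the luminance channel averaged arithmetically —
because averaging relative rather than absolute catches removes
brightness weighting from the "average egg" of a population.

## Pattern quantification

All pattern operators are mask-aware: pixels outside the egg mask never
influence any statistic (this is tested by randomizing the background).
Images follow one coordinate convention, stated once: matrices indexed
[row, column], origin top-left, major axis horizontal, blunt pole towards
increasing column unless declared otherwise.

* **Adaptive threshold.** A pixel is pattern iff it lies more than
  `offset` (default 0.05 in [0,1] brightness units) below the mask-aware
  local mean in a `window_mm` (default 3 mm) square. Pattern is defined
  dark-on-light only, because the eggs this workflow targets carry dark
  maculation on a paler ground.
* **Dispersion.** The egg is split into three equal-area bands along the
  major axis (terciles of the in-mask column distribution); dispersion is
  blunt-band coverage divided by overall coverage, so 1 is uniform and 3
  means all markings sit in the blunt third. The field literature
  describes pole concentration without giving a formula; the
  equal-area-tercile ratio was chosen because its extreme values have
  exact closed forms, which the tests pin down. A regression-slope
  alternative was considered and rejected as harder to oracle-test.
  Immaculate eggs have no markings to locate, so their dispersion is
  recorded missing and imputed as 1 (uniform) wherever the 5-D space
  requires a value — this keeps immaculate eggs inside the distance
  space, which the rejection analysis requires.
* **Granularity.** The image (mean-filled outside the mask) is Fourier
  band-passed into `n_bands = 7` octave bands of nominal marking size
  0.25–16 mm at the 19 px/mm standardization; each band keeps spatial
  wavelengths within a factor √2 of its size, and band energy is the
  variance of the filtered image inside the mask. Totals, the SD across
  bands, the maximum band (contrast) and the SD of the band-summed image
  (contrast variability) summarize the spectrum. Band edges are an
  approximation to the toolbox conventions used on real eggs; they are
  configurable for exact replication.
* **Feature detection.** Difference-of-Gaussian blob detection (3 scales
  per octave, σ spanning marking radii 0.15–3 mm, response threshold
  0.02) with scale-space non-maximum suppression; overlapping weaker
  candidates within 0.9 × the sum of radii are suppressed, a radius at
  which two genuinely disjoint markings can never fall. Feature area is
  `π(√2 σ)²` at the detection scale. There are no learned components and
  no RNG, so outputs are deterministic.

The multidimensional pattern distance is Euclidean in the 5-D space of
proportion pattern, dispersion, total energy, SD energy and feature
number. The scaling of those axes is the single most consequential
undocumented choice in this kind of analysis: the default z-scores each
trait over the pooled host + parasite population of the analysis at hand,
so no trait dominates through its units; a raw-units mode is provided
(`fit_distance_standardization(mode = "raw")`) and every fitted
standardization records its provenance. Likewise, model 1 uses absolute
trait differences by default (rejection should respond to mismatch
magnitude), with a `signed = TRUE` switch since the convention is not
fixed by the methods literature.

## Fidelity statistics

Repeatability is the one-way ANOVA intraclass correlation with the
standard unbalanced-design group-size correction; one-way (rather than
two-way) is the appropriate estimator for clutch repeatability, where
clutches are exchangeable groups with no crossed rater factor. Rank-sum
tests switch from exact enumeration to the tie-corrected normal
approximation above `n1 * n2 = 400`. The discriminant analysis uses
equal priors (so unequal sample sizes do not masquerade as
discriminability) and leave-one-out predictions; the optional Mahalanobis
outlier pre-filter uses the pooled within-class covariance with a
χ²(0.999) cutoff — removals are reported and reversible, and the
default is off. Fisher's exact test on the jack-knifed confusion matrix
asks whether assignment beats chance. The k-means morph labeller is a
convenience (25 seeded restarts on z-scored traits) and is not claimed to
reproduce any particular published morph classification, since real morph
boundaries are soft.

## Rejection models

Rejection is a binomial GLM (logit link, IRLS at R's default 1e-8
convergence tolerance). Perfect separation is detected (disjoint linear
predictors plus saturated fitted probabilities) and raised as an error
rather than returning divergent estimates. Reported fit statistics:
coefficients/SEs, AIC, a variance-function-based generalized R²
(Pearson-residual form, with the (n−1)/(n−p) adjustment) as the headline
adjusted R², and McFadden's likelihood-ratio R² as a labelled
alternative — the two can differ substantially for binary outcomes with
extreme fitted probabilities, which is why both are always reported.
Variance partitioning follows the all-subsets hierarchical partitioning
algorithm with deviance explained as the goodness-of-fit, capped at 8
predictors (2^k fits). VIFs come from the closed form on the design
matrix.

## Simulation

Each Monte-Carlo iteration samples one host and one parasite egg with
replacement (at most one egg per female, so prolific females are not
over-weighted), computes the pattern distance, and predicts rejection
from the fitted distance model. The default `"bernoulli"` mode draws
each event's fate and reports a Clopper–Pearson interval; the
`"expected"` mode averages predicted probabilities, with a delta-method
interval. Both are provided because a simulated "predicted rate" can
legitimately mean either; the law-of-large-numbers agreement between
them is tested. The monomorphic counterfactual collapses each species to
its centroid in the standardized space shared with the fitted model. The
fecundity projection is transparent arithmetic
(`eggs × (1 − rejection) × survival × lifespan`) with a two-significant-
figure display, using an 8-year lifespan as the conservative end of the
8–9 year estimate for a long-lived tropical parasite.

## What the synthetic generator emulates — and what it does not

`generate_population()` draws every trait on a latent Gaussian scale as
morph mean + female effect + egg effect, then transforms to the natural
domain (logistic for proportions, exp for positive traits, rounding at a
zero floor for counts). This preserves an analyzable variance
decomposition while respecting trait domains. The defaults encode the
study conditions the analyses assume:

* sample sizes 166 host and 28 parasite females, 3 eggs each — the
  sample scale of the field system this emulates;
* four soft morphs (immaculate, speckled, blotched, erythristic) with
  host weights (0.25, 0.35, 0.20, 0.20) and a parasite distribution
  shifted towards blotched (0.20, 0.30, 0.30, 0.20), the one
  population-level asymmetry reported in the field;
* between-female latent SDs roughly three times within-clutch SDs, which
  puts every trait's repeatability above the 0.69 regime reported for
  real clutches (the test suite verifies ICC > 0.69 trait by trait);
* erythristic ground colour with an elevated long-wavelength shoulder,
  and a small short-UV reflectance shoulder on host eggs only;
* rejection experiments paired within species, with outcomes drawn from
  `p(reject) = plogis(β0 + β1 D)`. The default (β0, β1) = (−1.8, 1.6)
  was back-solved once from the two operating points of the published
  fitted rejection model (35.9% rejection at distance 0.75, and a
  rejection probability near 93.7% at the typical distance between
  unrelated eggs, ≈3 pooled-z units) and then frozen. `candidates = 5`
  emulates the field protocol of giving hosts difficult decisions by
  pairing each host with the closest of five candidate eggs.

All generator randomness flows from a single seed per generator with a
documented draw order (morphs, female effects, egg effects, colour
noise), so every table, image and experiment set is a pure function of
its configuration. The generator does **not** emulate: photorealistic
shell texture or lighting, RAW-photo calibration, within-female morph
switching, observer error in outcome scoring, or covariance between
colour and pattern beyond what the shared morph induces. Passing tests
therefore demonstrate that the *algorithms* behave correctly under the
assumed statistical structure, not that the field system satisfies that
structure; field-scale estimates (discriminant rates, R², simulated
rejection percentages) require the field dataset, and the pipeline will
recompute all of them from conforming CSVs via `run_pipeline()`.

## Problem sizes and numerical tolerances

The shipped test and acceptance workloads use the generator's default
population (194 females, 582 eggs), 114-experiment designs, 1000-iteration
simulations, 50-replicate contrast checks and 200-replicate coverage
checks — sizes chosen to give Monte-Carlo standard errors comfortably
inside each asserted tolerance. Geometric image oracles allow for
discretization: disc coverage to ±0.02, blob counts to ±2 of truth,
dispersion extremes to the exact pixel-count ratio. Closed-form oracles
(receptor-noise distances, Fisher enumeration, VIF, Euclidean distance)
are asserted to 1e-10 or tighter.

## Known limitations

Receptor sensitivities are template-based unless measured curves are
supplied; the adaptive threshold detects dark-on-light pattern only; blob
detection merges markings that touch; the rejection models contain no
per-female random effects (each experiment is treated as independent);
and the simulation inherits any misfit of the logistic distance model.
These mirror the scope of the analysis chain the package implements, and
each is the natural next extension point.
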