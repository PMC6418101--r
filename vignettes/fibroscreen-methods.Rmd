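---
title: "Models and methods behind fibroscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibroscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscreen)
```

fibroscreen implements the quantitative stack of a phenotypic RNAi screen
in primary dermal fibroblasts together with the transcriptomic analysis
used to qualify such cells for screening. This vignette explains the
models, the defaults and the design decisions; it states no empirical
result beyond what the package's own tests and acceptance script compute.

## The ASMA score

The screen's readout is alpha smooth muscle actin (ASMA)
immunofluorescence, quantified per well as

$$S = \frac{D \times A}{N},$$

where $A$ is the number of ASMA pixels above threshold, $D$ the mean ASMA
intensity over those pixels, and $N$ the count of DAPI-positive nuclei.
Two points were genuinely open and are settled here as package decisions:

* **Density** is defined as the mean intensity over the *suprathreshold
  mask*, not over the whole field, so that $D \times A$ is the integrated
  suprathreshold intensity. This makes the product independent of field
  size and lets a fixed background be absorbed by the threshold.
* Quantification is **per field**, with no assignment of stain to
  individual cells; nuclei enter only through the normaliser $N$. Wells
  with $N = 0$ have an undefined score, are flagged
  (`score_defined = FALSE`) and are excluded from control statistics with
  a warning.

`segment_nuclei()` thresholds the DAPI channel (Otsu on the
\[0, 1\]-normalised image by default, or a fixed AU threshold), labels
connected components with 8-connectivity and discards components below
`min_nucleus_area` (default 9 px). A constant image has no Otsu separation
and yields zero nuclei — a documented degenerate case, not an error.
Touching nuclei merge; under-segmentation is accepted behaviour, since the
score is a ratio of field aggregates and mild under-counting affects both
controls alike. No watershed splitting or illumination correction is
attempted. Background subtraction is deliberately absent: thresholding
absorbs a constant background, and the score is invariant to sub-threshold
background shifts (a property test asserts this).

## Plate quality control

Per donor, negative-control wells (GFP shRNA) and positive-control wells
(ACTA2 shRNA) give

$$Z' = 1 - \frac{3(\sigma_- + \sigma_+)}{|\mu_- - \mu_+|}, \qquad
\text{window} = \mu_- / \mu_+ .$$

The Z′-factor is the standard screening quality statistic; the assay
window is read as the ratio of control means, the conventional
interpretation of a "fold" window. Sample standard deviations use the
$n-1$ denominator. Defaults gate a donor at Z′ ≥ 0.3 and window ≥ 2-fold,
the lower edge of the band a screenable primary-cell assay occupies. Both
statistics are invariant under common rescaling and common shifts of both
arms, and Z′ strictly decreases in either arm's spread — these invariances
are asserted as tests.

Percent inhibition is control-normalised per donor,
$100 (1 - \bar{S}_\text{test} / \bar{S}_\text{neg})$, using means rather
than medians so that inhibition, Z′ and the window rest on the same
location/scale estimates (a median variant sits behind `use_median`).
Knockdown percentages from expression panels are $100(1 - r)$ for relative
expression $r$; threshold summaries use strict inequalities, reading
"more than 60%" literally.

## Hit tiers

Genes are graded from their per-shRNA cross-donor mean inhibition by
count-and-threshold rules (`tier_rules()`; defaults
$t_{lo}, t_{mid}, t_{hi} = 25, 30, 35$ percent):

* **very strong** — ≥ 8 hairpins above $t_{hi}$;
* **strong** — ≥ 2 hairpins above $t_{hi}$;
* **moderate** — ≥ 1 hairpin above $t_{hi}$ and ≥ 1 in the open interval
  $(t_{lo}, t_{mid})$;
* **weak** — ≥ 3 hairpins in $(t_{lo}, t_{hi})$;
* otherwise **none**.

Three decisions were open and are settled here: tiers are evaluated in
precedence order (very strong first) so a gene receives its
best-supported label; all interval endpoints are strict, reading "more
than" / "less than" literally; and cross-donor averaging is unweighted
even when donors contribute unequal well counts, since the design averages
donors symmetrically. The very-strong count (8) describes rather than
defines that tier, so it is configurable. One ambiguity is flagged rather
than guessed: a gene with one hairpin above 35% and none in (25, 30) —
e.g. means of 36 and 24 — is classified `none` under the literal rules. The
classifier is verified against an independently coded brute-force
predicate evaluator on 10,000 random vectors, and tier monotonicity under
raising any hairpin's inhibition is asserted for the monotone tiers (the
moderate tier requires a mid-low hairpin and is intrinsically
non-monotone).

## The transcriptomic stage

**Batch correction.** `batch_correct()` is a parametric empirical-Bayes
location/scale adjuster: per-probe models with the protected covariate are
fitted, data are standardized, per-(probe, batch) locations
$\hat\gamma$ and scales $\hat\delta^2$ are estimated and shrunk toward
across-probe priors (normal on $\gamma$, inverse-gamma on $\delta^2$,
moment-matched, solved by the standard fixed-point iteration), and the
data are adjusted and restored. It is implemented in the package so that
the shrinkage parameters are first-class outputs (`tidy()` returns raw and
shrunken estimates per probe and batch); the test suite cross-checks the
corrected matrix against the independent reference implementation in the
`sva` package to near machine precision. A single batch is a no-op;
a covariate perfectly confounded with batch is refused.

**Differential expression.** `moderated_de()` delegates the per-probe fits
to limma (`lmFit`/`eBayes`) — the canonical moderated-t machinery — in
two-group or paired form (paired fits are one-sample fits on within-pair
differences). The composite significance rule is applied on top with
strict gates: $|\log_2 FC| > \log_2 1.5$, BH $q < 0.01$, log-odds $B > 0$
and average log2 intensity $> 4$. The prior proportion of differentially
expressed probes behind $B$ is nowhere standardised; the default is 0.01,
configurable, and the $B > 0$ gate mainly trims marginal calls. The
`avg_expr` column is the row mean of the analysed samples (not of the
pair differences) so the intensity gate has its intended meaning in
paired designs. Replicate hybridisations are excluded before fitting, as
they exist to estimate batch effects, not to add degrees of freedom.

**Signature retention.** `compare_signatures()` reports the baseline and
follow-up DEG counts, their overlap, retention as
$100 \, n_\text{overlap} / n_\text{base}$ (rounded to an integer percent
for reporting; the exact value is also returned) and the Pearson
correlation of the two log2-fold-change vectors over the *union* of the
DEG sets. Retention is computed on probes, the unit the pipeline actually
works in; when a probe-to-gene map is available, `collapse_probes()`
keeps the maximum-$|\log_2 FC|$ probe per gene first. Outlier samples are
handled by explicit exclusion (subset the metadata), never by automatic
detection.

## What the synthetic data emulate

The generator exists because the assay design — not any public dataset —
is what the pipeline must be validated against; every simulated entity
carries a ground-truth record.

**Screens** (`simulate_screen()`): negative-control scores are lognormal
with mean 1 and CV `cv_noise` (default 0.10), positive controls with mean
`1/fold_separation` (default 3, the middle of the 2–4-fold window a
working assay shows), test hairpins with mean
$1 - e\,(1 - 1/\text{fold\_separation})$ for efficacy $e$, all scaled by a
per-donor lognormal random effect (sdlog 0.1) chosen to mimic visible
donor-to-donor variability without per-donor tuning. The default design
uses 120 wells per condition per donor, the replication level at which
control statistics stabilise. Density, area and nuclei are decomposed so
$D \cdot A / N$ reproduces the drawn score exactly, keeping table- and
image-based pipelines interchangeable. An optional additive transduction
offset exists because viral transduction itself can raise ASMA; no
magnitude is established for it, so it defaults to 0. Seeding-density
kinetics, serum effects and adenoviral biology are deliberately not
modelled — they enter only through these score-level parameters.

**Knockdown panels** (`simulate_knockdown_panel()`): hairpin efficacy is a
two-component mixture — with weight 0.8 a truncated normal
$\mathcal{N}(0.84, 0.10^2)$ on \[0, 1\], else uniform on \[0, 0.6\] —
calibrated so the analytic tails give ≈ 79% of hairpins past 60% knockdown
and ≈ 64% past 75%, the performance band of an effective adenoviral shRNA
platform. `efficacy_tail()` exposes the closed form used to verify the
Monte-Carlo behaviour. The default panel is 31 genes × 2–4 hairpins
(103 shRNAs). Measurement noise reuses `cv_noise` as a per-donor
multiplicative CV; 0 disables it.

**Well images** (`render_well_image()`): nuclei are isotropic Gaussian
spots at rejection-sampled centres honouring a minimum separation; ASMA is
one anisotropic Gaussian stroke per cell (random orientation) with peak
amplitude linear in `asma_level`; background is constant; noise is
Poisson shot noise plus Gaussian read noise, both switchable. The default
minimum separation (24 px for a 4 px spot sigma) is chosen so that the
*suprathreshold footprints* of adjacent spots stay disjoint under Otsu
thresholding — Otsu sits close to background in a sparse field, so
footprints are wider than the visual spot — which is what makes exact
noise-free nuclei recovery a testable guarantee rather than a tendency.
Real images differ in ways the renderer does not attempt: non-uniform
illumination, cell-shape variation, clumping, focus drift. Passing tests
therefore certify the quantifier's logic (thresholding, labelling,
linearity, invariances), not vendor-grade segmentation performance.

**Expression studies** (`simulate_expression_study()`): log2 intensities
are per-probe baselines (uniform on 5–11, so the intensity gate at 4 acts
only through noise) plus a signed disease effect on signature probes
(|log2FC| uniform on 0.6–2.0), plus per-(probe, batch) additive shifts
($\mathcal{N}(0, 0.4)$) and residual-scale distortions (uniform
0.8–1.25), plus $\mathcal{N}(0, 0.25)$ residuals. At the follow-up
passage a fraction $\rho$ (default 0.77) of signature probes keep their
full effect; the rest are attenuated to 25% of baseline — attenuated
rather than erased, so non-retained probes fail the significance gates
while still correlating weakly with baseline fold changes, reproducing the
strong-but-imperfect concordance such studies show. Nine samples are
hybridised in both batches (the replicate anchor for batch estimation);
default group sizes are 8 disease and 8 healthy donors per passage,
paired across passages, with 2000 probes of which 200 carry signal —
sizes at which the moderated pipeline has high power on the smallest
effects while the whole retention analysis runs in well under a second.

## Numerical and reproducibility choices

* One master seed per config; per-stage streams are derived from it so
  stages can be rerun independently. RNG state is saved and restored
  around every generator call.
* Truncated-normal draws use inverse-CDF sampling, which degenerates
  exactly to a point mass as the sd goes to 0.
* Lognormal well noise is parameterised to have unit mean at any CV
  ($\mu_{\log} = -\sigma_{\log}^2/2$), so `cv_noise = 0` gives exactly the
  configured means.
* The EB fixed-point iteration stops at a relative change of $10^{-4}$
  (cap 100 iterations); pooled variances are floored at $10^{-12}$ to
  survive constant probes.
* Images are 16-bit; TIFF round-trips are exact up to 1 AU quantisation.
  A clip-fraction warning fires if more than `max_clip_fraction` of
  pixels saturate.
* Ties in hit ranking break lexicographically by shRNA id, making ranks
  stable and platform-independent.

## Problem sizes in the shipped checks

The test suite and acceptance script run the screens at their native
design size (12 donors × 240 control wells; 1000-hairpin panels), the
retention analysis at 2000 probes × 32 biological samples over 20 seeds,
the image property checks at 160–192 px fields over 50 seeds, and the
classifier oracle over 10,000 random vectors — sizes chosen so each check
exercises the statistics it targets while the whole suite completes in
well under a minute.

## Known limitations

* The renderer and quantifier are per-field; assays that need per-cell
  ASMA attribution (e.g. heterogeneous subpopulations) are out of scope.
* No plate-spatial normalisation (B-scores) or dose–response fitting;
  wells are exchangeable within a condition by construction.
* The retention analysis treats probes as the unit; gene-level retention
  depends on the probe→gene map supplied.
* Hit tiers are descriptive classifications, not significance statements;
  no multiple-testing machinery is attached to them, by design.
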