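---
title: "Methods: quantifying growth and developmental toxicity in Dictyostelium"
author: "dictytox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying growth and developmental toxicity in Dictyostelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictytox)
```

## The system and the problem

*Dictyostelium discoideum* grows as a unicellular amoeba and, on starvation,
executes a 24 h multicellular developmental program: aggregation (streaming),
mound, migratory slug, culminant and finally a fruiting body with stalk and
spore cells. Because growth and development are experimentally separable, the
same compound can be scored for general cytotoxicity (slowed vegetative
growth) and for developmental toxicity (blocked, delayed or weakened
progression through the stages). The ratio between the two dose thresholds is
the basis of a teratogenicity classifier, and pooled insertional-mutagenesis
(REMI-Seq) screens attach a genetic phenotype to a compound: which mutants
become resistant or hypersensitive under drug selection.

`dictytox` implements that whole analysis surface: doubling-time estimation
from time-lapse cell counts, NOAEL/LOAEL calling, stage-reporter fluorescence
analysis, the ratio classifier with predictivity metrics, screen selection
statistics, and validation-assay scores. A synthetic-data module generates
every input with the statistical structure the analyses assume, so the full
pipeline is exercised end to end without any external data.

## Growth toxicity

### Doubling-time estimation

Per-frame cell counts from time-lapse films are fitted by log-linear least
squares, `ln(count) ~ time`, and the doubling time is `ln(2)/slope`. The
exponential phase is located automatically: all contiguous sub-windows of at
least 8 h inside the 8–48 h range (with at least 5 points) are fitted, and
the selection prefers the *longest* window whose r² is within a tolerance of
the best window's r². The tolerance scales with the best fit's residual
variance, `min(r2_tol, 3 * (1 - max(r2)))` with `r2_tol = 0.15`:

* for noiseless data the tolerance vanishes and the selection reduces to a
  pure argmax of r², which recovers exact exponentials exactly (doubling
  time 10 h in, 10.0 h out, r² = 1);
* for noisy counts a pure argmax systematically favours short windows that
  fit the noise rather than the trend — in simulations it halved the
  estimated doubling time — while phase transitions (lag, saturation at the
  carrying capacity) depress r² by far more than counting noise does, so they
  still force the window away from the non-exponential phases.

A known limitation: when a well saturates *inside* the fit range under heavy
count noise, part of the saturation knee can slip into the selected window
and bias the doubling time upward by 10–20%. Narrow the `window` argument for
such wells.

Wells with a non-positive best slope (including constant counts) are flagged
`no_growth` rather than given a doubling time; fewer than 4 usable points is
an error.

### Dose anchoring and ladders

Dose ranges are anchored on the rat oral LD50 converted to molarity under
the assumption that 1 kg of body weight is equivalent to 1 litre, so
mg/kg ÷ g/mol = mmol/L (`anchor_dose_from_ld50()`). The development ladder
places three doses 5-, 25- and 125-fold below the anchor and two doses 5- and
25-fold above it; the first-pass growth ladder is geometric over a
configurable fold range (default 100-fold, 6 doses).

### NOAEL/LOAEL calling

A dose is adverse when its replicate endpoints (doubling times) differ from
the vehicle control by a two-sided Welch t-test at `alpha = 0.05` *and* the
difference is in the adverse direction — only a doubling-time *increase*
counts, since slowed growth is the toxicity readout. The LOAEL is the lowest
adverse dose, the NOAEL the highest tested dose below it; when no dose is
adverse the NOAEL is censored at the maximum tested dose. Non-monotone
responses keep the lowest adverse dose as LOAEL and emit a warning.

Two deliberate design choices sit on top of the plain significance rule:

* `call_noael_loael()` accepts a `min_effect` floor (fractional doubling-time
  increase). The default is 0 — significance alone decides — but the
  end-to-end pipeline uses `min_effect = 0.2`. With three replicate wells
  per dose and ~70 dose-control comparisons per cohort, a pure α-level rule
  produces on the order of two false adverse calls per run (one-directional
  type-I rate ≈ 2.5% per dose), each of which can shift a LOAEL a full
  ladder rung and flip a classification. Requiring a 20% effect in addition
  to significance — the same significance-plus-effect-size logic used by
  differential-expression tools — removes these while leaving the planted
  2-fold effects untouched.
* In the developmental assay the pipeline's per-dose adverse flag is, by
  default, *loss of a reporter expression profile* (`adverse_classes =
  "absent"`). Timing and strength t-test calls are computed and reported per
  reporter, but six reporters × two tests per dose would carry a ~46%
  per-dose false-adverse probability at α = 0.05 if any significant test
  made the dose adverse. Widen `adverse_classes` when timing defects should
  drive the NOAEL.

## Developmental reporter analysis

Each stage reporter's fluorescence course (13 points, 0–24 h every 2 h,
three replicate developments) is normalized to its replicate's total signal,
so normalized values sum to 1 and the across-course mean is exactly `1/T`. A
reporter has a *developmental profile* when the across-replicate mean at any
time point reaches `threshold / T`, with the per-reporter threshold
calibrated on vehicle controls as the highest value on the 1.1–1.6 grid
(step 0.1) at which every control development still shows a peak. Detection
is monotone in the threshold, and the calibrated value is maximal: one grid
step higher fails at least one control.

Comparing treated and control courses yields one of six calls: `absent`
(control has a profile, treated does not), `delayed`/`advanced` (Welch t-test
on per-replicate peak times), `attenuated`/`elevated` (Welch t-test on
per-replicate peak values), or `normal`. When both tests are significant the
timing call takes precedence; both p-values are always reported. A control
without a profile invalidates the assay, mirroring the manual inspection rule
that control developments must have progressed normally. Cell-type
proportioning (prespore/prestalk marker ratio at 24 h against wild type) is
only computed when the fruiting-body reporter is called `normal`, because an
incomplete development makes the 24 h ratio meaningless.

Agreement between qualitative (morphological) and quantitative (reporter)
call matrices is tallied under three pooling rules: strict identity; timing
defects pooled with absence; and all defects pooled (any-defect agreement).

## Teratogen classification and predictivity

The teratogenic-potential ratio is growth LOAEL ÷ development NOAEL, both in
mol/L; a ratio ≥ 10 (boundary inclusive) classifies a compound as a
teratogen. Where growth toxicity never reached significance at the highest
soluble dose, the censored growth NOAEL substitutes and the substitution is
recorded.

Predictivity metrics use the teratogen class as positive: sensitivity
100·TP/(TP+FN), specificity 100·TN/(TN+FP), PPV 100·TP/(TP+FP), NPV
100·TN/(TN+FN), concordance 100·(TP+TN)/N. The *overall predictive value*
is implemented as the arithmetic mean of PPV and NPV — the definition that
reproduces the reported performance rows from their confusion counts.
Metrics with empty-class denominators are reported as undefined (`NA`),
never as 0. Values are stored at full precision and rounded to integers for
reporting. For the growth-LOAEL-defined subset (TP=15, FP=2), the PPV
implied by the counts is 15/17 ≈ 88%; the package computes that value and
flags (in this document) that it differs from the externally reported 83,
which is not reproducible from the same counts.

Cross-model dose datasets are converted from mg/kg with the same 1 kg ≈ 1 L
rule, taking the lowest value when literature sources disagree. Pairwise
Pearson correlations are computed on log10 molar doses — molarities span
more than five decades, so linear-scale correlation would be dominated by a
few large doses (a linear-scale option exists) — and only for endpoint pairs
sharing more than 3 compounds; smaller overlaps are reported untested.
Phenotype-vs-dose comparisons use one-way ANOVA on log10 NOAEL across stage
groups, or a Welch t-test for two-group comparisons.

## Pooled-screen selection analysis

Raw insertion read counts are summed over sequence tags per insertion point,
cleared of non-uniquely mapped records, and scaled to reads per million per
sample, making the matrix depth-invariant. Mutants are binned by their mean
control (DMSO/vehicle) count — below 100, 100–1000 inclusive, above 1000 —
so that Z-scores compare mutants of similar sampling depth. For each
replicate, the log2 fold change against the control-replicate mean (with
pseudocount 1) is standardized within its (bin, replicate): these Z-scores
have mean 0 and SD 1 by construction.

Advantaged mutants require z > 1.5 in *both* biological replicates at round
5 (resistance accumulates over ~17.5 generations of selection);
disadvantaged mutants require z < −1 in both replicates at round 2, and the
lowest-abundance bin is excluded from the disadvantage analysis because its
technical dropout rate is high. A mutant meeting both criteria is flagged
conflicting and excluded from both sets, keeping them disjoint.

Two statistical consequences of this design worth knowing:

* Because both replicate fold changes share the control-mean denominator,
  their sampling noise is correlated at ρ = 1/3. The neutral
  both-replicates call rate is therefore the joint probability under that
  correlation, roughly twice the independent-replicates product — the test
  suite checks the rate against the correlated-normal oracle.
* Z-standardization is *within bin*; a bin with fewer than 3 members leaves
  its mutants neutral with a warning rather than fabricating a Z.

Gene assignment is strand-aware: intragenic insertions go to the host gene;
intergenic insertions at most 500 bp upstream of a transcription start go to
that gene (nearest start when two divergent genes both qualify, logged);
other intergenic insertions get no gene. Insertions in tRNAs, pseudogenes or
transposable elements, and blacklisted genes (e.g. generic axenic-growth
mutants), are removed from gene lists symmetrically for both directions.

List comparisons use the upper-tail hypergeometric probability of the
observed overlap (gene-level universe, carrying the same exclusions as the
lists); rank-quartile enrichment splits one screen's Z-ranking into
quartiles (sizes differing by at most one, ties broken by stable mutant-id
order) and tests the other screen's hits against uniformity with a 3-df
chi-squared; GO over-representation is per-term hypergeometric at p < 0.05
with no multiplicity correction by default (Benjamini–Hochberg available),
matching the screening-stage convention of treating the term list as
exploratory.

## Validation assay scores

Competition assays against a GFP-labelled wild type are normalized to their
intended 50:50 start by rescaling each round's odds so the round-0 fraction
is exactly 0.5 — an odds rescaling rather than a subtraction, because it
preserves the [0, 1] range. The fitness score is the mean over rounds 3 and
the final round of log2(normalized drug fraction / normalized vehicle
fraction); fixation values are floored at `1/(2 × cells measured)` so the
log stays finite. The score is 0 for coinciding trajectories and
antisymmetric in the two conditions.

The fluid-uptake score compares macropinocytosis inhibition between a test
mutant and a control mutant: each strain's fold-change reduction is
untreated MFI / treated MFI, and the score is log2(mutant fold reduction /
control fold reduction). Both scores use log base 2 throughout.

## The synthetic-data module

The generators produce data with the structure the analyses assume, under a
single master seed (identical seeds give byte-identical tables; all
sub-seeds derive from the master seed):

* **Growth films**: lag phase, exponential growth at a configurable
  doubling time, a carrying-capacity cap, and Poisson-lognormal count noise
  (overdispersed counts are the norm for microscopy segmentation). With
  `count_noise_cv = 0` the exact deterministic expectation is returned,
  which the closed-form test oracles rely on. Default conditions: 3
  replicate wells, 1 h framerate over 48 h, ~50 cells per frame initially.
* **Reporter courses**: a Gaussian bump on a constant baseline, with
  stage-specific centres/widths following the reporters' qualitative
  timings (initiation maximal at 0 h and decaying; streaming from ~6 h;
  mound from ~12 h; a sharp slug rise at 12–16 h; culminant after ~20 h;
  fruiting body only at 22–24 h). The two broad "rising" reporters are
  bumps rather than saturating sigmoids: a saturating course pins its
  argmax at 24 h, which would make a planted developmental delay invisible
  to the peak-time statistic the assay uses; a broad late-centred bump
  preserves both the rising character and delay recoverability. Treatments:
  a block at a stage zeroes the bumps of all downstream reporters, a delay
  shifts the bump centre, attenuation scales its amplitude. Measurement
  noise is multiplicative lognormal with CV 0.05 by default — no noise
  magnitude is prescribed by the assay itself, so this is a free parameter
  surfaced in the generator arguments.
* **Screens**: one starting pool with log-normal mutant abundances
  (σ = 1), split into a drug screen with per-mutant selection coefficients
  and a vehicle screen with all coefficients 0. Frequencies update as
  `f · (1+s)^g` per round with g = 3.5 generations; reads are multinomial
  at 5 × 10⁶ per sample, independently per biological replicate, sampled at
  rounds 2 and 5. The reference recovery experiment plants s = +0.5 in 50
  of 2000 mutants and s = −0.5 in another 50.
* **Competitions**: odds multiplied by `fitness_ratio^g` per round from a
  configurable start fraction, with optional beta-distributed measurement
  noise.

What the synthetic data does *not* emulate: image-level artefacts
(segmentation errors, well-edge effects), plate position effects,
autofluorescence drift, replicate-to-replicate biological drift in screens
beyond multinomial sampling, and compound solubility limits. Passing tests
therefore demonstrate that the statistical machinery recovers planted truth
under the assumed noise model, not that the assays are robust to every
artefact of real plates.

## Problem sizes and reproducibility

The shipped test suite and the acceptance script run the screen recovery at
2000 mutants × 20 seeds, the classification round trip on a 12-compound
cohort (6 doses + control, 3 wells, 6 reporters × 3 replicate developments
each), and the doubling-time recovery at 60–100 seeded wells — sizes chosen
so the whole suite completes in a few minutes on a single core while keeping
the binomial error of every estimated rate well inside the asserted margins.
`run_pipeline()` writes a JSON manifest (seed, settings, package and R
versions, output checksums); rerunning with the same seed reproduces every
output byte-identically.
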