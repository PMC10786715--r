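---
title: "Perturbational blood phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbational blood phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`perturbscreen` implements a complete analysis chain for perturbation-based
("evoked") blood cell phenotyping: hematology-analyzer event clouds are gated
and summarized into robust per-donor trait vectors, traits pass a two-level
quality control, genetic associations are scanned and clumped into loci,
traits are related to clinical endpoints under FDR control, and polygenic
scores built from the scan are evaluated against time-to-diagnosis outcomes
with delayed-entry survival models and cross-cohort meta-analysis. Because
the cohort-scale genotype and EHR resources this kind of study uses are
access-restricted, every stage is exercised against a synthetic cohort
generator with known ground truth; the generator is itself a first-class,
tested module.

# The synthetic cohort generator

## Cytometry events

Each donor x condition x channel sample is an i.i.d. draw from a
gate-anchored Gaussian mixture in (FSC, SSC, SFL) space. The default
templates place 25 components over four channels (WDF, WNR, RET, PLT-F
analogues) using the gate vocabulary of clinical analyzers: neutrophil
subpopulations NE1-NE4 (NE2 the evoked high-SSC/high-SFL subpopulation),
monocyte, lymphocyte and eosinophil gates, basophil/white-count gates,
mature and reticulated red cells, platelets and immature platelet fraction,
plus debris and ghost components. Component means are separated by at least
eight spreads on at least one axis so that axis-aligned box gates recover
mixture proportions essentially without misclassification; events are
clipped to an 18-bit instrument range `[0, 2^18)`. Event counts per sample
and the dynamic range are configuration parameters, not claims about any
instrument.

Donor-level biology enters through latent traits. Each targeted gate `g`
has a donor latent
`z[d,g] = sum(effect * dosage[d, v]) + loading[g] * tone[d] + N(0,1)`,
where `tone` is a single "inflammatory tone" latent per donor that couples
disease risk to gate weights without claiming mechanism, and the genetic
term carries the configured causal effects (in latent s.d. units per
allele). Baseline weights are multiplied by the condition's log-fold
changes (non-baseline conditions raise NE2, IPF and BASO weights by
default, mimicking evoked subpopulations) and by `exp(0.35 * z)`, then
renormalized within channel.

## Genotypes

Variants carry a per-haplotype standard-normal liability; inside an LD
block adjacent liabilities follow an AR(1) process with correlation
`ld_rho` and blocks are independent. Thresholding each haplotype liability
at `qnorm(1 - maf)` yields exact Hardy-Weinberg single-variant frequencies
with monotonically increasing between-variant dosage correlation in
`ld_rho` — a deliberately simple LD model with closed-form expectations
rather than a coalescent simulation. MAFs are uniform on the configured
range, positions are 10 kb apart on one chromosome.

## Outcomes

True onset ages are exponential with hazard `base_hazard * exp(eta)`,
`eta` a linear predictor over donor latents with configured log hazard
ratios. Entry (first-visit) age is independent of the latents, and the
emitted records mimic EHR behaviour: onsets before entry surface shortly
after the first visit (so they land in the downstream instant-event
window), a configured fraction of observed events appear as undated
problem-list entries, and onsets past the censoring age are emitted
censored. Continuous labs (eGFR, HbA1C) are Gaussian around configured
means with a tone contribution, giving realistic trait-lab correlation.

What the generator does **not** emulate: optical physics or dye chemistry,
imputation uncertainty, genotyping batch artefacts, informative entry or
loss to follow-up, and coding noise in diagnoses. Green tests therefore
demonstrate algorithmic correctness and calibration under a clean
generative model, not robustness to every failure mode of real cohort data.

# Gating and featurization

Gates are axis-aligned boxes with half-open intervals (lower inclusive,
upper exclusive) so shared edges never double-count, with integer priority
ranks resolving overlap (lower rank wins). Hand-drawn polygon regions used
in interactive analysis software are an extension point, not implemented.
Per gate we report `Count`, `Pct` (of all events in the channel) and, per
optical axis, the median, robust s.d. (`1.4826 * MAD`, Gaussian-consistent)
and robust CV (`100 * robust_sd / median`, missing when the median is 0).
Gates with fewer than `min_count = 10` events keep `Count`/`Pct` but mask
the distributional statistics — medians of near-empty gates are noise.
Parameter names follow `<CHANNEL>_<Condition>_<Gate>_<Stat>` so outputs are
join keys across modules. Count ratios accept gate *sets* on either side;
the default `NE2/NE4` is NE2 over the summed NE1-NE4 neutrophil counts,
i.e. the evoked-subpopulation fraction of total neutrophils. With the
default gate set this schema yields 278 parameters per condition; the
schema size is configuration-dependent, not asserted.

# Phenotype quality control

The pipeline order is fixed: univariate cell filter, then sample filter,
then transform.

1. **4-MAD cell filter.** A cell is masked when it lies more than
   `k = 4` MADs from its column median, the MAD scaled by 1.4826. With the
   scaled MAD the threshold sits at four robust standard deviations
   (~6 x 10^-5 two-sided tail for Gaussian columns); the raw MAD would put
   it at ~2.7 sigma and mask ~0.7% of clean cells, which is not a tenable
   outlier rule for 10^2-10^3 donors. Columns with zero MAD mask nothing —
   legitimately discrete traits would otherwise be discarded wholesale.
2. **2-D ICA sample filter.** Per (channel, condition) block, donors are
   projected onto two independent components (fixed-point logcosh ICA,
   fixed seed; missing cells median-imputed and columns standardized for
   the projection only). Each donor's Euclidean distance to the
   componentwise median sample is computed and donors beyond
   `median(d) + 2.5 * mad(d)` are removed. The threshold is anchored at
   the median distance because distances are non-negative and
   right-skewed; a bare `2.5 * mad(d)` cut would remove ~20% of perfectly
   homogeneous Gaussian donors. Rank-deficient or stubbornly non-convergent
   blocks (near-Gaussian structure defeats the fixed-point iteration) fall
   back to a PCA projection with a warning — any fixed 2-D projection
   serves the outlier-distance purpose.
3. **Quantile transform.** Rank-based inverse normal scores with offset
   `(r - 0.5)/n`, average ranks on ties, missingness preserved. The
   transform is invariant to any strictly monotone re-expression of the
   input, which is what makes downstream linear scans comparable across
   wildly differently-scaled readouts.

The number of effectively independent traits is estimated per measurement
block as the smallest number of principal components of the standardized
block reaching 90% cumulative variance; blocks are aggregated by their
maximum, a deliberately conservative choice that is reported alongside the
per-block counts.

# Genetic association

Variant QC applies, in order: variant missingness (> 10%), Hardy-Weinberg
exact test (p < 1e-50, computed on hard calls at dosage thresholds
0.5/1.5 with the standard conditional-enumeration recurrence evaluated
outward from the distribution mode), MAF (< 0.05) and MAC (< 10) floors;
donors fail on sample missingness (> 10%) or KING-robust kinship
(phi > 0.177, the higher-missingness member of each flagged pair removed;
pruning is skipped with a warning below 100 variants where the estimator
is too noisy).

The scan is per-variant OLS of the transformed trait on allele dosage plus
variance-standardized covariates (age, sex, draw-to-analysis time, study
month, chip, batch, genotype PCs from an SVD of frequency-standardized
dosages). Variants without missingness share one covariate projection via
Frisch-Waugh-Lovell residualization — numerically identical to the
per-variant fit and verified against a least-squares oracle at 1e-8 — and
missing dosages fall back to per-variant row omission. Two-sided p-values
use the t distribution at residual df and are floored at 1e-320; no
genomic-control or mixed-model correction is applied.

Clumping is greedy: the unassigned significant (p < 5e-8) variant with the
smallest p across traits seeds a region (ties broken by smaller position);
unassigned significant variants on the same chromosome within 250 kb and
with dosage r^2 > 0.5 *to the index* join it. Regions then need support
from at least two distinct trait names among their members' significant
hits ("independent hits from different traits"); requiring distinct member
variants instead is available as `scan_config(support = "variants")`. The
lead variant is the member with the smallest p across all traits.

# Clinical association

Binary diagnoses use logistic regression
(`outcome ~ readout + age + race + sex + draw_time`) with Wald z tests
(not likelihood-ratio tests), continuous labs use OLS with t tests; race
enters as a categorical factor with an alphabetical reference level.
Cells with fewer than 10 cases are skipped — below that, separation
artefacts dominate — and separation or non-convergence flags the cell
rather than reporting an unstable estimate. FDR across the trait x
endpoint grid uses Storey q-values: pi0 estimated on the lambda grid
0.05..0.95 with a df-3 smoothing spline extrapolated at the grid's end and
clamped to (0, 1]; with pi0 forced to 1 the q-values reduce exactly to
Benjamini-Hochberg, which is both the under-20-tests fallback and the test
oracle. The signed score matrix (z/t statistics, skipped cells zeroed with
a recorded mask) is projected by the same fixed-point ICA; components are
ordered by descending mixing variance and sign-fixed so the
largest-magnitude loading is positive, making the projection deterministic
up to the documented canonicalization.

# Polygenic scores and survival

Scores are clumping-and-thresholding: single-trait clumping at
p1 = 0.5 / r^2 = 0.5 / 100 kb on the reference panel's LD, lead variants
kept at p < 0.1, weights equal to scan betas oriented to the effect
allele. Scoring imputes missing dosages to twice the scoring cohort's
effect-allele frequency and also returns within-cohort z-scaled scores.

Time-to-first-diagnosis models use the counting-process formulation with
birth as time origin: a subject enters the risk set at the first-visit age
(delayed entry / left truncation). Records whose diagnosis falls within
one year of entry, and problem-list diagnoses without a date, are encoded
as `(0, entry, 1)` — the subject contributes risk from birth to entry and
the event at entry. This is the simplest counting-process-compatible
encoding of "occurred between birth and start of observation"; it slightly
overstates time-at-risk for instant events, and the acceptance simulations
show the induced bias on a log HR of 0.3 stays within one standard error
at 5,000 subjects with ~20% instant events. Cox fits use Efron tie
handling via the survival package; Kaplan-Meier quartile curves use
cohort-specific score quartiles (ties to the lower stratum) with a
left-truncation-aware product-limit estimator. Cross-cohort pooling is a
REML random-effects model (metafor), z/p from the normal approximation,
and Storey q-values across the model grid. CKD progression staging maps
eGFR bands 45-59 / 30-44 / 15-29 / <15 (inclusive lower edges) to stages
3a/3b/4/5, with an HbA1C > 5.7 row filter available for restricting to
dysglycemic subjects.

# Orchestration and reproducibility

`run_pipeline()` chains simulate, gate, qc, scan, clump, clinical, pgs,
survive, meta, ica in fixed order; each stage writes TSV outputs and a log
line recording the exact thresholds used, and the run ends with a JSON
manifest of MD5 checksums covering every output (any modified intermediate
is detectable). One global seed fans out to every consumer through a
Lehmer-style string hash (`child_seed`), so stage-level streams are
reproducible independently of stage order; reruns are byte-identical. The
polygenic-score stage simulates independent application cohorts from the
same generative model (distinct child seeds), playing the role of the
external biobanks a real deployment would score.

Problem sizes in the packaged demo and acceptance checks — 200 donors x
500 variants x 3 conditions end-to-end, a 2,000 x 5,000 null scan, 5,000
subjects for survival recovery, 200 seeded repeats of 10,000-event
mixtures — were chosen so each property is measured with enough precision
for its stated bound while the whole suite stays comfortably interactive.

# Numerical choices and degenerate inputs

* p-values are floored at 1e-320 to keep `-log10(p)` finite under
  underflow.
* The HWE recurrence starts at the distribution mode so extreme
  configurations stay representable in double precision.
* Empty event tables, empty gate lists, zero-count denominators, constant
  readouts, all-missing columns, separation in logistic models, single
  studies in meta-analysis and degenerate (tied) score distributions all
  return defined results or flagged skips rather than errors; negative
  mixture weights are clipped to zero (all-zero weights are an error).
* ICA is weakly identifiable on near-Gaussian input; the projection logs
  this and proceeds, and the QC filter falls back to PCA rather than
  failing a block.

# Known limitations

* Box gates cannot express concave regions; misclassification is
  negligible only because the generator's components are well separated,
  as real evoked populations need not be.
* The LD model has no recombination-rate structure, so clumping distances
  are exercised but not stressed.
* The instant-event encoding is one of several defensible readings of
  interval-censored pre-entry onsets; a proper interval-censored likelihood
  is out of scope.
* Storey's pi0 smoother uses a fixed df-3 spline; very sparse p-value
  grids fall back to BH rather than attempting adaptive smoothing.
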