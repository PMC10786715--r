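# perturbscreen

Quantitative blood-cell readouts measured *after* an ex vivo perturbation
(a chemical stressor, a TLR ligand, a drug) expose cellular states that are
invisible at baseline — an evoked neutrophil subpopulation, a shifted
platelet fluorescence distribution — and those evoked traits turn out to be
heritable and clinically informative. `perturbscreen` is an R implementation
of the full analysis chain such a screen needs, for statistical geneticists
and computational hematologists who want every stage testable on synthetic
data with known ground truth:

1. **Synthetic cohort generator** — cytometry event clouds as gate-anchored
   Gaussian mixtures in (FSC, SSC, SFL) space across four analyzer channels
   (WDF/WNR/RET/PLT-F analogues), genotypes with AR(1) LD blocks under
   Hardy–Weinberg equilibrium, donor latent traits coupling genotype and an
   inflammatory-tone latent to gate weights, and EHR-style outcomes with
   delayed entry, undated problem-list events and censoring.
2. **Gating & featurization** — priority-ranked axis-aligned gates with
   half-open bounds; per gate the count, percentage and robust statistics
   (median, 1.4826·MAD robust s.d., robust CV) per optical axis; count
   ratios such as NE2/NE4 (the evoked neutrophil fraction).
3. **Phenotype QC** — 4-MAD univariate cell masking, a 2-D ICA sample
   outlier filter per channel × condition (removal beyond
   median(d) + 2.5·mad(d) from the median sample), rank-based
   inverse-normal transformation, and a block-wise PCA estimate of the
   number of independent traits at 90% cumulative variance.
4. **Genetic association** — variant/sample QC (missingness, exact
   Hardy–Weinberg test, MAF/MAC floors, KING-robust kinship pruning at
   φ > 0.177), covariate-adjusted per-variant OLS scans
   (Frisch–Waugh–Lovell fast path, verified against a least-squares
   oracle), and greedy LD clumping (r² > 0.5, < 250 kb, lead = smallest p)
   with the "at least two supporting traits per region" rule.
5. **Clinical association** — logistic (Wald z) and linear (t) models per
   trait × endpoint, Storey q-values (spline-smoothed π₀; exactly
   Benjamini–Hochberg when π₀ = 1), and a fixed-point logcosh ICA
   projection of the signed score matrix.
6. **Polygenic scores & survival** — clumping-and-thresholding scores
   (clump p1 0.5 / r² 0.5 / 100 kb, score threshold p < 0.1), additive
   scoring with 2·MAF imputation, counting-process Cox models with delayed
   entry and the "instant event" encoding (diagnoses within 1 year of
   first visit encoded as occurring between birth and entry),
   left-truncation-aware Kaplan–Meier quartile curves, REML random-effects
   meta-analysis across cohorts, and eGFR-based CKD staging (45–59 → 3a,
   30–44 → 3b, 15–29 → 4, < 15 → 5).
7. **Orchestration** — a ten-stage pipeline with one global seed fanned out
   per stage, TSV/VCF/CSV outputs, threshold-logging and an MD5 manifest;
   reruns are byte-identical.

## Worked example

```r
library(perturbscreen)

cfg  <- simulation_config(n_donors = 120, n_variants = 300,
                          events_per_sample = 2000, seed = 7)
geno <- simulate_genotypes(cfg)
lat  <- simulate_donor_latents(cfg, geno)
tabs <- simulate_events(donor_state(cfg, lat, 1, "Pam3CSK4_19h"),
                        "Pam3CSK4_19h", cfg)
row  <- featurize(tabs, gates_from_templates(cfg$gate_templates))
head(subset(row, grepl("NE2", parameter)), 4)
```

```
      donor    condition                    parameter    value
 donor_0001 Pam3CSK4_19h   WDF_Pam3CSK4_19h_NE2_Count    93.00
 donor_0001 Pam3CSK4_19h     WDF_Pam3CSK4_19h_NE2_Pct     4.65
 donor_0001 Pam3CSK4_19h WDF_Pam3CSK4_19h_NE2_Med_FSC 60315.47
 donor_0001 Pam3CSK4_19h WDF_Pam3CSK4_19h_NE2_Med_SSC 90011.06
```

Donor 1 carries 93 events (4.65% of the channel) in the evoked NE2 gate
under 19 h of Pam3CSK4, with the gate's median optical position; the
derived `WDF_Pam3CSK4_19h_NE2/NE4` ratio for this donor is 0.084, i.e.
8.4% of neutrophils sit in the evoked subpopulation. The end-to-end demo:

```r
st <- run_pipeline(demo_pipeline_config(seed = 7), "run1")
```

```
simulate: 200 donors, 500 variants, 3 conditions, seed 7
gate: 200 donors x 834 parameters
qc: mad_k=4 masked 1796 cells; ica_k=2.5 removed 34 donors
qc: independent traits per block [baseline=83, Pam3CSK4_19h=84, LPS_18h=83], overall 84
scan: 834 traits x 500 variants on 166 donors (0 excluded by variant QC)
clump: 3 regions (r2>0.50, <250 kb, >=2 traits, p<5e-08)
clinical: 9 traits x 5 endpoints, pi0=0.189
pgs: 3 scores built (p1=0.5, r2=0.5, kb=100, score_p=0.1)
survive: 18 cohort x score x endpoint models
meta: 9 pooled models, 0 with tau2 > 0
```

The three clumped regions are exactly the three planted causal variants
(each supported by multiple NE2-, RET1- and PLT-derived traits), and the
polygenic scores built from them are carried into delayed-entry Cox models
on two independently simulated application cohorts, then pooled by REML
meta-analysis.

A thin CLI over the same functions lives at
`inst/scripts/perturbscreen-cli.R`
(`Rscript perturbscreen-cli.R run-all --config cfg.yaml --out run/`).

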