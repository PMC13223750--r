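---
title: "Methods: localizing the QPRT bottleneck in de novo NAD+ synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing the QPRT bottleneck in de novo NAD+ synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpnad)
```

## The model

Inflamed intestinal mucosa degrades tryptophan (Trp) along the kynurenine
pathway (KP): cytokine-driven IDO1 induction raises the flux Trp → Kyn,
and in serum the Kyn:Trp ratio tracks disease activity. The pathway's end
point, *de novo* NAD⁺ synthesis, requires QPRT to convert quinolinic acid
(QA) into nicotinic acid mononucleotide (NAMN). When QPRT is
transcriptionally suppressed while upstream flux is high, QA accumulates
and NAD⁺ production stalls — a bottleneck. `kpnad` detects this pattern
from three longitudinal inputs: a serum metabolite matrix (µM), a mucosal
expression matrix (TPM), and a sample sheet with per-visit disease
activity (HBI for CD on 0–16, total Mayo for UC on 0–12), by

1. summarizing expression into per-reaction activity scores (RAS) over a
   KP reconstruction via gene–protein–reaction (GPR) rules,
2. fitting per response the linear mixed model
   `y ~ sex * activity + age + bmi + diagnosis + (1 | patient)`,
3. flagging reactions whose RAS falls significantly with activity while
   lying downstream (directed substrate→product reachability) of a
   reaction whose RAS rises significantly.

The key modeling assumptions: a patient-level random intercept captures
between-patient baselines; activity effects are linear on the
standardized score; RAS is a meaningful ordinal proxy for reaction
capacity (no flux balance is attempted).

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `min_nonmissing` | 0.8 | fraction of samples a metabolite must be observed in (inclusive boundary — exactly 80% is kept) |
| `or_mode` | `"sum"` | OR semantics in GPR rules; `"max"` available |
| `alpha` | 0.05 | BH-adjusted significance for flagging |
| `n_perm` | 1000 | GSEA gene-label permutations; p floored at 1/(n_perm+1) |
| `covariates` | age, bmi, diagnosis | fixed-effect adjustments; diagnosis only enters when UC and CD are pooled |
| `ratio_on` | `"raw"` | ratio panel from raw concentrations (missing → NA); `"imputed"` available |

Half-minimum imputation uses the global per-metabolite minimum across the
cohort (per-batch minima are not modeled). Autoscaling divides by the
sample standard deviation (n−1); the convention is stated here because
published pipelines differ and rarely say which they use.

## Design decisions that were genuinely open

**Pooling HBI and Mayo.** The two activity scales are not commensurate
and no published harmonization exists for pooling them in one mixed
model. `standardize_activity()` z-scores the score within diagnosis
before pooling, so "activity" is measured in within-diagnosis standard
deviations. This is a configuration choice, not a claim about clinical
equivalence.

**Centered sex.** In `y ~ sex * activity`, treatment coding would make
the `activity` coefficient the slope in the sex = 0 stratum only,
doubling its variance for a balanced cohort. The binary sex covariate is
therefore centered, making the reported main effect the sex-averaged
marginal slope — the quantity a pathway-level effect map actually
displays. The interaction term keeps its meaning (difference in slopes).

**GPR semantics.** AND → minimum of children (an enzyme complex is
limited by its scarcest subunit), OR → sum (isozymes add capacity). This
is the prevailing RAS convention, is 1-homogeneous (doubling all TPM
doubles every score) and monotone in every gene; OR → max is available
for sensitivity analysis. Genes absent from the panel contribute 0 to OR
and are skipped in AND; a rule with no measured gene scores NaN rather
than 0, distinguishing "no evidence" from "transcriptionally silent".

**Ratios before imputation.** The five KP ratios are computed on raw
concentrations with NA propagation by default. Computing them after
half-minimum imputation would manufacture extreme ratios exactly where
measurements are least trustworthy (both options are exposed).

**Inference.** Mixed models are fit by REML (lme4) and fixed-effect
p-values use the Wald normal approximation — no Satterthwaite or
Kenward–Roger correction. This is the simplest defensible default; with
the visit schedules used here (≥ 4 visits, ≥ 20 patients) the simulated
type-I error sits at 0.047–0.051 (acceptance criterion 4). BH adjustment
is applied per term family within an analysis batch (all reactions
together, all metabolites together), and non-convergent fits return
NaN-flagged rows instead of aborting the batch.

**Bottleneck rule.** The decision rule — negative-significant reaction
downstream of a positive-significant one, with spontaneous (GPR-less)
reactions conducting reachability but never being flagged — formalizes
reading the sign pattern off a fitted pathway map. It is an
artifact-defined criterion; the only reaction id anchored to the
full-genome reconstruction is `R24a` (QA → NAMN, GPR `QPRT`). The other
ids in `load_trp_subnetwork()` are fixture-local names for a canonical KP
reconstruction.

**Run configuration** is JSON (`jsonlite`), one schema for library and
CLI use; every report embeds the resolved configuration (minus the
output path, so reports are byte-identical wherever materialized).

## What the synthetic generator does and does not emulate

`generate_cohort()` draws UC/CD patients (exact configured fractions),
covariates from documented distributions (age ~ N(38, 12²) clipped to
18–80; BMI ~ N(25, 4²) clipped to 16–45; sex Bernoulli(0.5)), and
activity trajectories `a_i − b_i·ln(1 + week)` clipped to the scale
range: remitters get `b_i > 0` reaching a residual score of 0–2 by the
last visit, non-remitters `b_i = 0` plus visit noise (sd 0.6 score
points). A configurable fraction of non-baseline scores is masked to
exercise log-decline imputation.

`generate_metabolome()` and `generate_expression()` are lognormal around
linear-in-activity log-means with a shared patient random effect (sd
0.15 on the log scale) — the simplest forms producing the monotone
relations the analysis assumes. Planted structure: Trp falls (−0.10 per
activity SD) and Kyn rises (+0.15), so Kyn:Trp rises; PA is deliberately
uncoupled; log-QA rises by `qa_coupling·|beta_qprt|` (default 2 × 0.15 =
0.30) tying QA accumulation to QPRT suppression; log-IDO1 rises by
`beta_ido1` and log-QPRT falls by `beta_qprt` (defaults ±0.15) while all
other KP genes have zero planted slope. Residual sds default to 0.25
(metabolites) and 0.30 (expression) on the log scale — mid-range for
targeted serum panels and bulk biopsy RNA-seq. Left-censoring removes
values below the per-metabolite 3% marginal quantile by default,
matching the low missingness of targeted KP assays (1–6%).

Not emulated: cross-metabolite covariance beyond the shared patient
effect and activity coupling, batch effects, assay drift, microbiome
contributions, therapy-class effects, and dropout. A green end-to-end
test therefore establishes that the pipeline recovers planted monotone
activity coupling under realistic noise — not that it would survive
batch confounding or panel-wide correlation structure.

## Numerical choices

* Determinism: every generator runs under a locally scoped seed
  (`seed`, `seed + 1`, `seed + 2` for cohort/metabolome/expression;
  `seed + 101` for GSEA permutations) and restores the caller's RNG
  state; two runs with the same configuration are byte-identical
  (acceptance criterion 9).
* Log-decline imputation fits `a + b·ln(1 + week)` by least squares per
  patient (exact for two observed visits), clips to the scale range, and
  carries single observations; observed values are never altered.
* Autoscaling refuses zero-variance and non-positive columns by name;
  the 80% boundary is inclusive; BH is the step-up cumulative-minimum
  form, capped at 1, NA entries excluded from the family size.
* Spearman p-values use the t approximation on mid-ranks with
  pairwise-complete observations; |rho| = 1 returns p = 0; fewer than 3
  complete pairs returns a NaN-flagged row.
* GSEA uses weight exponent 1 on |statistic| and a gene-label
  permutation null: the ranking arrives as one precomputed vector from
  the mixed-model stage, so phenotype permutation would require
  refitting and is out of scope — a documented limitation, as label
  permutation ignores inter-gene correlation.
* The single-sample signature score implements the up-set mean-rank
  form, normalized to the closed-form extremes ±0.5; the bidirectional
  variant is out of scope because the packaged sets are single-direction.

## Known limitations

* RAS is a transcriptional proxy; no constraint-based flux estimation,
  no post-transcriptional regulation.
* The packaged subnetwork replaces a full genome-scale extraction; ids
  other than `R24a` are fixture-local.
* TNF and IL23 signature sets are published externally and must be
  supplied as GMT; only the six-gene IFNγ set is built in.
* Wald-normal inference is mildly anti-conservative for very small
  cohorts (< ~20 patients); the calibration figures above do not extend
  there.
* The empty numeric acceptance-target list is deliberate: the motivating
  study's printed statistics derive from undeposited clinical data, so
  every quantitative guarantee this package makes is property-based and
  computed by its own test suite at run time.
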