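# kpnad

Detection of a metabolic bottleneck in *de novo* NAD⁺ synthesis from
tryptophan in longitudinal IBD cohorts.

## The problem

In active inflammatory bowel disease, tryptophan (Trp) is aggressively
degraded along the kynurenine pathway (KP): inflammatory cytokines induce
IDO1, the first KP enzyme, and the serum kynurenine-to-tryptophan ratio
(Kyn:Trp) rises with disease activity. The KP should end in *de novo* NAD⁺
synthesis, but the committed step — conversion of quinolinic acid (QA) to
nicotinic acid mononucleotide (NAMN) by QPRT — is transcriptionally
suppressed in the inflamed mucosa. The result is a bottleneck: QA
accumulates in serum while mucosal NAD⁺ stays depleted. `kpnad` implements
the computational pipeline that localizes this bottleneck from
longitudinal multi-omics:

1. **Targeted-metabolomics preprocessing** — below-LOD values treated as
   missing, metabolites retained when ≥ 80% observed (inclusive), missing
   cells imputed as half the metabolite's minimum, log₁₀ transform with
   autoscaling, and the KP ratio panel computed on raw concentrations:
   Kyn:Trp, PA:QA, QA:Trp, QA:3OHAnth and
   QA:sumIDO = QA / (3OHAnth + 3OHKyn + KA + Kyn + PA + QA + Xanth).
2. **Reaction activity scores (RAS)** — recon3D-style gene–protein–reaction
   boolean rules evaluated on TPM: AND (enzyme complex) → min of children,
   OR (isozymes) → sum; the packaged Trp-degradation subnetwork carries the
   anchored reaction id `R24a` (QA → NAMN, GPR `QPRT`).
3. **Longitudinal mixed models** — per response
   `y ~ sex * activity + age + bmi + diagnosis + (1 | patient)` fit by
   REML (lme4), Wald-normal p-values, Benjamini–Hochberg adjustment across
   responses per term; disease activity (HBI for CD, total Mayo for UC) is
   z-scored within diagnosis before pooling, and missing scores are imputed
   per patient assuming a logarithmic decline,
   `score = a + b·ln(1 + week)`. Remitter/non-remitter contrasts are
   reported per visit week, and Spearman correlations with FDR support the
   serum ratio analyses.
4. **Enrichment** — t-value rankings (main effect + sex interaction),
   permutation GSEA (weighted running sum, gene-label null), hypergeometric
   overrepresentation, and rank-based single-sample signature scores with
   the built-in IFNγ gene set.
5. **Bottleneck flagging** — a catalysed reaction whose RAS falls
   significantly with activity while lying downstream of a reaction whose
   RAS rises significantly.

A seeded synthetic-cohort generator (`synthetic_config()`,
`generate_cohort()`, `generate_metabolome()`, `generate_expression()`)
emulates the cohort structure — UC/CD, visits at weeks 0/2/6/14/52,
log-declining activity in remitters, LOD censoring, planted IDO1/QPRT
effects — so the whole chain is testable without any data download.

## Worked example

```r
library(kpnad)

cfg    <- synthetic_config(n_patients = 60, weeks = c(0, 2, 6, 14), seed = 1)
cohort <- impute_activity_log_decline(generate_cohort(cfg))
expr   <- generate_expression(cohort, cfg)

model <- load_trp_subnetwork()
ras   <- compute_ras_matrix(model, expr)
keep  <- colnames(ras)[!apply(ras, 2, function(x) all(is.nan(x)))]
assoc <- fit_activity_lmm(ras[, keep], cohort)

act <- assoc[assoc$term == "activity", ]
head(act[order(act$p_adj), c("response", "estimate", "se", "t", "p_adj")], 3)
#>  response estimate    se     t    p_adj
#>       R01    5.556 0.811  6.85 9.45e-11
#>      R24a   -5.415 1.087 -4.98 4.08e-06
#>       R03    0.654 0.357  1.83 1.68e-01

flag_bottlenecks(assoc, model)
#> [1] "R24a"
```

The Trp → Kyn reaction (`R01`, driven by the planted IDO1 induction) rises
with disease activity while the QPRT-catalysed QA → NAMN step (`R24a`)
falls; since `R24a` lies downstream of `R01`, it is flagged as the
bottleneck. The serum side shows the matching picture — QA-centred ratios
rise with activity while PA:QA falls, and at the week-14 visit QA
correlates positively with Kyn:Trp (Spearman, BH-adjusted):

```r
met    <- generate_metabolome(cohort, cfg)
ratios <- compute_ratio_panel(apply_eighty_percent_rule(met))
w14    <- cohort$week == 14
spearman_with_fdr(ratios[w14, ], met[w14, "QA"])
#>      feature   rho       p   p_adj  n
#> 1    Kyn:Trp  0.52 9.3e-05 9.3e-05 52
#> 2      PA:QA -0.78 3.0e-12 1.5e-11 55
#> 3     QA:Trp  0.75 1.4e-10 3.5e-10 52
#> 4  QA:sumIDO  0.72 3.1e-09 3.9e-09 50
#> 5 QA:3OHAnth  0.72 1.1e-09 1.8e-09 54
```

The end-to-end run (`run_pipeline()`, or `exec/kpnad run --config cfg.json
--seed 7 --outdir out/`) writes every intermediate table plus a JSON
bottleneck report and is byte-identical under a fixed seed.

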