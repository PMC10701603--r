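# actisig

Derive a hormone-receptor **activity gene signature** from panels of
treatment-versus-vehicle perturbation transcriptomes, and deploy it on tumor
cohorts: per-sample activity scoring, random-gene-set null benchmarking,
pathway correlation, panel-gene clustering and classifier extraction,
Kaplan–Meier / log-rank survival stratification with permutation-based
prognostic-power assessment, single-cell recovery-curve scoring, and
ChIP-peak proximity enrichment around transcription start sites.

The package is aimed at computational biologists who have (or can simulate)
a panel of agonist/vehicle expression contrasts — e.g. glucocorticoid
treatment across cell-line models — and want a reusable, testable pipeline
from those contrasts to cohort-level biology. Every input can be generated
synthetically with planted ground truth, so the full pipeline is verifiable
end to end without external downloads.

## The method

**Signature building.** For each model, genes are tested treated-vs-vehicle
with a moderated t statistic: the pooled per-gene variance s²_g (d df) is
shrunk towards a prior, s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d), with (d₀, s₀²)
estimated by method-of-moments on log s²_g; p-values (d₀ + d df, two-sided)
are BH-adjusted. Upregulated genes satisfy logFC > 0.5 **and** padj < 0.05
(strict). Models with an outlying number of upregulated genes
(> median + 3·MAD) are discarded; genes present in ≥ 3 models form the
consensus; and only genes with positive Pearson correlation (R > 0) with the
anchor gene (e.g. *NR3C1* for the glucocorticoid receptor) across a
reference cohort are kept.

**Activity scoring.** Expression is z-scored per gene,
z = (x − mean)/sd, and a sample's activity is the mean z over signature
genes. Scores are benchmarked against size-matched random gene sets
(empirical p = (1 + #{null ≥ obs})/(n + 1)), and the activity-versus-anchor
trend is summarised by a degree-6 polynomial fit with R² = 1 − SSE/SST.

**Deployment.** Pathway scores (weighted-ECDF single-sample enrichment)
are correlated with activity and aggregated into families (display flag at
|mean R| > 0.45); panel genes are k-means clustered and the
activity-coupled cluster becomes a compact classifier; cohorts are
median-split within subtype and compared by log-rank, with SigCheck-style
permutation against random same-size gene sets; cells are scored by the
area under the signature recovery curve in the top 5% of within-cell ranks;
and peak density is profiled in 10 kb bins of TSS distance out to 100 kb
against random gene-set nulls.

See `vignettes/activity-signatures.Rmd` for the full model description,
parameter meanings and design choices.

## Worked example

```r
library(actisig)

cfg    <- sim_config(n_models = 8, n_genes = 2000, n_responsive = 60, seed = 42)
panel  <- simulate_model_panel(cfg)
up     <- lapply(panel$models, function(m)
            significant_up(moderated_t_contrast(m$matrix, m$arms)))
cohort <- simulate_cohort(cfg, panel$truth$gene[panel$truth$responsive], seed = 43)

sig <- build_signature(up, cohort$matrix, "NR3C1", min_models = 3)
sig
#> GeneSignature: 56 genes
#>   min_models 3, models used 8, discarded 0
#>   G00024, G00049, G00146, G00165, G00197, G00226, G00259, G00299, G00314, G00321, ...

scores <- activity_score(cohort$matrix, sig)
scores
#> ActivityScores: 500 samples (genes used: 56, missing: 0)
#>      S0001      S0002      S0003      S0004      S0005      S0006
#> -0.0418382 -1.3076666 -0.4041429  0.5355039 -0.7533269 -0.2928775

cor(as.numeric(scores), cohort$activity)      # recovery of the latent activity
#> 0.994
poly_fit_r2(as.numeric(cohort$matrix["NR3C1", ]), as.numeric(scores))$r2
#> 0.609                                        # degree-6 trend vs anchor mRNA

groups <- assign_groups(scores, cohort$cohort, "LumA")
logrank_test(cohort$cohort$time, cohort$cohort$event, groups)
#> chi-square 56.16 on 2 df, p = 6.37e-13

sigcheck_permutation(cohort$matrix, cohort$cohort, sig$genes[1:8],
                     n_iter = 199, seed = 7)
#> PrognosticPermutation: observed log-rank p 8.16e-28, empirical p 0.005 (199 nulls)
```

Reading the output: the builder recovered a 56-gene signature from the
8-model panel (60 genes were planted; occurrence ≥ 3 under penetrance 0.6
prunes the rest); its per-sample score tracks the planted latent activity at
R = 0.994; activity relates non-linearly to anchor mRNA (trend R² = 0.609 —
mirroring the observation that receptor mRNA alone is a weak activity
proxy); the activity split of Luminal-A samples separates progression
(log-rank p ≈ 6e-13); and an 8-gene sub-signature stratifies survival better
than all 199 random same-size gene sets (empirical p = 0.005).

A command-line interface over the same functions is installed at
`system.file("cli", "actisig.R", package = "actisig")` with subcommands
`simulate`, `diffexpr`, `build-signature`, `score`, `pathways`, `stratify`,
`survival` and `chip-enrich`, each writing machine-readable TSV/JSON plus a
log.

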