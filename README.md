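# mir200sig

Transcriptome analysis of early-stage lung adenocarcinoma anchored on the
miR-200 microRNA family: supervised gene-signature derivation, continuous
tumor classification by constrained mixture deconvolution, EMT and immune
scoring, gene-set enrichment, and survival stratification — with a
synthetic-cohort generator providing ground truth for every stage.

## Who this is for

Computational biologists analysing bulk RNA-seq of tumor cohorts who want
to (a) derive a gene signature supervised by an external anchor
measurement (here a microRNA level), (b) express each tumor as a
continuous mixture of two transcriptional programs instead of a hard
subtype call, and (c) connect that mixture proportion to immune
microenvironment and outcome.

## The model at the core

Each tumor profile $x$ (logCPM over a discriminant gene panel) is modelled
as a convex combination of two program centroids,

$$x \approx w\,c_\text{up} + (1-w)\,c_\text{down},
\qquad w \in [0,1],$$

and $w$ — the tumor's "impregnation" by the miR-200-sign-up program — is
estimated by simplex-constrained least squares, which for two classes has
the closed form

$$\hat w = \operatorname{clamp}\!\left(
 \frac{(x - c_\text{down})\cdot(c_\text{up} - c_\text{down})}
      {\lVert c_\text{up} - c_\text{down}\rVert^2},\; 0,\; 1\right).$$

Centroids are learned by iterative refinement over "pure" samples
(top weight ≥ 0.8), starting from clusters cut on the anchor-supervised
signature. Tumors with $\hat w > 0.5$ are called `miR-200-sign-up`,
otherwise `miR-200-sign-down`; quartiles of $\hat w$ give a finer
stratification. See the methods vignette
(`vignettes/mir200-signature-methods.Rmd`) for the full model, parameter
meanings, and known limitations.

## Worked example

```r
library(mir200sig)

co  <- simulate_cohort(sim_params(seed = 42))       # 107 tumors, ground truth known
run <- run_pipeline(co$expression, co$annotations,
                    pipeline_config(seed = 42),
                    gene_sets = co$marker_sets)
run
#> mir200sig pipeline run
#>  signature genes: 1158
#>  samples scored: 107
#>  classes: miR-200-sign-down = 53, miR-200-sign-up = 54
#>  DFS log-rank (class): chisq = 10.6, p = 0.00116

head(run$weights, 4)
#> # A tibble: 4 x 6
#>   sample_id  w_down  w_up residual class             quartile
#> 1 T001      0.289   0.711     5.29 miR-200-sign-up   Q3
#> 2 T002      0       1         6.40 miR-200-sign-up   Q4
#> 3 T003      0.689   0.311     5.84 miR-200-sign-down Q2
#> 4 T004      0.00851 0.991     6.12 miR-200-sign-up   Q4
```

`w_up` is the per-tumor mixture weight of the up-program (`w_down = 1 -
w_up`); `residual` is the fit residual norm. The log-rank p of 0.00116
says the two classes separate in disease-free survival, in the planted
direction — the up class survives longer. Enrichment runs along the
weight axis recover the planted biology (lymphoid markers enriched at low
`w_up`, ES = −0.93; myeloid at high `w_up`, ES = +0.94), and the
stage-adjusted Cox model keeps the class effect
(HR 0.38, 95% CI 0.21–0.70 for the up class):

```r
run$survival$by_class$adjusted_cox
#> # A tibble: 5 x 6
#>   term                 estimate    hr conf_low conf_high p_value
#> 1 groupmiR-200-sign-up   -0.963 0.382   0.209      0.697 0.00171
#> ...
```

`tidy()`, `glance()` and `autoplot()` methods are provided for the fitted
deconvolution model and the survival curves; individual stages
(`select_most_variable()`, `extreme_groups()`, `rank_differential()`,
`derive_signature()`, `fit_wisp()`, `score_mixture()`, `emt_76gs()`,
`emt_ks()`, `marker_scores()`, `preranked_gsea()`, `km_estimate()`,
`logrank_test()`, `cox_fit()`, `stratified_report()`, ...) are exported
and pipe-friendly for partial workflows, and `read_expression()` /
`read_annotations()` / `read_gmt()` ingest the standard TSV/GMT formats.

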