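---
title: "Methods: the miR-200 signature pipeline and its deconvolution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miR-200 signature pipeline and its deconvolution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mir200sig)
```

## The scientific problem

The miR-200 family sustains the epithelial phenotype by repressing the
ZEB transcription factors; its loss pushes tumors toward a mesenchymal,
invasive program. In early-stage lung adenocarcinoma, generic
epithelial–mesenchymal transition (EMT) scores carry little prognostic
information, while the expression of the chromosome-1 miR-200 cluster does.
`mir200sig` implements the full analysis built on that observation:

1. derive a gene signature supervised by an *anchor* microRNA (miR-429 or
   the mean chromosome-1 miR-200 level), by contrasting the anchor-high and
   anchor-low tails of the cohort and intersecting with the most variable
   genes;
2. treat every tumor as a *mixture* of two latent transcriptional programs
   ("miR-200-sign-up" and "miR-200-sign-down") and estimate the per-tumor
   mixture proportion by constrained least squares against refined class
   centroids (the weighted-in-silico-pathology, WISP-style, approach);
3. score EMT state and immune infiltration, test gene-set enrichment along
   the mixture-weight axis;
4. stratify disease-free and overall survival by mixture class and
   quartile, with stage adjustment.

Because the original cohort's RNA-seq is not publicly deposited, the
package ships a synthetic-cohort generator with the statistical structure
the analysis assumes, so that every stage is tested against known ground
truth.

## The mixture model and its estimator

For a sample expression profile $x$ (logCPM over a gene panel) and class
centroids $c_\text{up}, c_\text{down}$, the mixture weight solves

$$\min_{w \ge 0,\; \sum_k w_k = 1} \big\lVert x - \textstyle\sum_k w_k c_k \big\rVert^2 .$$

With two classes the solution is closed-form: the projection of $x$ onto
the segment joining the centroids, clamped to $[0, 1]$,

$$\hat w_\text{up} = \operatorname{clamp}\!\left(
  \frac{(x - c_\text{down})\cdot(c_\text{up} - c_\text{down})}
       {\lVert c_\text{up} - c_\text{down}\rVert^2}, 0, 1\right).$$

`estimate_weights()` implements this (with an optional per-gene weighted
objective); three or more classes fall back to non-negative least squares
followed by renormalization onto the simplex, which is an approximation
and documented as such. The tests verify the closed form against a
0.001-step grid search of the constrained objective.

### Centroid refinement and its bias

`fit_wisp()` starts from the two clusters cut on the signature genes
(cluster I → down, II → up), then alternates: centroids = per-class means
over the current *pure* samples; weights for all samples against those
centroids; pure samples = those whose top weight reaches the purity
threshold (default 0.8, at most 10 iterations). This mirrors the usual
centroid-refinement deconvolution training loop.

An important, easy-to-miss property: the refined centroids are means of
*observed* samples, which are themselves mixtures. When the cohort's true
proportions are spread broadly over $[0, 1]$ (the generator's default is
uniform), the pure sets stabilize around samples with true proportion
roughly $\ge 0.76$ (respectively $\le 0.24$), so the estimated centroids
sit at about $0.86$ and $0.14$ along the true inter-centroid axis rather
than at the latent endpoints. Weights estimated against such centroids are
stretched versions of the truth and clamp at the ends; on uniform
proportions this puts their RMSE against the true proportions near 0.09
even with modest noise. The refinement recovers the *latent* program
centroids (and therefore unbiased proportions) only when genuinely
near-pure samples exist in the cohort — the assumption the approach makes
of real tumor series. The test suite reflects this split: estimator
correctness and proportion recovery are checked against the true
centroids (the algebraic inversion of the mixing equation), centroid
recovery is checked on cohorts containing near-pure samples, and
class-level outputs (classification, concordance, survival direction),
which are robust to the stretch because it preserves the 0.5 midpoint,
are checked on the default uniform cohorts.

## The synthetic cohort generator

`simulate_cohort()` draws, per sample $s$ with true proportion
$p_s$:

* expression $x_{gs} = p_s C^\text{up}_g + (1 - p_s) C^\text{down}_g +
  \varepsilon_{gs}$, $\varepsilon \sim N(0, \sigma^2)$ independently per
  cell, on the logCPM scale (no count-level noise model — negative
  binomial sampling, library-size artefacts and batch effects are *not*
  emulated, so passing tests say nothing about robustness to those);
* an anchor value $p_s + N(0, \sigma_a^2)$ — the anchor microRNA is
  measured separately from the expression matrix, as in the motivating
  study design (ΔΔCt values), so it lives in the annotation table;
* mutation flags with class-conditional probabilities (TP53 enriched in
  the down class, EGFR/KRAS in the up class, STK11 near-neutral), strong
  enough that Fisher tests resolve the enrichment at cohorts of about
  100;
* disease-free survival times $\sim \text{Exponential}(h_0
  e^{\beta(1-p_s)})$ with administrative censoring at the horizon plus a
  uniform random dropout fraction.

Defaults are fixed once: 107 samples (the size of the motivating series),
2000 genes of which 300 are program genes at a mean pure-program shift of
2 logCPM, noise sd 0.5, anchor noise sd 0.1, uniform proportions. The
survival parameters $\beta = 1.5$ and $h_0 = 0.0055$/month with a
60-month horizon were calibrated so the two classes reproduce the
published survival contrast of the motivating cohort — a down-class
median disease-free survival of about 41 months, an up-class median not
reached within follow-up, and a strongly significant log-rank separation
at $n = 107$. Immune marker genes (10 lymphoid, 10 myeloid, shift 2
logCPM) track $1 - p$ and $p$ respectively, mirroring the reported
lymphocyte enrichment at low up-signature impregnation.

## Signature derivation parameters

* `n_extreme = 15`: the anchor-high and anchor-low contrast groups
  (15 vs 15 tumors in the motivating design). Ties at a group boundary are
  broken by lexicographic sample id, with a warning.
* `n_de = 1500` genes ranked by absolute Welch *t* on logCPM. The choice
  of Welch *t* is the package's own: the derivation needs a ranking, not
  calibrated p-values, so moderated variants add nothing here. Genes
  constant in both groups get statistic 0 (warned); constant-but-different
  genes get an effectively infinite statistic and rank first.
* `n_variable = 1500` genes by variance of logCPM (MAD available by
  option); ties by gene symbol so the selection is deterministic.
* The signature is the intersection of the two lists, preserving the
  |*t*| order — the analogue of the published 493-gene set. Clustering on
  it (Ward linkage on 1 − Pearson distance; both configurable, and the
  package's default convention for all expression clustering here) yields
  clusters named I / IIA / IIB by increasing mean anchor value.

## Scores and enrichment

* **Correlation-weighted EMT score** (`emt_76gs()`): weights = Pearson
  correlation of each signature gene with an anchor epithelial gene
  (CDH1 by default), score = weighted expression sum, mean-centered.
  Higher = more epithelial, matching the annotation convention of the
  76-gene score.
* **KS EMT score** (`emt_ks()`): signed two-sample Kolmogorov–Smirnov
  statistic between the expression distributions of an epithelial and a
  mesenchymal gene set within each sample; positive = mesenchymal, so the
  two EMT scores are anticorrelated by construction. An exact
  $D^+ = D^-$ tie is signed by the mean difference of the two sets (zero
  when the means tie as well); this keeps the swap-the-sets antisymmetry
  exact and the magnitude equal to the classical KS statistic for
  continuous data.
* **Compact panel score** (`emt_kgene()`): direction-signed z-score
  average; the panel identity is caller-supplied configuration — the
  package claims no default list.
* **Immune marker scores** (`marker_scores()`): per-population arithmetic
  mean logCPM of marker genes, an MCP-counter-style surrogate.
* **Pre-ranked enrichment** (`preranked_gsea()`): genes ranked by Pearson
  correlation with the up-signature weight; weighted running-sum
  enrichment score; null by re-drawing the set's positions uniformly in
  the ranking (set permutation — phenotype permutation would require
  re-ranking per permutation and is out of scope). The p-value is the
  same-sign exceedance fraction among same-sign permutation scores (the
  classical pre-ranked convention); normalizing instead by the total
  permutation count would make null p-values concentrate below 0.5 and
  break calibration. NES divides ES by the same-sign mean |ES|. The p
  resolution is limited by the permutation count.

## Survival analysis

Kaplan–Meier, log-rank and Cox proportional hazards go through the
`survival` package (product-limit estimator, hypergeometric-variance
log-rank, Breslow ties by default with Efron as option); the package layer
adds the tidy contracts, the median rule (smallest time with survival
≤ 0.5, an explicit "not reached" flag otherwise — never infinity in an
output table), stage-stratified reporting with an "insufficient n" rule
(default minimum 5 per stratum), and a pooled stage-adjusted Cox model
with class as exposure and stage dummy-coded against its first level.
Tests verify the toys by hand-enumerated risk sets and the Cox fit against
a grid maximization of the Breslow partial likelihood. When comparing
class medians across simulations, a replicate where *neither* median is
reached is decided by the 60-month survival fractions; with the default
survival calibration this affects only a small minority of replicates.

## Problem sizes used by the test suite

The suite runs on cohorts of 20–300 samples and 100–2000 genes: 1000
random instances for the grid-search equivalence of the estimator, 20
seeded cohorts (100 × 2000) for proportion recovery, three default-size
cohorts (107 samples) for the concordance property, 500 replicates for
log-rank type-I calibration, 20 seeds for Cox interval coverage and for
the survival-direction property. These sizes give stable Monte-Carlo
behaviour for the assertions made while keeping a full run around a
minute.

## Known limitations

* The refinement bias discussed above: mixture weights from a cohort
  without near-pure samples are stretched estimates of the true
  proportions (classification at the 0.5 cutoff is unaffected).
* The ≥ 3-class solver is NNLS plus renormalization, not an exact
  simplex-constrained solver.
* The generator does not emulate count-level noise, batch structure, or
  realistic gene–gene correlation beyond the two planted programs, so
  test results quantify algorithmic correctness, not robustness on real
  RNA-seq.
* Reproducing the motivating study's numeric tables (its 65/42 class
  split, its centroid values, its validation-cohort statistics) requires
  its raw data, which is not publicly deposited; nothing in this package
  claims those numbers.
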