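#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis. Defaults
#' mirror the published workflow dimensions: 15-vs-15 extreme anchor groups,
#' 1500 differential and 1500 most-variable genes intersected into the
#' signature, a 150-gene centroid panel, and a 0.5 class cutoff on the
#' up-signature weight.
#'
#' @param n_extreme Extreme-group size for signature derivation.
#' @param n_de Differential genes kept from the anchor contrast.
#' @param n_variable Most-variable genes.
#' @param n_centroid_genes Centroid panel size.
#' @param purity_threshold Pure-sample weight threshold in [fit_wisp()].
#' @param max_iterations Centroid-refinement iteration cap.
#' @param cutoff Class cutoff on the up-weight, in (0, 1).
#' @param k_subtypes Clusters for unsupervised subtype discovery.
#' @param k_signature Clusters cut on the signature genes (2 = the
#'   down/up split used to initialize deconvolution).
#' @param min_tumor_content Sample QC threshold.
#' @param prior_count logCPM prior count.
#' @param n_perm Permutations for gene-set enrichment.
#' @param seed Integer seed making the full run reproducible.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_extreme = 15, n_de = 1500, n_variable = 1500,
                            n_centroid_genes = 150, purity_threshold = 0.8,
                            max_iterations = 10, cutoff = 0.5,
                            k_subtypes = 3, k_signature = 2,
                            min_tumor_content = 0.20, prior_count = 0.5,
                            n_perm = 1000, seed = 1L) {
  stopifnot(n_extreme >= 1, n_de >= 1, n_variable >= 1, n_centroid_genes >= 1,
            purity_threshold > 0, purity_threshold <= 1,
            cutoff > 0, cutoff < 1, max_iterations >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full miR-200 signature analysis
#'
#' Executes, in order: preprocessing (logCPM conversion if needed,
#' tumor-content QC, variable-gene selection), unsupervised subtype
#' clustering, supervised signature derivation from the anchor microRNA,
#' signature clustering (initial down/up classes), centroid-refinement
#' deconvolution, classification and quartile binning, EMT / immune /
#' enrichment scoring (when gene sets are supplied), and survival
#' stratification. With a fixed `config$seed` the run is reproducible; all
#' result tables are keyed and ordered by sample id, so permuting the input
#' sample columns does not change them.
#'
#' @param expression An [expression_matrix()] (counts or logCPM).
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param config A [pipeline_config()].
#' @param gene_sets Optional named list of gene sets; sets named
#'   `epithelial` and `mesenchymal` feed the EMT scores, any others are
#'   scored as marker populations and tested for enrichment.
#' @param outdir Optional directory; when given, each artifact is written
#'   as a TSV stamped with the config hash and seed.
#' @return List of class `mir200_run` with elements `variable_genes`,
#'   `subtypes`, `signature`, `signature_clusters`, `model` (wisp_model),
#'   `weights` (with class and quartile), `scores`, `enrichment`,
#'   `survival` (list: `by_class`, `by_quartile`, each a
#'   `stratified_report`), and `config`.
#' @export
run_pipeline <- function(expression, annotations, config = pipeline_config(),
                         gene_sets = NULL, outdir = NULL) {
  annotations <- validate_annotations(annotations)
  shared <- intersect(colnames(expression), annotations$sample_id)
  if (length(shared) < 2) {
    stop("expression and annotations share fewer than 2 samples", call. = FALSE)
  }
  set.seed(config$seed)

  x <- .stage("preprocess", {
    x <- expression[, sort(shared)]
    if (expr_unit(x) == "counts") x <- counts_to_logcpm(x, config$prior_count)
    keep <- filter_by_tumor_content(annotations, config$min_tumor_content)
    x[, intersect(colnames(x), keep)]
  })
  ann <- annotations[match(colnames(x), annotations$sample_id), ]

  variable_genes <- .stage("variable_genes",
    select_most_variable(x, n = min(config$n_variable, nrow(x))))

  subtypes <- .stage("subtype_clustering", {
    k <- min(config$k_subtypes, ncol(x))
    hierarchical_cluster(x, genes = variable_genes$gene, k = k)
  })

  signature <- .stage("signature_derivation", {
    grp <- extreme_groups(ann, n_extreme = config$n_extreme)
    de <- rank_differential(x, grp$low, grp$high, n_de = config$n_de)
    derive_signature(de, variable_genes,
                     metadata = list(n_extreme = config$n_extreme,
                                     anchor = "anchor_value"))
  })

  signature_clusters <- .stage("signature_clustering",
    cluster_on_signature(x, signature, ann, k = config$k_signature))

  model <- .stage("deconvolution",
    fit_wisp(x, signature_clusters,
             n_panel = min(config$n_centroid_genes, nrow(signature)),
             purity_threshold = config$purity_threshold,
             max_iterations = config$max_iterations))

  weights <- .stage("classification", {
    w <- classify_weights(model$weights, cutoff = config$cutoff)
    if (nrow(w) >= 4) w <- quartile_bins(w)
    dplyr::arrange(w, .data$sample_id)
  })

  scores <- .stage("scoring", {
    s <- tibble(sample_id = colnames(x))
    if (!is.null(gene_sets)) {
      epi <- gene_sets$epithelial
      mes <- gene_sets$mesenchymal
      if (!is.null(epi) && length(intersect(epi, rownames(x))) >= 2) {
        anchor <- intersect(epi, rownames(x))[1]
        s <- dplyr::left_join(s, emt_76gs(x, epi, anchor_gene = anchor),
                              by = "sample_id")
      }
      if (!is.null(epi) && !is.null(mes)) {
        s <- dplyr::left_join(s, emt_ks(x, epi, mes), by = "sample_id")
      }
      other <- gene_sets[setdiff(names(gene_sets), c("epithelial", "mesenchymal"))]
      if (length(other) > 0) {
        s <- dplyr::left_join(s, marker_scores(x, other), by = "sample_id")
      }
    }
    dplyr::arrange(s, .data$sample_id)
  })

  enrichment <- .stage("enrichment", {
    if (is.null(gene_sets) || length(gene_sets) == 0) NULL else {
      ranking <- rank_genes_by_weight_association(x, weights)
      usable <- gene_sets[vapply(gene_sets,
                                 function(g) length(intersect(g, ranking$gene)) > 0,
                                 logical(1))]
      if (length(usable) == 0) NULL else {
        preranked_gsea(ranking, usable, n_perm = config$n_perm,
                       seed = config$seed)
      }
    }
  })

  surv <- .stage("survival", {
    list(
      by_class = stratified_report(weights, ann, endpoint = "dfs",
                                   grouping = "class"),
      by_quartile = if (nrow(weights) >= 8 && "quartile" %in% names(weights)) {
        stratified_report(weights, ann, endpoint = "dfs", grouping = "quartile")
      } else NULL
    )
  })

  run <- structure(
    list(variable_genes = variable_genes, subtypes = subtypes,
         signature = signature, signature_clusters = signature_clusters,
         model = model, weights = weights, scores = scores,
         enrichment = enrichment, survival = surv, config = config),
    class = "mir200_run")

  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  w <- function(df, name) {
    if (!is.null(df)) .write_stamped_tsv(df, file.path(outdir, name), cfg)
  }
  w(as_tibble(run$signature), "signature.tsv")
  cent <- as_tibble(run$model$centroids, rownames = "gene")
  w(cent, "centroids.tsv")
  w(run$weights, "weights.tsv")
  w(run$scores, "scores.tsv")
  w(run$enrichment, "enrichment.tsv")
  w(run$survival$by_class$per_stratum, "survival_by_class.tsv")
  if (!is.null(run$survival$by_quartile)) {
    w(run$survival$by_quartile$per_stratum, "survival_by_quartile.tsv")
  }
  invisible(outdir)
}

#' @export
print.mir200_run <- function(x, ...) {
  cat("mir200sig pipeline run\n")
  cat(" signature genes:", nrow(x$signature), "\n")
  cat(" samples scored:", nrow(x$weights), "\n")
  tab <- table(x$weights$class)
  cat(" classes:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  lr <- x$survival$by_class$pooled
  cat(sprintf(" DFS log-rank (class): chisq = %.3g, p = %.3g\n",
              lr$statistic, lr$p_value))
  invisible(x)
}
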