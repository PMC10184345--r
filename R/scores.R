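#' Correlation-weighted EMT score (76GS style)
#'
#' Weights every signature gene by its Pearson correlation with an anchor
#' epithelial gene (default CDH1) across samples, scores each sample as the
#' weighted sum of its expression over the signature genes, and mean-centers
#' the scores across the cohort. Higher score = more epithelial.
#'
#' @param x logCPM [expression_matrix()].
#' @param signature_genes Character vector of signature genes (genes absent
#'   from the matrix are dropped).
#' @param anchor_gene Anchor for the correlation weights (default `"CDH1"`).
#' @return Tibble `sample_id`, `emt_76gs`.
#' @export
emt_76gs <- function(x, signature_genes, anchor_gene = "CDH1") {
  vals <- .as_expr_values(x)
  if (!anchor_gene %in% rownames(vals)) {
    stop("anchor gene ", anchor_gene, " absent from matrix", call. = FALSE)
  }
  if (ncol(vals) < 3) stop("need at least 3 samples", call. = FALSE)
  genes <- intersect(signature_genes, rownames(vals))
  if (length(genes) < 2) stop("fewer than 2 usable signature genes", call. = FALSE)
  anchor <- vals[anchor_gene, ]
  if (sd(anchor) == 0) {
    warning("anchor gene has zero variance; all weights 0", call. = FALSE)
    w <- rep(0, length(genes))
  } else {
    gv <- apply(vals[genes, , drop = FALSE], 1, sd)
    w <- numeric(length(genes))
    if (any(gv == 0)) {
      warning(sum(gv == 0), " zero-variance gene(s) given weight 0", call. = FALSE)
    }
    ok <- gv > 0
    w[ok] <- cor(t(vals[genes[ok], , drop = FALSE]), anchor)[, 1]
  }
  raw <- colSums(w * vals[genes, , drop = FALSE])
  tibble(sample_id = colnames(vals), emt_76gs = unname(raw - mean(raw)))
}

#' Two-sample Kolmogorov-Smirnov EMT score
#'
#' Per sample, compares the empirical distribution of expression over an
#' epithelial gene set with that over a mesenchymal gene set.
#' With `D+ = max(F_epi - F_mes)` and `D- = max(F_mes - F_epi)`, the score
#' is `+D+` when `D+ > D-` (mesenchymal genes shifted higher), `-D-` when
#' `D- > D+`, and on an exact tie `D+` signed by the mean difference (0 when
#' the means tie too, e.g. identical distributions) — so positive =
#' mesenchymal, the score lies in \[-1, 1\], and swapping the two sets
#' negates it exactly.
#'
#' @param x logCPM [expression_matrix()].
#' @param epithelial_set,mesenchymal_set Character vectors of gene symbols;
#'   intersected with the matrix and required disjoint afterwards, each with
#'   at least 2 members.
#' @return Tibble `sample_id`, `emt_ks`.
#' @export
emt_ks <- function(x, epithelial_set, mesenchymal_set) {
  vals <- .as_expr_values(x)
  epi <- intersect(epithelial_set, rownames(vals))
  mes <- intersect(mesenchymal_set, rownames(vals))
  if (length(epi) < 2 || length(mes) < 2) {
    stop("each set needs >= 2 genes present in the matrix", call. = FALSE)
  }
  if (length(intersect(epi, mes)) > 0) {
    stop("epithelial and mesenchymal sets overlap after intersection: ",
         paste(head(intersect(epi, mes), 3), collapse = ", "), call. = FALSE)
  }
  score <- vapply(seq_len(ncol(vals)), function(j) {
    e <- vals[epi, j]
    m <- vals[mes, j]
    pts <- sort(unique(c(e, m)))
    fe <- vapply(pts, function(t) mean(e <= t), numeric(1))
    fm <- vapply(pts, function(t) mean(m <= t), numeric(1))
    dplus <- max(fe - fm)
    dminus <- max(fm - fe)
    if (dplus > dminus) dplus
    else if (dminus > dplus) -dminus
    else sign(mean(m) - mean(e)) * dplus  # tie: direction by mean shift
  }, numeric(1))
  tibble(sample_id = colnames(vals), emt_ks = score)
}

#' Small-panel directional EMT score
#'
#' Z-scores each panel gene across samples, flips the sign of
#' epithelial-direction genes, and averages — the panel analogue of a
#' published compact EMT score (the gene list is supplied by the caller;
#' this package ships no default claim about its identity). Higher = more
#' mesenchymal.
#'
#' @param x logCPM [expression_matrix()].
#' @param gene_list Panel genes (absent genes dropped with a warning; at
#'   least one must be present).
#' @param directions Character vector (`"epithelial"`/`"mesenchymal"`),
#'   same length as `gene_list`.
#' @return Tibble `sample_id`, `emt_kgene`.
#' @export
emt_kgene <- function(x, gene_list, directions) {
  stopifnot(length(gene_list) == length(directions))
  if (!all(directions %in% c("epithelial", "mesenchymal"))) {
    stop("directions must be 'epithelial' or 'mesenchymal'", call. = FALSE)
  }
  vals <- .as_expr_values(x)
  present <- gene_list %in% rownames(vals)
  if (!any(present)) stop("no panel gene present in the matrix", call. = FALSE)
  if (!all(present)) {
    warning(sum(!present), " panel gene(s) absent; dropped", call. = FALSE)
  }
  genes <- gene_list[present]
  dirs <- directions[present]
  z <- t(scale(t(vals[genes, , drop = FALSE])))
  z[is.nan(z)] <- 0   # constant genes contribute 0
  sgn <- ifelse(dirs == "epithelial", -1, 1)
  tibble(sample_id = colnames(vals),
         emt_kgene = unname(colMeans(sgn * z)))
}

#' Marker-based immune population scores
#'
#' MCP-counter-style abundance surrogate: each population's score in a
#' sample is the arithmetic mean logCPM of its marker genes present in the
#' matrix. Populations with no present marker are omitted with a warning.
#'
#' @param x logCPM [expression_matrix()].
#' @param marker_sets Named list of marker gene vectors (e.g. from
#'   [read_gmt()]).
#' @return Tibble `sample_id` plus one column per scored population.
#' @export
marker_scores <- function(x, marker_sets) {
  vals <- .as_expr_values(x)
  out <- tibble(sample_id = colnames(vals))
  scored <- 0
  for (pop in names(marker_sets)) {
    genes <- intersect(marker_sets[[pop]], rownames(vals))
    if (length(genes) == 0) {
      warning("population '", pop, "' has no marker present; omitted",
              call. = FALSE)
      next
    }
    out[[pop]] <- unname(colMeans(vals[genes, , drop = FALSE]))
    scored <- scored + 1
  }
  if (scored == 0) stop("no population had any marker present", call. = FALSE)
  out
}

#' Compare one gene's expression across sample groups
#'
#' Per-group median and IQR plus a two-sided Wilcoxon rank-sum p-value for
#' two groups, or Kruskal-Wallis for more — the single-gene comparison used
#' e.g. for PD-L1 across signature classes.
#'
#' @param x logCPM [expression_matrix()].
#' @param gene Gene symbol.
#' @param groups Tibble `sample_id`, `group`, or a named vector
#'   sample_id -> group. At least 2 groups of at least 2 samples each.
#' @return Tibble: one row per group (`group`, `n`, `median`, `iqr`) with
#'   the shared `p_value` and `method` columns.
#' @export
compare_gene_across_groups <- function(x, gene, groups) {
  vals <- .as_expr_values(x)
  if (!gene %in% rownames(vals)) stop("gene ", gene, " absent", call. = FALSE)
  g <- if (is.data.frame(groups)) {
    setNames(as.character(groups$group), groups$sample_id)
  } else {
    setNames(as.character(groups), names(groups))
  }
  g <- g[intersect(names(g), colnames(vals))]
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  v <- vals[gene, names(g)]
  if (length(tab) == 2) {
    lv <- names(tab)
    ht <- suppressWarnings(wilcox.test(v[g == lv[1]], v[g == lv[2]]))
    method <- "wilcoxon"
  } else {
    ht <- kruskal.test(split(v, g))
    method <- "kruskal-wallis"
  }
  dplyr::summarise(
    dplyr::group_by(tibble(group = g, value = v), .data$group),
    n = dplyr::n(),
    median = median(.data$value),
    iqr = stats::IQR(.data$value),
    .groups = "drop"
  ) |>
    dplyr::mutate(p_value = ht$p.value, method = method)
}
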