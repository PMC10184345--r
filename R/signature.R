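#' Extreme anchor groups
#'
#' Ranks samples by the anchor microRNA value and returns the bottom and top
#' `n_extreme` samples — the contrast the supervised signature is derived
#' from. Boundary ties are broken by lexicographic sample id with a warning.
#'
#' @param annotations Annotation tibble with `sample_id` and `anchor_value`.
#' @param n_extreme Group size (default 15).
#' @return List with character vectors `low` and `high`.
#' @export
extreme_groups <- function(annotations, n_extreme = 15) {
  stopifnot(n_extreme >= 1)
  ann <- annotations[!is.na(annotations$anchor_value), ]
  if (nrow(ann) < 2 * n_extreme) {
    stop("need at least ", 2 * n_extreme, " samples with known anchor value, have ",
         nrow(ann), call. = FALSE)
  }
  if (length(unique(ann$anchor_value)) == 1) {
    stop("degenerate anchor ranking: all anchor values identical", call. = FALSE)
  }
  ord <- order(ann$anchor_value, ann$sample_id)
  v <- ann$anchor_value[ord]
  n <- length(v)
  # warn when a tie straddles a group boundary (the lexicographic rule decides)
  if (v[n_extreme] == v[n_extreme + 1] || v[n - n_extreme + 1] == v[n - n_extreme]) {
    warning("anchor tie at a group boundary; broken by sample id", call. = FALSE)
  }
  ids <- ann$sample_id[ord]
  list(low = ids[seq_len(n_extreme)], high = ids[seq(n - n_extreme + 1, n)])
}

# vectorised Welch two-sample t over matrix rows; positive = higher in high
.welch_t <- function(vals, low, high) {
  a <- vals[, low, drop = FALSE]
  b <- vals[, high, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  diff <- m2 - m1
  t <- numeric(length(diff))
  zero_var <- se == 0
  if (any(zero_var & diff != 0)) {
    # constant within both groups but different between them: effectively
    # infinite separation; use a huge finite statistic to keep ranks sane
    t[zero_var & diff != 0] <- sign(diff[zero_var & diff != 0]) * 1e12
  }
  if (any(zero_var & diff == 0)) {
    warning(sum(zero_var & diff == 0),
            " gene(s) with zero variance in both groups; statistic set to 0",
            call. = FALSE)
  }
  ok <- !zero_var
  t[ok] <- diff[ok] / se[ok]
  t
}

#' Rank genes by differential expression between two sample groups
#'
#' Per-gene Welch two-sample t statistic between the groups; genes ordered by
#' `|t|` descending (ties by symbol). The sign gives the direction:
#' positive means higher in the `high` (anchor-high) group, i.e. a
#' miR-200-sign-up gene.
#'
#' @param x logCPM [expression_matrix()].
#' @param low,high Disjoint character vectors of sample ids, each of size
#'   at least 2.
#' @param n_de Number of top genes returned (default 1500).
#' @return Tibble `gene`, `statistic`, `direction` (`"up"`/`"down"`), ordered
#'   by decreasing `|statistic|`.
#' @export
rank_differential <- function(x, low, high, n_de = 1500) {
  vals <- .as_expr_values(x)
  if (length(intersect(low, high)) > 0) stop("groups must be disjoint", call. = FALSE)
  if (length(low) < 2 || length(high) < 2) stop("each group needs >= 2 samples", call. = FALSE)
  missing_s <- setdiff(c(low, high), colnames(vals))
  if (length(missing_s) > 0) {
    stop("sample(s) not in matrix: ", paste(head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  t <- .welch_t(vals, low, high)
  ord <- order(-abs(t), rownames(vals))
  n_de <- min(n_de, nrow(vals))
  top <- ord[seq_len(n_de)]
  tibble(gene = rownames(vals)[top],
         statistic = t[top],
         direction = ifelse(t[top] >= 0, "up", "down"))
}

#' Derive the anchor-supervised gene signature
#'
#' Intersects the differentially expressed gene list (anchor-high vs
#' anchor-low contrast) with the most-variable gene set, preserving the
#' `|t|` ordering of the differential list — the analogue of intersecting
#' 1500 anchor-associated genes with the 1500 most variable genes to obtain
#' a 493-gene signature.
#'
#' @param de Tibble from [rank_differential()].
#' @param variable_set Tibble from [select_most_variable()] or a character
#'   vector of genes.
#' @param metadata Optional named list recorded on the result (e.g.
#'   `n_extreme`, anchor name).
#' @return Tibble `gene`, `statistic`, `direction` of class
#'   `gene_signature`, with derivation metadata in attributes.
#' @export
derive_signature <- function(de, variable_set, metadata = list()) {
  vg <- if (is.data.frame(variable_set)) variable_set$gene else variable_set
  if (nrow(de) == 0 || length(vg) == 0) stop("empty input list", call. = FALSE)
  sig <- de[de$gene %in% vg, , drop = FALSE]
  if (nrow(sig) == 0) {
    stop("empty intersection between differential and variable gene lists",
         call. = FALSE)
  }
  out <- as_tibble(sig)
  class(out) <- c("gene_signature", class(out))
  attr(out, "metadata") <- utils::modifyList(
    list(n_de = nrow(de), n_variable = length(vg)), metadata)
  out
}

#' Hierarchical clustering restricted to the signature genes
#'
#' Delegates to [hierarchical_cluster()] on the signature genes and names
#' the resulting clusters by mean anchor value: the cluster with the lowest
#' mean anchor becomes `I` (the miR-200-sign-down-like cluster), and the
#' remaining clusters `II`, or `IIA`/`IIB` when `k = 3`, in increasing
#' anchor order.
#'
#' @param x logCPM [expression_matrix()].
#' @param signature A `gene_signature` tibble or character vector of genes.
#' @param annotations Annotation tibble supplying `anchor_value`.
#' @param k Number of clusters (2 or 3 are the meaningful choices here).
#' @inheritParams hierarchical_cluster
#' @return Tibble `sample_id`, `cluster` (integer), `label` (I/II/IIA/IIB...).
#' @export
cluster_on_signature <- function(x, signature, annotations, k = 3,
                                 distance = "pearson", linkage = "ward") {
  genes <- if (is.data.frame(signature)) signature$gene else signature
  cl <- hierarchical_cluster(x, genes = genes, k = k,
                             distance = distance, linkage = linkage)
  anchors <- setNames(annotations$anchor_value, annotations$sample_id)
  mean_anchor <- tapply(anchors[cl$sample_id], cl$cluster, mean)
  ord <- order(mean_anchor)   # lowest anchor -> cluster I
  label_names <- if (k == 2) c("I", "II") else if (k == 3) c("I", "IIA", "IIB") else
    c("I", paste0("II", LETTERS[seq_len(k - 1)]))
  label_map <- setNames(label_names, names(mean_anchor)[ord])
  cl$label <- unname(label_map[as.character(cl$cluster)])
  cl
}
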