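#' Agglomerative clustering of samples into expression subtypes
#'
#' Clusters samples on a gene subset with distance `1 - Pearson correlation`
#' between sample profiles and Ward linkage (the dominant convention for
#' expression heatmap clustering; both are configurable), then cuts the tree
#' into `k` groups. The partition is deterministic given the input and does
#' not depend on sample column order.
#'
#' @param x logCPM [expression_matrix()].
#' @param genes Genes to cluster on (default: all rows of `x`).
#' @param k Number of clusters, `2 <= k <= n_samples`.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage `"ward"` (ward.D2), `"average"` or `"complete"`.
#' @return Tibble `sample_id`, `cluster` (integer 1..k) with attributes
#'   `k`, `distance`, `linkage`, and the `hclust` tree in attribute `tree`.
#' @export
hierarchical_cluster <- function(x, genes = NULL, k = 3,
                                 distance = c("pearson", "euclidean"),
                                 linkage = c("ward", "average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  vals <- .as_expr_values(x)
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(vals))
    if (length(missing_g) > 0) {
      stop("gene(s) not in matrix: ", paste(head(missing_g, 5), collapse = ", "),
           call. = FALSE)
    }
    vals <- vals[genes, , drop = FALSE]
  }
  n <- ncol(vals)
  if (k < 2 || k > n) stop("k must be between 2 and the number of samples", call. = FALSE)
  if (distance == "pearson") {
    sds <- apply(vals, 2, sd)
    if (any(sds == 0)) {
      stop("constant sample profile (undefined correlation): ",
           colnames(vals)[sds == 0][1], call. = FALSE)
    }
    d <- as.dist(1 - cor(vals))
  } else {
    d <- stats::dist(t(vals))
  }
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  tree <- hclust(d, method = method)
  labels <- cutree(tree, k = k)
  out <- tibble(sample_id = colnames(vals), cluster = unname(labels))
  attr(out, "k") <- k
  attr(out, "distance") <- distance
  attr(out, "linkage") <- linkage
  attr(out, "tree") <- tree
  out
}

#' Per-class mean expression centroids
#'
#' @param x logCPM [expression_matrix()].
#' @param assignment Tibble `sample_id`, class column (`cluster` or `class`
#'   or `label`); or a named vector sample_id -> class.
#' @param genes Optional gene subset.
#' @return Matrix genes x classes of per-class mean expression.
#' @export
compute_centroids <- function(x, assignment, genes = NULL) {
  vals <- .as_expr_values(x)
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  lab <- .assignment_vector(assignment)
  missing_s <- setdiff(colnames(vals), names(lab))
  if (length(missing_s) > 0) {
    stop("assignment does not cover sample(s): ",
         paste(head(missing_s, 5), collapse = ", "), call. = FALSE)
  }
  lab <- lab[colnames(vals)]
  classes <- sort(unique(lab))
  cent <- vapply(classes, function(cl) {
    members <- names(lab)[lab == cl]
    if (length(members) == 0) stop("empty class: ", cl, call. = FALSE)
    rowMeans(vals[, members, drop = FALSE])
  }, numeric(nrow(vals)))
  cent <- matrix(cent, nrow = nrow(vals),
                 dimnames = list(rownames(vals), as.character(classes)))
  cent
}

.assignment_vector <- function(assignment) {
  if (is.data.frame(assignment)) {
    col <- intersect(c("class", "label", "cluster"), names(assignment))[1]
    if (is.na(col)) stop("assignment needs a class/label/cluster column", call. = FALSE)
    setNames(as.character(assignment[[col]]), assignment$sample_id)
  } else if (!is.null(names(assignment))) {
    setNames(as.character(assignment), names(assignment))
  } else {
    stop("assignment must be a data frame or a named vector", call. = FALSE)
  }
}

#' Nearest-centroid assignment by Pearson correlation
#'
#' Correlates each sample profile with each reference class centroid over the
#' shared genes and assigns the class with the highest correlation
#' (correlation is affine-invariant, so scaled/shifted copies of a centroid
#' still match it perfectly). Ties are broken by class-name order with a
#' warning.
#'
#' @param x logCPM [expression_matrix()].
#' @param reference Genes x classes centroid matrix (rownames = genes).
#' @return Tibble: `sample_id`, `class` (assigned), `best_cor`, plus one
#'   `cor_<class>` column per reference class.
#' @export
assign_by_centroid_correlation <- function(x, reference) {
  vals <- .as_expr_values(x)
  shared <- intersect(rownames(vals), rownames(reference))
  if (length(shared) < 2) stop("fewer than 2 shared genes with the reference", call. = FALSE)
  vs <- vals[shared, , drop = FALSE]
  rf <- reference[shared, , drop = FALSE]
  if (any(apply(vs, 2, sd) == 0)) {
    stop("zero-variance sample profile over shared genes: ",
         colnames(vs)[apply(vs, 2, sd) == 0][1], call. = FALSE)
  }
  if (any(apply(rf, 2, sd) == 0)) {
    stop("zero-variance reference centroid over shared genes", call. = FALSE)
  }
  cors <- cor(vs, rf)   # samples x classes
  best <- apply(cors, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1) {
      warning("correlation tie; assigned first class in name order", call. = FALSE)
    }
    top[1]
  })
  out <- tibble(
    sample_id = colnames(vs),
    class = colnames(rf)[best],
    best_cor = cors[cbind(seq_len(nrow(cors)), best)]
  )
  cor_cols <- as_tibble(as.data.frame(cors))
  names(cor_cols) <- paste0("cor_", colnames(rf))
  dplyr::bind_cols(out, cor_cols)
}
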