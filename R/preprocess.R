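#' Convert raw counts to log2 counts-per-million
#'
#' `logCPM(g, s) = log2((count(g, s) + c) / (libsize(s) + 2c) * 1e6)` with
#' prior count `c` (default 0.5) stabilising zeros. Library size is the
#' column sum of raw counts. Preserves the within-sample rank order of genes.
#'
#' @param x An [expression_matrix()] with unit `"counts"`.
#' @param prior_count Prior count `c` added to every cell.
#' @return An [expression_matrix()] with unit `"logCPM"`.
#' @export
counts_to_logcpm <- function(x, prior_count = 0.5) {
  if (expr_unit(x) != "counts") stop("input unit must be counts", call. = FALSE)
  stopifnot(prior_count >= 0)
  vals <- .as_expr_values(x)
  lib <- colSums(vals)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(vals)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  denom <- rep(lib + 2 * prior_count, each = nrow(vals))
  out <- log2((vals + prior_count) / denom * 1e6)
  expression_matrix(out, unit = "logCPM")
}

#' Drop samples with low tumor-cell content
#'
#' Samples whose pathology-reviewed tumor-cell fraction is strictly below
#' `min_fraction` are excluded (the boundary value is kept). Samples with
#' unknown content are retained with a warning.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param min_fraction Exclusion threshold, default 0.20.
#' @return Character vector of retained sample identifiers.
#' @export
filter_by_tumor_content <- function(annotations, min_fraction = 0.20) {
  tc <- annotations$tumor_content
  unknown <- is.na(tc)
  if (any(unknown)) {
    warning(sum(unknown), " sample(s) with unknown tumor content retained",
            call. = FALSE)
  }
  keep <- unknown | tc >= min_fraction
  annotations$sample_id[keep]
}

#' Select the most variable genes
#'
#' Genes are ranked by variance of logCPM across samples (descending); ties
#' broken by lexicographic gene symbol. The dispersion statistic is
#' configurable (`"variance"` or `"mad"`).
#'
#' @param x logCPM [expression_matrix()].
#' @param n Number of genes requested (default 1500). If `n` exceeds the
#'   gene count, all genes are returned with a warning.
#' @param statistic Dispersion measure.
#' @return Tibble `gene`, `dispersion`, ordered by decreasing dispersion.
#' @export
select_most_variable <- function(x, n = 1500, statistic = c("variance", "mad")) {
  statistic <- match.arg(statistic)
  stopifnot(n >= 1)
  vals <- .as_expr_values(x)
  disp <- switch(statistic,
    variance = rowSums((vals - rowMeans(vals))^2) / (ncol(vals) - 1),
    mad = apply(vals, 1, stats::mad)
  )
  if (n > nrow(vals)) {
    warning("requested ", n, " genes but only ", nrow(vals), " available",
            call. = FALSE)
    n <- nrow(vals)
  }
  ord <- order(-disp, rownames(vals))
  top <- ord[seq_len(n)]
  tibble(gene = rownames(vals)[top], dispersion = unname(disp[top]))
}
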