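#' Construct a validated expression matrix
#'
#' The package's expression container is a plain numeric matrix with genes in
#' rows and samples in columns, plus a `unit` attribute recording whether the
#' values are raw counts or log2 counts-per-million (logCPM). All downstream
#' functions accept this container.
#'
#' @param values Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene symbols) and colnames (sample identifiers).
#' @param unit `"counts"` or `"logCPM"`. Counts must be non-negative and
#'   integral.
#' @return The matrix with class `expression_matrix` and a `unit` attribute.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(c("A", "B", "C"), c("S1", "S2")))
#' expression_matrix(m, unit = "counts")
#' @export
expression_matrix <- function(values, unit = c("logCPM", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs rownames (genes) and colnames (samples)",
         call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    stop("duplicate gene identifiers: ", paste(head(dup_g, 5), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicate sample identifiers: ", paste(head(dup_s, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("expression values must be complete (no NA)", call. = FALSE)
  if (unit == "counts") {
    if (any(values < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("counts must be integral", call. = FALSE)
    }
  }
  structure(values, unit = unit, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_unit(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 5))
  invisible(x)
}

#' Expression unit of a matrix
#' @param x An `expression_matrix` (or plain matrix, in which case `"logCPM"`
#'   is assumed).
#' @return `"counts"` or `"logCPM"`.
#' @export
expr_unit <- function(x) attr(x, "unit") %||% "logCPM"

# subsetting keeps the unit tag; drop is forced off so a single gene/sample
# stays a matrix
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  structure(out, unit = expr_unit(x), class = class(x))
}

.as_expr_values <- function(x) {
  if (!is.matrix(x)) stop("expected a genes x samples matrix", call. = FALSE)
  # plain matrix for internal math: ordinary drop semantics, no unit tag
  x <- unclass(x)
  attr(x, "unit") <- NULL
  x
}
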