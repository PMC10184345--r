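#' Read a gene x sample expression table
#'
#' Expects a tab-delimited text file: first column gene symbols, header row of
#' sample identifiers, numeric cells. Lines starting with `#` are treated as
#' comments. Duplicate gene rows are collapsed by keeping the row with the
#' highest mean value (with a message); duplicate sample columns are an error.
#'
#' @param path File path.
#' @param unit Declared unit of the stored values (`"logCPM"` or `"counts"`).
#' @return An [expression_matrix()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, unit = c("logCPM", "counts")) {
  unit <- match.arg(unit)
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("malformed expression file: need header plus data rows", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("malformed header: no sample columns", call. = FALSE)
  sample_ids <- header[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0) {
    stop("duplicate sample identifier(s) in header: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != length(header))
  if (length(bad) > 0) {
    stop("row ", bad[1] + 1, " has ", nf[bad[1]], " fields, expected ",
         length(header), call. = FALSE)
  }
  genes <- vapply(rows, `[[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col_chr <- vapply(rows, `[[`, character(1), j + 1)
    col_num <- suppressWarnings(as.numeric(col_chr))
    if (anyNA(col_num)) {
      i <- which(is.na(col_num))[1]
      stop(sprintf("non-numeric cell at row %d (gene %s), column %s: '%s'",
                   i + 1, genes[i], sample_ids[j], col_chr[i]), call. = FALSE)
    }
    vals[, j] <- col_num
  }
  rownames(vals) <- genes
  if (anyDuplicated(genes)) {
    # keep, per duplicated symbol, the row with the highest mean value
    means <- rowMeans(vals)
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)
    message("collapsed ", length(genes) - length(keep),
            " duplicate gene row(s), keeping highest-mean row per symbol")
    vals <- vals[keep, , drop = FALSE]
  }
  expression_matrix(vals, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expression_matrix()] or plain genes x samples matrix.
#' @param path Output path.
#' @param digits Number of decimal places written (default 6). Values
#'   round-trip through [read_expression()] at this precision.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @export
write_expression <- function(x, path, digits = 6, header = NULL) {
  vals <- .as_expr_values(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene", colnames(vals)), collapse = "\t"), con)
  body <- apply(vals, 1, function(r) paste(formatC(r, digits = digits, format = "f"),
                                           collapse = "\t"))
  writeLines(paste(rownames(vals), body, sep = "\t"), con)
  invisible(path)
}

.STAGE_LEVELS <- c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV", "unknown")
.MUTATION_GENES <- c("TP53", "KRAS", "EGFR", "STK11")

#' Read per-sample clinical and molecular annotations
#'
#' Tab-delimited file with required columns `sample_id`, `anchor_value`
#' (the anchor microRNA level, e.g. a delta-delta-Ct value), `dfs_time`
#' (months) and `dfs_event` (0/1). Recognised optional columns: `os_time`,
#' `os_event`, `stage` (IA..IV), `tumor_content` (fraction in \[0,1\]), and
#' mutation flags `TP53`, `KRAS`, `EGFR`, `STK11` with values
#' `mutant` / `wild-type` / `unknown`. Missing optional fields default to
#' `"unknown"` (or `NA` for optional numeric fields).
#'
#' @param path File path.
#' @return A tibble, one row per sample, `stage` an ordered factor.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_annotations(as_tibble(df))
}

#' Validate (and complete) an annotation table
#'
#' Applies the same rules as [read_annotations()] to an in-memory data frame:
#' required columns present, events in \{0,1\}, non-negative times, optional
#' columns filled with `"unknown"`/`NA` defaults.
#'
#' @param df Data frame of per-sample annotations.
#' @return A validated tibble.
#' @export
validate_annotations <- function(df) {
  df <- as_tibble(df)
  required <- c("sample_id", "anchor_value", "dfs_time", "dfs_event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required annotation column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in annotations: ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  }
  check_surv <- function(time, event, what) {
    if (any(stats::na.omit(time) < 0)) stop(what, " time must be non-negative", call. = FALSE)
    ev <- stats::na.omit(event)
    if (!all(ev %in% c(0, 1))) {
      stop(what, " event must be 0 or 1, got: ",
           paste(unique(ev[!ev %in% c(0, 1)]), collapse = ", "), call. = FALSE)
    }
  }
  check_surv(df$dfs_time, df$dfs_event, "dfs")
  if (!"os_time" %in% names(df)) df$os_time <- NA_real_
  if (!"os_event" %in% names(df)) df$os_event <- NA_real_
  check_surv(df$os_time, df$os_event, "os")
  if (!"stage" %in% names(df)) df$stage <- "unknown"
  df$stage <- as.character(df$stage)
  df$stage[is.na(df$stage)] <- "unknown"
  bad_stage <- setdiff(unique(df$stage), .STAGE_LEVELS)
  if (length(bad_stage) > 0) {
    stop("unrecognised stage value(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  df$stage <- factor(df$stage, levels = .STAGE_LEVELS, ordered = TRUE)
  if (!"tumor_content" %in% names(df)) df$tumor_content <- NA_real_
  tc <- stats::na.omit(df$tumor_content)
  if (any(tc < 0 | tc > 1)) stop("tumor_content must lie in [0, 1]", call. = FALSE)
  for (g in .MUTATION_GENES) {
    if (!g %in% names(df)) df[[g]] <- "unknown"
    df[[g]] <- as.character(df[[g]])
    df[[g]][is.na(df[[g]])] <- "unknown"
    bad <- setdiff(unique(df[[g]]), c("mutant", "wild-type", "unknown"))
    if (length(bad) > 0) {
      stop("mutation flag for ", g, " must be mutant/wild-type/unknown, got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write an annotation table as TSV
#' @param df Annotation tibble.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_annotations <- function(df, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  close(con)
  readr::write_tsv(df, path, append = !is.null(header),
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT semantics: one set per line, fields `name`, `description`,
#' then members, tab-separated. Member order is preserved; duplicate members
#' within a set are collapsed with a warning.
#'
#' @param path File path.
#' @return Named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields (set '",
         fields[[which(nf < 3)[1]]][1], "' has no members)", call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name: ", names_[duplicated(names_)][1], call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, anyDuplicated, integer(1)) > 0)
  if (ndup > 0) {
    warning(ndup, " set(s) contained duplicate members; collapsed", call. = FALSE)
    sets <- lapply(sets, unique)
  }
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(desc, names_)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(n) {
    paste(c(n, desc[[n]] %||% "na", sets[[n]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

# header line stamped on every pipeline output table: config hash + seed
.output_header <- function(config) {
  sprintf("mir200sig config=%s seed=%s",
          digest::digest(config), config$seed %||% "NA")
}

.write_stamped_tsv <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(paste0("# ", .output_header(config)), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
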