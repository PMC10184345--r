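#' Select the discriminant centroid gene panel
#'
#' Ranks genes by absolute Welch t statistic between the two initial classes
#' and keeps the top `n_panel`, enforcing (when available) at least 25%
#' representation of each direction so the panel cannot collapse onto a
#' single program. Ties break by gene symbol; swapping the class names
#' yields the identical panel.
#'
#' @param x logCPM [expression_matrix()].
#' @param labels Tibble `sample_id` + class column, or named vector, with
#'   exactly two classes of at least 2 samples each.
#' @param n_panel Panel size (default 150).
#' @return Character vector of panel genes (ordered by decreasing `|t|`).
#' @export
select_centroid_panel <- function(x, labels, n_panel = 150) {
  vals <- .as_expr_values(x)
  lab <- .assignment_vector(labels)
  lab <- lab[intersect(names(lab), colnames(vals))]
  classes <- sort(unique(lab))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  g1 <- names(lab)[lab == classes[1]]
  g2 <- names(lab)[lab == classes[2]]
  if (length(g1) < 2 || length(g2) < 2) stop("each class needs >= 2 samples", call. = FALSE)
  t <- .welch_t(vals, g1, g2)
  names(t) <- rownames(vals)
  if (n_panel >= length(t)) {
    if (n_panel > length(t)) {
      warning("panel size exceeds gene count; returning all ", length(t),
              " genes", call. = FALSE)
    }
    return(names(t)[order(-abs(t), names(t))])
  }
  ord <- order(-abs(t), names(t))
  sel <- ord[seq_len(n_panel)]
  min_dir <- floor(0.25 * n_panel)
  for (s in c(1, -1)) {
    have <- sum(sign(t[sel]) == s)
    avail <- sum(sign(t) == s)
    need <- min(min_dir, avail) - have
    if (need > 0) {
      # swap in the strongest unselected genes of the missing direction for
      # the weakest selected genes of the other direction
      cand <- setdiff(ord[sign(t[ord]) == s], sel)[seq_len(need)]
      drop_pool <- sel[sign(t[sel]) != s]
      drop <- rev(drop_pool)[seq_len(need)]
      sel <- c(setdiff(sel, drop), cand)
    }
  }
  sel <- sel[order(-abs(t[sel]), names(t)[sel])]
  names(t)[sel]
}

#' Constrained mixture-weight estimation for one or more samples
#'
#' Solves, per sample, `min || x - sum_k w_k c_k ||^2` subject to
#' `w_k >= 0`, `sum w_k = 1` — the per-tumor "impregnation" of each
#' reference transcriptional program. For two classes the solution is the
#' closed-form clamped projection onto the segment between the centroids:
#' `w_up = clamp(((x - c_down) . (c_up - c_down)) / ||c_up - c_down||^2, 0, 1)`.
#' Three or more classes fall back to non-negative least squares followed by
#' simplex renormalization (an approximation, documented as such).
#'
#' @param x logCPM [expression_matrix()] (or single named numeric profile).
#' @param centroids Genes x classes matrix; column names are the class names.
#' @param gene_weights Optional non-negative per-gene weights for a weighted
#'   least-squares objective (default: unweighted).
#' @param min_panel_fraction Refuse to score when fewer than this fraction of
#'   centroid genes is present in `x` (default 0.5); silent degradation
#'   would corrupt the weights.
#' @return Tibble: `sample_id`, one `w_<class>` column per class, and the
#'   per-sample `residual` (Euclidean norm of the fit residual).
#' @examples
#' cent <- cbind(down = c(0, 0, 0), up = c(1, 1, 1))
#' rownames(cent) <- c("g1", "g2", "g3")
#' x <- matrix(0.3, 3, 1, dimnames = list(rownames(cent), "s1"))
#' estimate_weights(x, cent)
#' @export
estimate_weights <- function(x, centroids, gene_weights = NULL,
                             min_panel_fraction = 0.5) {
  if (is.null(dim(x))) {
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  }
  vals <- .as_expr_values(x)
  if (is.null(rownames(centroids)) || is.null(colnames(centroids))) {
    stop("centroids need gene rownames and class colnames", call. = FALSE)
  }
  shared <- intersect(rownames(centroids), rownames(vals))
  if (length(shared) < 2) stop("fewer than 2 shared genes with the centroids", call. = FALSE)
  if (length(shared) < min_panel_fraction * nrow(centroids)) {
    stop(sprintf("only %d of %d centroid genes present (< %.0f%%); refusing to score",
                 length(shared), nrow(centroids), 100 * min_panel_fraction),
         call. = FALSE)
  }
  cent <- centroids[shared, , drop = FALSE]
  vs <- vals[shared, , drop = FALSE]
  k <- ncol(cent)
  gw <- gene_weights
  if (!is.null(gw)) {
    if (!is.null(names(gw))) gw <- gw[shared]
    if (any(is.na(gw)) || any(gw < 0) || all(gw == 0)) {
      stop("gene_weights must be non-negative with at least one positive",
           call. = FALSE)
    }
  }
  if (k == 2) {
    d <- cent[, 2] - cent[, 1]
    if (all(d == 0)) stop("degenerate centroids: classes are identical", call. = FALSE)
    gwv <- gw %||% rep(1, length(d))
    denom <- sum(gwv * d^2)
    if (denom == 0) stop("degenerate centroids under the gene weights", call. = FALSE)
    xc <- vs - cent[, 1]
    w2 <- pmin(pmax(colSums(xc * (gwv * d)) / denom, 0), 1)
    W <- cbind(1 - w2, w2)
  } else {
    W <- t(vapply(seq_len(ncol(vs)), function(j) {
      .nnls_simplex(cent, vs[, j], gw)
    }, numeric(k)))
  }
  fitted <- cent %*% t(W)
  res <- sqrt(colSums((vs - fitted)^2))
  out <- tibble(sample_id = colnames(vs))
  for (i in seq_len(k)) out[[paste0("w_", .class_key(colnames(cent)[i]))]] <- unname(W[, i])
  out$residual <- unname(res)
  out
}

# short column-safe key for a class name ("miR-200-sign-up" -> "up")
.class_key <- function(cls) {
  key <- c("miR-200-sign-down" = "down", "miR-200-sign-up" = "up")[cls]
  ifelse(is.na(key), gsub("[^A-Za-z0-9]+", "_", cls), key)
}

# non-negative least squares (Lawson-Hanson style active set) followed by
# renormalization onto the simplex; used only for >= 3 classes
.nnls_simplex <- function(A, b, gene_weights = NULL) {
  if (!is.null(gene_weights)) {
    s <- sqrt(gene_weights)
    A <- A * s
    b <- b * s
  }
  k <- ncol(A)
  passive <- rep(TRUE, k)
  w <- rep(0, k)
  for (iter in seq_len(10 * k)) {
    if (!any(passive)) break
    sol <- stats::coef(stats::lm.fit(A[, passive, drop = FALSE], b))
    if (all(sol >= -1e-12)) {
      w[passive] <- pmax(sol, 0)
      break
    }
    idx <- which(passive)
    passive[idx[which.min(sol)]] <- FALSE
    w[] <- 0
  }
  if (sum(w) == 0) stop("degenerate centroids: NNLS collapsed to zero", call. = FALSE)
  w / sum(w)
}

#' Fit the centroid-refinement deconvolution model
#'
#' The training loop of the weighted-in-silico-pathology approach:
#' starting from two initial classes (typically `I` -> down, `II` -> up from
#' [cluster_on_signature()]), iterate (1) class centroids = per-class means
#' over the current pure samples (initially all class members), (2) estimate
#' mixture weights for every sample against those centroids, (3) redefine
#' the pure samples of each class as those whose top weight reaches
#' `purity_threshold`. Stops when the pure-sample sets are unchanged or
#' after `max_iterations`.
#'
#' Note the centroids are estimated from observed pure-ish samples, which
#' are themselves mixtures; with a broad proportion distribution this
#' shrinks the estimated centroids inward relative to the latent pure
#' programs (see the package vignette).
#'
#' @param x logCPM [expression_matrix()].
#' @param initial_labels Tibble/named vector giving each sample's initial
#'   class; values must be (or map to) `miR-200-sign-down` / `miR-200-sign-up`.
#'   Cluster labels `I`/`II`/`IIA`/`IIB` are mapped automatically
#'   (I -> down, II* -> up).
#' @param panel Optional pre-selected centroid gene panel; default selects
#'   `n_panel` genes with [select_centroid_panel()].
#' @param n_panel Panel size when `panel` is NULL.
#' @param purity_threshold Weight a sample must reach for its top class to
#'   count as pure (default 0.8).
#' @param max_iterations Maximum refinement iterations (default 10).
#' @param gene_weights Optional per-gene weights (see [estimate_weights()]).
#' @return Object of class `wisp_model`: list with `centroids` (panel x 2),
#'   `weights` (tibble: `sample_id`, `w_down`, `w_up`, `residual`),
#'   `pure_samples`, `iterations`, `converged`, `panel`, `purity_threshold`.
#' @export
fit_wisp <- function(x, initial_labels, panel = NULL, n_panel = 150,
                     purity_threshold = 0.8, max_iterations = 10,
                     gene_weights = NULL) {
  stopifnot(purity_threshold > 0.5, purity_threshold <= 1, max_iterations >= 1)
  vals <- .as_expr_values(x)
  lab <- .assignment_vector(initial_labels)
  lab <- .to_updown(lab)
  lab <- lab[intersect(names(lab), colnames(vals))]
  classes <- c(.CLASS_DOWN, .CLASS_UP)
  if (!setequal(unique(lab), classes)) {
    stop("initial labels must contain both classes", call. = FALSE)
  }
  if (is.null(panel)) {
    panel <- select_centroid_panel(vals, lab, n_panel = n_panel)
  } else {
    missing_g <- setdiff(panel, rownames(vals))
    if (length(missing_g) > 0) {
      stop("panel gene(s) not in matrix: ",
           paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
    }
  }
  pv <- vals[panel, , drop = FALSE]
  pure <- list(names(lab)[lab == .CLASS_DOWN], names(lab)[lab == .CLASS_UP])
  names(pure) <- classes
  weights <- NULL
  converged <- FALSE
  iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    cent <- vapply(classes, function(cl) rowMeans(pv[, pure[[cl]], drop = FALSE]),
                   numeric(nrow(pv)))
    rownames(cent) <- panel
    weights <- estimate_weights(pv, cent, gene_weights = gene_weights)
    top_class <- ifelse(weights$w_up >= weights$w_down, .CLASS_UP, .CLASS_DOWN)
    top_w <- pmax(weights$w_up, weights$w_down)
    new_pure <- lapply(classes, function(cl) {
      weights$sample_id[top_class == cl & top_w >= purity_threshold]
    })
    names(new_pure) <- classes
    for (cl in classes) {
      if (length(new_pure[[cl]]) == 0) {
        stop("class ", cl, " lost all pure samples at iteration ", iter,
             call. = FALSE)
      }
    }
    if (setequal(new_pure[[1]], pure[[1]]) && setequal(new_pure[[2]], pure[[2]])) {
      pure <- new_pure
      converged <- TRUE
      break
    }
    pure <- new_pure
  }
  cent <- vapply(classes, function(cl) rowMeans(pv[, pure[[cl]], drop = FALSE]),
                 numeric(nrow(pv)))
  rownames(cent) <- panel
  weights <- estimate_weights(pv, cent, gene_weights = gene_weights)
  structure(
    list(centroids = cent, weights = weights, pure_samples = pure,
         iterations = iter, converged = converged, panel = panel,
         purity_threshold = purity_threshold),
    class = "wisp_model"
  )
}

.to_updown <- function(lab) {
  out <- lab
  out[lab %in% c("I", "down", .CLASS_DOWN)] <- .CLASS_DOWN
  out[grepl("^II", lab) | lab %in% c("up", .CLASS_UP)] <- .CLASS_UP
  bad <- setdiff(unique(out), c(.CLASS_DOWN, .CLASS_UP))
  if (length(bad) > 0) {
    stop("cannot map initial label(s) to classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @export
print.wisp_model <- function(x, ...) {
  cat(sprintf(
    "wisp_model: %d panel genes, %d samples, %d iteration(s)%s\n",
    length(x$panel), nrow(x$weights), x$iterations,
    if (x$converged) " (converged)" else " (max iterations reached)"))
  cat(sprintf("pure samples: %d down, %d up (threshold %.2f)\n",
              length(x$pure_samples[[.CLASS_DOWN]]),
              length(x$pure_samples[[.CLASS_UP]]), x$purity_threshold))
  invisible(x)
}

#' Tidy the per-sample weights of a fitted deconvolution model
#' @param x A `wisp_model`.
#' @param ... Ignored.
#' @return The per-sample weight tibble.
#' @export
tidy.wisp_model <- function(x, ...) x$weights

#' One-row fit summary of a deconvolution model
#' @param x A `wisp_model`.
#' @param ... Ignored.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.wisp_model <- function(x, ...) {
  tibble(
    n_panel = length(x$panel),
    n_samples = nrow(x$weights),
    iterations = x$iterations,
    converged = x$converged,
    n_pure_down = length(x$pure_samples[[.CLASS_DOWN]]),
    n_pure_up = length(x$pure_samples[[.CLASS_UP]]),
    purity_threshold = x$purity_threshold
  )
}

#' Classify samples from mixture weights
#'
#' Up-weight strictly above the cutoff is `miR-200-sign-up`, strictly below
#' is `miR-200-sign-down`; a weight exactly at the cutoff is assigned down
#' (conservative) with a warning.
#'
#' @param weights Tibble with `sample_id` and `w_up` (from
#'   [estimate_weights()] or [fit_wisp()]).
#' @param cutoff Classification cutoff on the up-weight (default 0.5).
#' @return Input tibble with a `class` column added.
#' @export
classify_weights <- function(weights, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1, "w_up" %in% names(weights))
  at <- weights$w_up == cutoff
  if (any(at)) {
    warning(sum(at), " sample(s) exactly at the cutoff assigned ",
            .CLASS_DOWN, call. = FALSE)
  }
  weights$class <- ifelse(weights$w_up > cutoff, .CLASS_UP, .CLASS_DOWN)
  weights
}

#' Bin samples into quartiles of the up-weight
#'
#' Samples are ordered by increasing up-weight (ties by sample id) and split
#' at the empirical quartile ranks: sample of rank r (of n) lands in bin
#' `floor(4 * (r - 1) / n) + 1`, so bin sizes differ by at most one.
#'
#' @param weights Tibble with `sample_id` and `w_up`.
#' @return Input tibble with a `quartile` column (`Q1`..`Q4`, Q4 = highest
#'   up-weight).
#' @export
quartile_bins <- function(weights) {
  n <- nrow(weights)
  if (n < 4) stop("need at least 4 samples for quartile bins", call. = FALSE)
  ord <- order(weights$w_up, weights$sample_id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  weights$quartile <- paste0("Q", floor(4 * (rank - 1) / n) + 1)
  weights
}

#' Score a cohort against fixed reference centroids
#'
#' Applies a trained model (or an external centroid table) to a new
#' expression matrix: estimates constrained mixture weights over the shared
#' panel genes, classifies at the cutoff and bins into quartiles. Refuses to
#' score when fewer than half the panel genes are present.
#'
#' @param x logCPM [expression_matrix()].
#' @param centroids A `wisp_model` or a genes x classes centroid matrix.
#' @param cutoff Classification cutoff (default 0.5).
#' @param gene_weights Optional per-gene objective weights.
#' @return Tibble `sample_id`, `w_down`, `w_up`, `residual`, `class`,
#'   `quartile`.
#' @export
score_mixture <- function(x, centroids, cutoff = 0.5, gene_weights = NULL) {
  cent <- if (inherits(centroids, "wisp_model")) centroids$centroids else centroids
  w <- estimate_weights(x, cent, gene_weights = gene_weights,
                        min_panel_fraction = 0.5)
  w <- classify_weights(w, cutoff = cutoff)
  if (nrow(w) >= 4) w <- quartile_bins(w)
  w
}
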