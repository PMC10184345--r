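#' Simulation parameters for a synthetic two-program cohort
#'
#' Defines the generative model under which every downstream stage is tested:
#' each tumor's expression profile is a convex mixture
#' `p * C_up + (1 - p) * C_down` of two latent transcriptional program
#' centroids plus Gaussian noise on the logCPM scale; the anchor microRNA
#' value tracks the mixture proportion; mutation flags are class-enriched;
#' and disease-free survival follows a proportional-hazards model whose
#' hazard increases with `1 - p` (the miR-200-sign-down fraction).
#'
#' @param n_samples Cohort size. Default 107, mirroring a resected
#'   lung-adenocarcinoma series of that size.
#' @param n_genes Total genes simulated.
#' @param n_program_genes Genes truly differing between the two programs
#'   (split evenly between up- and down-direction).
#' @param effect_size Mean logCPM shift of a program gene between the two
#'   pure programs (months/logCPM units as appropriate).
#' @param noise_sd Per-cell Gaussian noise sd (logCPM).
#' @param anchor_noise_sd Noise sd on the anchor value around the true
#'   proportion.
#' @param proportion_sampler Function `n -> numeric in [0,1]` drawing true
#'   mixture proportions; default uniform.
#' @param mutation_probs Named list; per gene, `c(down = p, up = p)` mutation
#'   probabilities conditional on the true class. Defaults plant TP53
#'   enrichment in the down class and EGFR/KRAS enrichment in the up class,
#'   strong enough for Fisher tests to resolve at n of about 100.
#' @param beta Log-hazard ratio on `(1 - p)`: hazard is
#'   `baseline_hazard * exp(beta * (1 - p))`.
#' @param baseline_hazard Events per month at `p = 1`.
#' @param horizon Administrative censoring time, months.
#' @param dropout Fraction of samples with additional uniform random
#'   censoring before the horizon.
#' @param n_immune_genes Marker genes per simulated immune population
#'   (lymphoid, elevated at low proportion; myeloid, elevated at high
#'   proportion).
#' @param immune_shift logCPM shift of immune markers across the proportion
#'   range.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 107,
                       n_genes = 2000,
                       n_program_genes = 300,
                       effect_size = 2,
                       noise_sd = 0.5,
                       anchor_noise_sd = 0.1,
                       proportion_sampler = stats::runif,
                       mutation_probs = list(
                         TP53 = c(down = 0.65, up = 0.15),
                         EGFR = c(down = 0.10, up = 0.45),
                         KRAS = c(down = 0.10, up = 0.40),
                         STK11 = c(down = 0.15, up = 0.10)
                       ),
                       beta = 1.5,
                       baseline_hazard = 0.0055,
                       horizon = 60,
                       dropout = 0.1,
                       n_immune_genes = 10,
                       immune_shift = 2,
                       seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1, n_program_genes <= n_genes,
            noise_sd >= 0, anchor_noise_sd >= 0, effect_size >= 0,
            baseline_hazard > 0, horizon > 0, dropout >= 0, dropout <= 1,
            2 * n_immune_genes <= n_genes - n_program_genes)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws a cohort under the model described in [sim_params()]. Gene
#' identifiers encode their role: `UPGxxx` / `DNGxxx` are planted program
#' genes (higher in the pure up / down program respectively), `LYMxx` /
#' `MYExx` are immune marker genes whose expression tracks `1 - p` / `p`,
#' and `BGDxxxx` are background genes identical in both programs.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   `expression` (an [expression_matrix()], logCPM), `annotations`
#'   (tibble), `truth` (tibble: `sample_id`, `proportion`, `class`),
#'   `centroids` (genes x 2 matrix, columns `miR-200-sign-down`,
#'   `miR-200-sign-up`), `program_genes`, `marker_sets` (list with
#'   `lymphoid`, `myeloid`, `epithelial`, `mesenchymal`), and `params`.
#' @examples
#' co <- simulate_cohort(sim_params(n_samples = 20, n_genes = 200,
#'                                  n_program_genes = 40, seed = 7))
#' dim(co$expression)
#' @export
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) stop("`params` must come from sim_params()", call. = FALSE)
  set.seed(params$seed)
  n_up <- ceiling(params$n_program_genes / 2)
  n_dn <- params$n_program_genes - n_up
  n_imm <- params$n_immune_genes
  n_bgd <- params$n_genes - params$n_program_genes - 2 * n_imm
  genes <- c(
    sprintf("UPG%04d", seq_len(n_up)),
    sprintf("DNG%04d", seq_len(n_dn)),
    if (n_imm > 0) sprintf("LYM%02d", seq_len(n_imm)),
    if (n_imm > 0) sprintf("MYE%02d", seq_len(n_imm)),
    if (n_bgd > 0) sprintf("BGD%05d", seq_len(n_bgd))
  )
  base <- rnorm(params$n_genes, mean = 6, sd = 1.5)
  names(base) <- genes
  half <- params$effect_size / 2
  c_up <- base
  c_dn <- base
  up_idx <- seq_len(n_up)
  dn_idx <- n_up + seq_len(n_dn)
  c_up[up_idx] <- base[up_idx] + half
  c_dn[up_idx] <- base[up_idx] - half
  c_up[dn_idx] <- base[dn_idx] - half
  c_dn[dn_idx] <- base[dn_idx] + half
  # immune markers are mixture-consistent too: lymphoid high in the pure
  # down program, myeloid high in the pure up program
  if (n_imm > 0) {
    lym_idx <- n_up + n_dn + seq_len(n_imm)
    mye_idx <- n_up + n_dn + n_imm + seq_len(n_imm)
    c_dn[lym_idx] <- base[lym_idx] + params$immune_shift
    c_up[mye_idx] <- base[mye_idx] + params$immune_shift
  }
  p <- params$proportion_sampler(params$n_samples)
  stopifnot(all(p >= 0 & p <= 1))
  sample_ids <- sprintf("T%03d", seq_len(params$n_samples))
  mix <- outer(c_up, p) + outer(c_dn, 1 - p)
  noise <- matrix(rnorm(params$n_genes * params$n_samples, sd = params$noise_sd),
                  nrow = params$n_genes)
  expr <- mix + noise
  dimnames(expr) <- list(genes, sample_ids)

  anchor <- p + rnorm(params$n_samples, sd = params$anchor_noise_sd)
  cls <- ifelse(p > 0.5, "up", "down")
  mut <- lapply(params$mutation_probs, function(pr) {
    prob <- ifelse(cls == "down", pr[["down"]], pr[["up"]])
    ifelse(rbinom(params$n_samples, 1, prob) == 1, "mutant", "wild-type")
  })
  # survival: exponential with hazard h0 * exp(beta * (1 - p)),
  # administrative censoring at the horizon plus random dropout
  hazard <- params$baseline_hazard * exp(params$beta * (1 - p))
  t_dfs <- rexp(params$n_samples, rate = hazard)
  cens <- rep(params$horizon, params$n_samples)
  drop <- runif(params$n_samples) < params$dropout
  cens[drop] <- runif(sum(drop), 0, params$horizon)
  dfs_time <- pmin(t_dfs, cens)
  dfs_event <- as.integer(t_dfs <= cens)
  # overall survival: same structure, later events
  t_os <- rexp(params$n_samples,
               rate = 0.6 * params$baseline_hazard * exp(params$beta * (1 - p)))
  os_time <- pmin(t_os, cens)
  os_event <- as.integer(t_os <= cens)
  stage_pool <- c("IA", "IB", "IIA", "IIB", "IIIA")
  stage <- sample(stage_pool, params$n_samples, replace = TRUE,
                  prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
  ann <- tibble(
    sample_id = sample_ids,
    anchor_value = anchor,
    dfs_time = dfs_time, dfs_event = dfs_event,
    os_time = os_time, os_event = os_event,
    stage = stage,
    tumor_content = round(runif(params$n_samples, 0.2, 0.9), 2),
    TP53 = mut$TP53, KRAS = mut$KRAS, EGFR = mut$EGFR, STK11 = mut$STK11
  )
  ann <- validate_annotations(ann)
  centroids <- cbind(c_dn, c_up)
  colnames(centroids) <- c(.CLASS_DOWN, .CLASS_UP)
  truth <- tibble(
    sample_id = sample_ids,
    proportion = p,
    class = ifelse(p > 0.5, .CLASS_UP, .CLASS_DOWN)
  )
  marker_sets <- list(
    lymphoid = genes[grepl("^LYM", genes)],
    myeloid = genes[grepl("^MYE", genes)],
    epithelial = genes[up_idx],
    mesenchymal = genes[dn_idx]
  )
  structure(
    list(expression = expression_matrix(expr, unit = "logCPM"),
         annotations = ann,
         truth = truth,
         centroids = centroids,
         program_genes = genes[c(up_idx, dn_idx)],
         marker_sets = marker_sets,
         params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genes (%d program genes), seed %s\n",
              ncol(x$expression), nrow(x$expression),
              length(x$program_genes), x$params$seed))
  invisible(x)
}

#' Per-sample ground-truth table of a synthetic cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Tibble with `sample_id`, true `proportion`, true `class`, and the
#'   anchor value actually observed.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dplyr::left_join(cohort$truth,
                   dplyr::select(cohort$annotations, "sample_id", "anchor_value"),
                   by = "sample_id")
}
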