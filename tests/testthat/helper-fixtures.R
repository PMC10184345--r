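# programmatic fixtures shared across test files

# small deterministic logCPM matrix
toy_matrix <- function(n_genes = 10, n_samples = 6, seed = 42, unit = "logCPM") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 6, sd = 2),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (unit == "counts") m <- matrix(rpois(n_genes * n_samples, 50),
                                    nrow = n_genes, dimnames = dimnames(m))
  expression_matrix(m, unit = unit)
}

# small synthetic cohort with planted structure (fast defaults for tests)
small_cohort <- function(n_samples = 60, n_genes = 400, n_program_genes = 80,
                         noise_sd = 0.5, effect_size = 2, seed = 1,
                         beta = 1.5, ...) {
  simulate_cohort(sim_params(
    n_samples = n_samples, n_genes = n_genes,
    n_program_genes = n_program_genes, noise_sd = noise_sd,
    effect_size = effect_size, beta = beta, seed = seed, ...))
}

# proportion sampler with true near-pure samples: 45% near 0, 45% near 1,
# 10% intermediate
bimodal_props <- function(n) {
  k <- stats::rmultinom(1, n, c(0.45, 0.1, 0.45))[, 1]
  p <- c(stats::rbeta(k[1], 1, 50), stats::runif(k[2], 0.2, 0.8),
         1 - stats::rbeta(k[3], 1, 50))
  sample(p)
}

# independent grid-search oracle for the two-class constrained objective
grid_weight_oracle <- function(x, c_dn, c_up, step = 0.001) {
  grid <- seq(0, 1, by = step)
  obj <- vapply(grid, function(w) sum((x - w * c_up - (1 - w) * c_dn)^2),
                numeric(1))
  grid[which.min(obj)]
}

# brute-force running-sum enrichment score (plain loop over the ranking)
brute_es <- function(stats_ordered, hits, p_exponent = 1) {
  N <- length(stats_ordered)
  is_hit <- seq_len(N) %in% hits
  wsum <- sum(abs(stats_ordered[is_hit])^p_exponent)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      inc <- if (wsum == 0) 1 / sum(is_hit) else abs(stats_ordered[i])^p_exponent / wsum
      cur <- cur + inc
    } else {
      cur <- cur - 1 / (N - sum(is_hit))
    }
    run[i] <- cur
  }
  if (max(run, 0) >= -min(run, 0)) max(run, 0) else min(run, 0)
}

# hand risk-set enumeration of the two-group log-rank statistic
brute_logrank <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + d1 - e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}
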