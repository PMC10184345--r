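make_two_class_matrix <- function() {
  # 10 genes: 2 clearly split up, 2 clearly split down, 6 flat
  set.seed(71)
  v <- matrix(rnorm(10 * 8, 5, 0.1), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  v[1:2, 5:8] <- v[1:2, 5:8] + 5   # up in class B
  v[3:4, 1:4] <- v[3:4, 1:4] + 5   # up in class A
  labels <- setNames(rep(c("down", "up"), each = 4), colnames(v))
  list(x = expression_matrix(v), labels = labels)
}

test_that("panel selection finds the discriminant genes and is label-symmetric", {
  tc <- make_two_class_matrix()
  panel <- select_centroid_panel(tc$x, tc$labels, n_panel = 4)
  expect_setequal(panel, c("g01", "g02", "g03", "g04"))
  swapped <- setNames(ifelse(tc$labels == "down", "up", "down"),
                      names(tc$labels))
  expect_setequal(select_centroid_panel(tc$x, swapped, n_panel = 4), panel)
})

test_that("panel larger than the gene count saturates with a warning", {
  tc <- make_two_class_matrix()
  expect_warning(panel <- select_centroid_panel(tc$x, tc$labels, n_panel = 25),
                 "exceeds")
  expect_setequal(panel, rownames(tc$x))
})

test_that("panel enforces at least 25% of each direction when available", {
  set.seed(81)
  v <- matrix(rnorm(40 * 12, 5, 0.05), 40, 12,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:12)))
  # 30 strong up-direction genes, 6 weaker down-direction genes
  v[1:30, 7:12] <- v[1:30, 7:12] + 3
  v[31:36, 1:6] <- v[31:36, 1:6] + 0.5
  labels <- setNames(rep(c("down", "up"), each = 6), colnames(v))
  panel <- select_centroid_panel(expression_matrix(v), labels, n_panel = 20)
  t_by_gene <- rank_differential(expression_matrix(v), names(labels)[1:6],
                                 names(labels)[7:12], n_de = 40)
  signs <- setNames(sign(t_by_gene$statistic), t_by_gene$gene)
  expect_gte(sum(signs[panel] < 0), 5)   # floor(0.25 * 20)
})

test_that("weights hit the endpoints and exact convex combinations", {
  set.seed(91)
  cent <- cbind(down = rnorm(50, 4), up = rnorm(50, 6))
  rownames(cent) <- sprintf("g%02d", 1:50)
  x <- cbind(pure_up = cent[, "up"],
             mix = 0.3 * cent[, "up"] + 0.7 * cent[, "down"])
  rownames(x) <- rownames(cent)
  w <- estimate_weights(expression_matrix(x), cent)
  expect_equal(w$w_up[1], 1)
  expect_equal(w$residual[1], 0, tolerance = 1e-9)
  expect_equal(w$w_up[2], 0.3, tolerance = 1e-9)
  expect_equal(w$w_down[2], 0.7, tolerance = 1e-9)
})

test_that("weights always lie on the simplex", {
  co <- small_cohort(seed = 7)
  w <- estimate_weights(co$expression, co$centroids)
  expect_true(all(w$w_up >= 0 & w$w_up <= 1))
  expect_true(all(abs(w$w_up + w$w_down - 1) < 1e-9))
  expect_true(all(w$residual >= 0))
})

test_that("closed-form weights match the grid-search oracle", {
  set.seed(101)
  for (i in 1:100) {
    cent <- cbind(down = rnorm(30, 5), up = rnorm(30, 5.5))
    rownames(cent) <- sprintf("g%02d", 1:30)
    p <- runif(1, -0.2, 1.2)  # include out-of-simplex targets that clamp
    x <- p * cent[, "up"] + (1 - p) * cent[, "down"] + rnorm(30, sd = 0.4)
    names(x) <- rownames(cent)
    w <- estimate_weights(x, cent)$w_up
    oracle <- grid_weight_oracle(x, cent[, "down"], cent[, "up"])
    expect_lt(abs(w - oracle), 0.002)
  }
})

test_that("identical centroids are rejected", {
  cent <- cbind(down = rep(3, 5), up = rep(3, 5))
  rownames(cent) <- paste0("g", 1:5)
  x <- setNames(rnorm(5), rownames(cent))
  expect_error(estimate_weights(x, cent), "degenerate centroids")
})

test_that("three-class fallback recovers noise-free simplex mixtures", {
  set.seed(111)
  cent <- matrix(rnorm(90, 5), 30, 3,
                 dimnames = list(sprintf("g%02d", 1:30), c("A", "B", "C")))
  w_true <- c(0.2, 0.5, 0.3)
  x <- setNames(as.numeric(cent %*% w_true), rownames(cent))
  w <- estimate_weights(x, cent)
  expect_equal(unname(unlist(w[1, c("w_A", "w_B", "w_C")])), w_true,
               tolerance = 1e-6)
})

test_that("a cohort of pure samples is a one-iteration fixed point", {
  set.seed(121)
  cent <- cbind(rnorm(60, 4), rnorm(60, 6))
  colnames(cent) <- c("miR-200-sign-down", "miR-200-sign-up")
  rownames(cent) <- sprintf("g%02d", 1:60)
  v <- cent[, c(1, 1, 1, 2, 2, 2)]
  colnames(v) <- sprintf("s%d", 1:6)
  labels <- setNames(rep(c("down", "up"), each = 3), colnames(v))
  fit <- fit_wisp(expression_matrix(v), labels, n_panel = 30)
  expect_equal(fit$iterations, 1)
  expect_true(fit$converged)
  expect_equal(fit$centroids[, 1], cent[fit$panel, 1], tolerance = 1e-12)
  expect_equal(sort(unname(fit$weights$w_up)), rep(c(0, 1), each = 3))
})

test_that("intermediate samples are excluded from the pure sets", {
  co <- small_cohort(
    n_samples = 80, n_genes = 400, n_program_genes = 80, noise_sd = 0.3,
    seed = 77,
    proportion_sampler = function(n) {
      k <- round(0.3 * n)  # 30% intermediates by construction
      c(runif(k, 0.35, 0.65),
        sample(c(runif(ceiling((n - k) / 2), 0, 0.1),
                 runif(floor((n - k) / 2), 0.9, 1))))
    })
  cl <- cluster_on_signature(co$expression, co$program_genes,
                             co$annotations, k = 2)
  fit <- fit_wisp(co$expression, cl)
  truth <- co$truth
  intermediates <- truth$sample_id[truth$proportion > 0.35 &
                                     truth$proportion < 0.65]
  pure_all <- unlist(fit$pure_samples)
  expect_length(intersect(intermediates, pure_all), 0)
})

test_that("refined centroids recover the programs when pure samples exist", {
  co <- small_cohort(n_samples = 100, n_genes = 400, n_program_genes = 80,
                     noise_sd = 0.5, seed = 55,
                     proportion_sampler = bimodal_props)
  cl <- cluster_on_signature(co$expression, co$program_genes,
                             co$annotations, k = 2)
  fit <- fit_wisp(co$expression, cl)
  mae <- mean(abs(fit$centroids - co$centroids[fit$panel, ]))
  expect_lt(mae, 0.1)
})

test_that("fit is invariant to sample order and symmetric under label swap", {
  co <- small_cohort(n_samples = 50, n_genes = 300, n_program_genes = 60,
                     seed = 31)
  labels <- setNames(ifelse(co$truth$proportion > 0.5, "up", "down"),
                     co$truth$sample_id)
  fit1 <- fit_wisp(co$expression, labels, n_panel = 60)
  set.seed(5)
  perm <- sample(ncol(co$expression))
  fit2 <- fit_wisp(expression_matrix(unclass(co$expression)[, perm]),
                   labels, n_panel = 60)
  w1 <- fit1$weights[order(fit1$weights$sample_id), ]
  w2 <- fit2$weights[order(fit2$weights$sample_id), ]
  expect_equal(w1$w_up, w2$w_up, tolerance = 1e-12)
  # swapping the class names swaps the weights
  swapped <- setNames(ifelse(labels == "up", "down", "up"), names(labels))
  fit3 <- fit_wisp(co$expression, swapped, n_panel = 60)
  w3 <- fit3$weights[order(fit3$weights$sample_id), ]
  expect_equal(w1$w_up, w3$w_down, tolerance = 1e-12)
})

test_that("estimated weight is monotone in the true proportion (noise-free)", {
  co <- small_cohort(n_samples = 40, n_genes = 200, n_program_genes = 60,
                     noise_sd = 0, seed = 41,
                     proportion_sampler = function(n) seq(0, 1, length.out = n))
  labels <- setNames(ifelse(co$truth$proportion > 0.5, "up", "down"),
                     co$truth$sample_id)
  fit <- suppressWarnings(fit_wisp(co$expression, labels, n_panel = 60))
  w <- fit$weights$w_up[match(co$truth$sample_id, fit$weights$sample_id)]
  expect_true(all(diff(w[order(co$truth$proportion)]) >= -1e-12))
})

test_that("classification applies the cutoff with a conservative boundary", {
  w <- tibble::tibble(sample_id = c("a", "b", "c"),
                      w_down = c(0.3, 0.5, 0.8), w_up = c(0.7, 0.5, 0.2))
  expect_warning(cl <- classify_weights(w), "cutoff")
  expect_identical(cl$class, c("miR-200-sign-up", "miR-200-sign-down",
                               "miR-200-sign-down"))
})

test_that("class labels agree with truth away from the boundary", {
  co <- small_cohort(n_samples = 100, seed = 15,
                     proportion_sampler = function(n) {
                       p <- runif(n)
                       ifelse(p > 0.5, 0.6 + 0.4 * (p - 0.5) / 0.5,
                              0.4 * p / 0.5)  # keeps |p - 0.5| > 0.1
                     })
  cl <- cluster_on_signature(co$expression, co$program_genes,
                             co$annotations, k = 2)
  fit <- fit_wisp(co$expression, cl)
  res <- classify_weights(fit$weights)
  agree <- mean(res$class == co$truth$class[
    match(res$sample_id, co$truth$sample_id)])
  expect_gte(agree, 0.95)
})

test_that("quartile bins split by rank with documented remainder placement", {
  w8 <- tibble::tibble(sample_id = sprintf("s%d", 1:8), w_up = (1:8) / 10)
  q8 <- quartile_bins(w8)
  expect_equal(unname(table(q8$quartile)), rep(2L, 4), ignore_attr = TRUE)
  w5 <- tibble::tibble(sample_id = sprintf("s%d", 1:5), w_up = (1:5) / 10)
  q5 <- quartile_bins(w5)
  expect_equal(as.integer(table(q5$quartile)[paste0("Q", 1:4)]),
               c(2L, 1L, 1L, 1L))
})

test_that("quartile bin means increase strictly for random weights", {
  set.seed(61)
  w <- tibble::tibble(sample_id = sprintf("s%04d", 1:1000), w_up = runif(1000))
  q <- quartile_bins(w)
  means <- tapply(q$w_up, q$quartile, mean)[paste0("Q", 1:4)]
  expect_true(all(diff(means) > 0))
})

test_that("scoring refuses when most panel genes are missing", {
  co <- small_cohort(n_samples = 20, n_genes = 100, n_program_genes = 40,
                     seed = 8)
  cent <- co$centroids
  keep <- rownames(co$expression)[1:40]
  small <- co$expression[keep, ]
  expect_error(score_mixture(small, cent), "refusing to score")
  full <- score_mixture(co$expression, cent)
  expect_true(all(c("class", "quartile") %in% names(full)))
})

test_that("tidy and glance summarize a fitted model", {
  co <- small_cohort(n_samples = 30, n_genes = 200, n_program_genes = 60,
                     seed = 2)
  labels <- setNames(ifelse(co$truth$proportion > 0.5, "up", "down"),
                     co$truth$sample_id)
  fit <- fit_wisp(co$expression, labels, n_panel = 40)
  expect_identical(tidy(fit), fit$weights)
  g <- glance(fit)
  expect_equal(g$n_samples, 30)
  expect_true(g$converged)
})
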