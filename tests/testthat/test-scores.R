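test_that("correlation-weighted EMT score matches the hand computation", {
  v <- rbind(A = c(1, 2, 3), B = c(3, 2, 1))
  colnames(v) <- c("s1", "s2", "s3")
  sc <- emt_76gs(expression_matrix(v), c("A", "B"), anchor_gene = "A")
  # w_A = 1, w_B = -1 -> raw = A - B = (-2, 0, 2); already centered
  expect_equal(sc$emt_76gs, c(-2, 0, 2))
  expect_identical(sc$sample_id[which.max(sc$emt_76gs)], "s3")
})

test_that("constant genes get weight zero and offsets cancel", {
  set.seed(5)
  v <- rbind(anchor = rnorm(6), g1 = rnorm(6), flat = rep(2, 6))
  colnames(v) <- paste0("s", 1:6)
  expect_warning(sc <- emt_76gs(expression_matrix(v), c("g1", "flat"),
                                anchor_gene = "anchor"),
                 "zero-variance")
  v2 <- v
  v2["g1", ] <- v["g1", ] + 10
  expect_warning(sc2 <- emt_76gs(expression_matrix(v2), c("g1", "flat"),
                                 anchor_gene = "anchor"), "zero-variance")
  expect_equal(sc$emt_76gs, sc2$emt_76gs, tolerance = 1e-12)

  flat_all <- rbind(anchor = rep(1, 6), g1 = rep(4, 6), g2 = rep(2, 6))
  colnames(flat_all) <- paste0("s", 1:6)
  expect_warning(sc3 <- emt_76gs(expression_matrix(flat_all), c("g1", "g2"),
                                 anchor_gene = "anchor"), "zero variance")
  expect_equal(sc3$emt_76gs, rep(0, 6))
})

test_that("KS score hits the maximal-separation endpoints and null", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(c("e1", "e2", "e3", "m1", "m2", "m3"), "s1"))
  x <- expression_matrix(cbind(v, s2 = v[, 1]))
  sc <- emt_ks(x, c("e1", "e2", "e3"), c("m1", "m2", "m3"))
  expect_equal(sc$emt_ks, c(1, 1))   # mesenchymal genes strictly higher
  # identical multisets -> 0
  v2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1,
               dimnames = list(c("e1", "e2", "e3", "m1", "m2", "m3"), "s1"))
  x2 <- expression_matrix(cbind(v2, s2 = v2[, 1]))
  expect_equal(emt_ks(x2, c("e1", "e2", "e3"), c("m1", "m2", "m3"))$emt_ks,
               c(0, 0))
})

test_that("|KS score| equals the two-sample KS statistic and swap negates it", {
  set.seed(9)
  genes <- c(paste0("e", 1:8), paste0("m", 1:7))
  v <- matrix(rnorm(15 * 10), 15, 10, dimnames = list(genes, paste0("s", 1:10)))
  x <- expression_matrix(v)
  epi <- paste0("e", 1:8)
  mes <- paste0("m", 1:7)
  sc <- emt_ks(x, epi, mes)
  for (j in 1:10) {
    ks <- suppressWarnings(stats::ks.test(v[epi, j], v[mes, j]))$statistic
    expect_equal(abs(sc$emt_ks[j]), unname(ks), tolerance = 1e-12)
  }
  swapped <- emt_ks(x, mes, epi)
  expect_equal(swapped$emt_ks, -sc$emt_ks)
})

test_that("panel EMT score reduces to z-scores and cancels opposites", {
  set.seed(13)
  v <- rbind(mes1 = rnorm(8), twin = 0)
  v["twin", ] <- v["mes1", ]
  colnames(v) <- paste0("s", 1:8)
  x <- expression_matrix(v)
  single <- emt_kgene(x, "mes1", "mesenchymal")
  expect_equal(single$emt_kgene,
               as.numeric(scale(v["mes1", ])), tolerance = 1e-12)
  both <- emt_kgene(x, c("mes1", "twin"), c("mesenchymal", "epithelial"))
  expect_equal(both$emt_kgene, rep(0, 8), tolerance = 1e-12)
})

test_that("panel EMT score matches a brute-force recomputation", {
  set.seed(17)
  v <- matrix(rnorm(7 * 12), 7, 12,
              dimnames = list(paste0("g", 1:7), paste0("s", 1:12)))
  dirs <- rep(c("epithelial", "mesenchymal"), length.out = 7)
  sc <- emt_kgene(expression_matrix(v), rownames(v), dirs)
  brute <- colMeans(do.call(rbind, lapply(seq_len(7), function(i) {
    z <- (v[i, ] - mean(v[i, ])) / sd(v[i, ])
    if (dirs[i] == "epithelial") -z else z
  })))
  expect_equal(sc$emt_kgene, unname(brute), tolerance = 1e-12)
})

test_that("marker scores are per-population means with omission warnings", {
  v <- rbind(g1 = c(2, 4), g2 = c(4, 8), other = c(1, 1))
  colnames(v) <- c("sA", "sB")
  x <- expression_matrix(v)
  sc <- marker_scores(x, list(pop = c("g1", "g2"), solo = "other"))
  expect_equal(sc$pop, c(3, 6))
  expect_equal(sc$solo, c(1, 1))
  expect_warning(sc2 <- marker_scores(x, list(pop = "g1", gone = "zz")),
                 "omitted")
  expect_false("gone" %in% names(sc2))
  expect_error(suppressWarnings(marker_scores(x, list(gone = "zz"))),
               "no population")
})

test_that("planted lymphoid markers anticorrelate with the up proportion", {
  co <- small_cohort(n_samples = 100, seed = 23)
  sc <- marker_scores(co$expression,
                      co$marker_sets[c("lymphoid", "myeloid")])
  p <- co$truth$proportion[match(sc$sample_id, co$truth$sample_id)]
  expect_lt(cor(sc$lymphoid, p, method = "spearman"), -0.5)
  expect_gt(cor(sc$myeloid, p, method = "spearman"), 0.5)
})

test_that("group comparison reports medians and exact rank-sum tails", {
  set.seed(3)
  v <- matrix(rnorm(2 * 10), 2, 10,
              dimnames = list(c("PDL1", "x"), paste0("s", 1:10)))
  v["PDL1", 6:10] <- v["PDL1", 6:10] + 100   # disjoint ranges
  groups <- setNames(rep(c("down", "up"), each = 5), colnames(v))
  res <- compare_gene_across_groups(expression_matrix(v), "PDL1", groups)
  expect_equal(nrow(res), 2)
  expect_equal(res$p_value[1], 2 / choose(10, 5), tolerance = 1e-12)
  # identical groups: p = 1 within test resolution
  v["PDL1", ] <- rep(c(1, 2, 3, 4, 5), 2)
  g2 <- setNames(rep(c("a", "b"), 5), colnames(v))
  res2 <- suppressWarnings(
    compare_gene_across_groups(expression_matrix(v), "PDL1", g2))
  expect_gte(res2$p_value[1], 0.99)
})

test_that("three or more groups switch to Kruskal-Wallis", {
  set.seed(7)
  v <- matrix(rnorm(2 * 12), 2, 12,
              dimnames = list(c("g", "h"), paste0("s", 1:12)))
  groups <- setNames(rep(c("a", "b", "c"), each = 4), colnames(v))
  res <- compare_gene_across_groups(expression_matrix(v), "g", groups)
  expect_identical(unique(res$method), "kruskal-wallis")
  expect_equal(nrow(res), 3)
})
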