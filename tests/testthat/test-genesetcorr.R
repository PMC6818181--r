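test_that("overlap tail equals closed-form small cases", {
  expect_equal(hypergeom_tail(10, 3, 3, 3), 1 / 120, tolerance = 1e-14)
  expect_equal(hypergeom_tail(10, 3, 3, 1), 1 - 35 / 120, tolerance = 1e-14)
  expect_equal(hypergeom_tail(10, 3, 3, 0), 1)
  expect_equal(hypergeom_tail(20, 5, 4, 2),
               1 - (choose(5, 0) * choose(15, 4) + choose(5, 1) * choose(15, 3)) /
                 choose(20, 4), tolerance = 1e-14)
  expect_error(hypergeom_tail(10, 11, 3, 1), class = "warburgph_validation_error")
  expect_error(hypergeom_tail(10, 3, 3, 4), class = "warburgph_validation_error")
})

test_that("overlap tail is monotone non-increasing in m and matches phyper", {
  for (N in c(8, 15, 40)) for (M in c(3, 7)) for (n in c(2, 5)) {
    ms <- 0:min(n, M)
    p <- vapply(ms, function(m) hypergeom_tail(N, M, n, m), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
    # independent route: base R's hypergeometric upper tail
    expect_equal(p, phyper(ms - 1, M, N - M, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("a gene built from PC1 is fitted exactly by PC regression", {
  set.seed(50)
  X <- matrix(rnorm(15 * 20), 20, 15)  # samples x genes
  vals <- t(X)
  rownames(vals) <- paste0("m", 1:15)
  pc <- prcomp(X)
  g <- 2 + 3 * pc$x[, 1]
  vals <- rbind(vals, target = g)
  colnames(vals) <- paste0("s", 1:20)
  em <- make_em(vals)
  rep <- gene_vs_set_correlation("target", gene_set("S", paste0("m", 1:15)), em,
                                 variance_gate = 0.1)
  expect_identical(rep$method, "pc_regression")
  expect_equal(rep$r_squared, 1, tolerance = 1e-10)
})

test_that("perfectly collinear sets take the regression branch with full variance", {
  base <- rnorm(20, 5)
  vals <- rbind(a = base, b = 2 * base - 1, c = -base + 4, target = rnorm(20, 5))
  colnames(vals) <- paste0("s", 1:20)
  em <- make_em(vals)
  rep <- gene_vs_set_correlation("target", gene_set("S", c("a", "b", "c")), em)
  expect_identical(rep$method, "pc_regression")
  expect_equal(rep$variance_explained, 1, tolerance = 1e-12)
})

test_that("self-correlation and a failed variance gate are handled", {
  set.seed(51)
  vals <- matrix(rnorm(20 * 30, 5), 20, 30,
                 dimnames = list(paste0("m", 1:20), paste0("s", 1:30)))
  em <- make_em(vals)
  expect_error(gene_vs_set_correlation("m1", gene_set("S", paste0("m", 1:5)), em),
               class = "warburgph_validation_error")
  # isotropic noise on 19 genes: PC1+PC2 cannot reach 75% -> fallback
  rep <- gene_vs_set_correlation("m1", gene_set("S", paste0("m", 2:20)), em)
  expect_identical(rep$method, "overlap_test")
  expect_true(rep$P >= 0 && rep$P <= 1)
})

test_that("overlap test recovers a planted correlated block", {
  a <- paste0("a", 1:6); b <- paste0("b", 1:6)
  spec <- simulation_spec(n_genes = 120, n_case = 100, n_control = 100, seed = 52,
                          latent_links = list(list(set_a = a, set_b = b, rho = 0.8)))
  em <- simulate_dataset(spec)$matrix
  rep <- overlap_test("a1", gene_set("B", b), em)
  expect_gte(rep$m, 5)          # nearly all of b is selected as correlated
  expect_lt(rep$P, 1e-4)
  # a gene with no planted structure: degenerate or insignificant
  rep0 <- overlap_test("gene_0050", gene_set("B", b), em)
  expect_gte(rep0$P, 0.01)
})

test_that("pc-regression R^2 is invariant to a consistent sample permutation", {
  set.seed(53)
  spec <- simulation_spec(n_genes = 30, n_case = 25, n_control = 25, seed = 53,
                          latent_links = list(list(set_a = paste0("a", 1:5),
                                                   set_b = "tgt", rho = 0.7)))
  em <- simulate_dataset(spec)$matrix
  perm <- sample(ncol(em$values))
  em2 <- expression_matrix(em$values[, perm], em$groups[perm])
  s <- gene_set("A", paste0("a", 1:5))
  r1 <- gene_vs_set_correlation("tgt", s, em, variance_gate = 0.1)
  r2 <- gene_vs_set_correlation("tgt", s, em2, variance_gate = 0.1)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-10)
})

test_that("principal curve on exact-line data recovers the coordinate", {
  set.seed(54)
  t_true <- sort(runif(60, -2, 2))
  direction <- c(1, 2, -1) / sqrt(6)
  X <- outer(t_true, direction) + 5
  fit <- fit_principal_curve(X)
  expect_gt(abs(cor(fit$lambda, t_true)), 0.999)
  expect_lt(mean(sqrt(rowSums((fit$points - X)^2))), 0.05)
})

test_that("identical gene sets give PCC = 1, antithetic give -1", {
  set.seed(55)
  base <- matrix(rnorm(5 * 40, 6), 5, 40,
                 dimnames = list(paste0("a", 1:5), paste0("s", 1:40)))
  anti <- -(base - rowMeans(base))
  rownames(anti) <- paste0("b", 1:5)
  # duplicate rows under new ids for the identical-set comparison
  vals <- rbind(base, anti,
                matrix(base, 5, 40, dimnames = list(paste0("c", 1:5), colnames(base))))
  em <- make_em(vals)
  same <- set_vs_set_correlation(gene_set("A", paste0("a", 1:5)),
                                 gene_set("C", paste0("c", 1:5)), em)
  expect_equal(same$pcc, 1, tolerance = 1e-8)
  opp <- set_vs_set_correlation(gene_set("A", paste0("a", 1:5)),
                                gene_set("B", paste0("b", 1:5)), em)
  expect_equal(opp$pcc, -1, tolerance = 1e-6)
})

test_that("set-vs-set validates degenerate inputs", {
  vals <- matrix(5, 4, 12, dimnames = list(paste0("a", 1:4), paste0("s", 1:12)))
  em <- make_em(vals)
  expect_error(set_vs_set_correlation(gene_set("A", c("a1", "a2")),
                                      gene_set("B", c("a3", "a4")), em),
               class = "warburgph_validation_error")
  expect_error(set_vs_set_correlation(gene_set("A", c("a1", "a2")),
                                      gene_set("B", c("a1", "a2")), em),
               class = "warburgph_validation_error")
})

test_that("enrichment ranks a contained query first and handles disjoint sets", {
  lib <- list(gene_set("hit", paste0("x", 1:5)),
              gene_set("partial", c("x1", "x2", "y1", "y2", "y3")),
              gene_set("miss", paste0("z", 1:5)))
  query <- gene_set("q", paste0("x", 1:5))
  tab <- enrich_genesets(query, lib, N = 100)
  expect_identical(tab$set[1], "hit")
  expect_identical(tab$P[tab$set == "miss"], 1)
  expect_true(all(diff(tab$P) >= 0))
  expect_equal(tab$q, p.adjust(tab$P, "BH")[order(tab$P)], tolerance = 1e-12)
})
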