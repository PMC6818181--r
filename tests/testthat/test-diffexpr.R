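test_that("null data give zero fold change and no calls", {
  set.seed(20)
  half <- matrix(rnorm(60, 5), 6, 10)
  em <- make_em(cbind(half, half))
  de <- differential_expression(em)
  expect_equal(de$log2FC, rep(0, 6))
  expect_true(all(de$deg_call == "unchanged"))
  expect_equal(de$FC, 2^de$log2FC)
})

test_that("a 2-unit log2 shift at n=20/20 is called up with FC 4", {
  # within-gene spread < 2 so the shifted groups separate completely: the
  # exact rank-sum p is then its floor, 2/choose(40, 20) < 1e-6
  ctrl <- t(sapply(1:5, function(i) seq(5, 5.9, length.out = 20) + i / 100))
  em <- make_em(cbind(ctrl + 2, ctrl))
  de <- differential_expression(em)
  expect_equal(de$FC, rep(4, 5))
  expect_equal(de$p_value, rep(2 / choose(40, 20), 5), tolerance = 1e-12)
  expect_true(all(de$p_value < 1e-6))
  expect_true(all(de$deg_call == "up"))
})

test_that("rank-sum p matches the textbook extreme-split value", {
  em <- make_em(matrix(c(1:5, 6:10), 1, 10))
  de <- differential_expression(em)
  expect_equal(de$p_value, 2 / choose(10, 5))
  expect_identical(de$deg_call, "down")  # case ranks all below control
})

test_that("swapping group labels negates log2FC and swaps calls, p invariant", {
  set.seed(22)
  spec <- simulation_spec(n_genes = 60, n_case = 15, n_control = 15, seed = 22,
                          planted_fc = c(up1 = 4, dn1 = 0.25))
  em <- simulate_dataset(spec)$matrix
  em_sw <- expression_matrix(em$values,
                             ifelse(em$groups == "case", "control", "case"))
  de <- differential_expression(em)
  de_sw <- differential_expression(em_sw)
  expect_equal(de_sw$log2FC, -de$log2FC)
  expect_equal(de_sw$p_value, de$p_value)
  expect_true(all(de_sw$deg_call[de$deg_call == "up"] == "down"))
  expect_true(all(de_sw$deg_call[de$deg_call == "down"] == "up"))
  expect_true(all(de_sw$heatmap_call[de$heatmap_call == "up"] == "down"))
})

test_that("BH q-values dominate p-values and gate the calls", {
  set.seed(23)
  spec <- simulation_spec(n_genes = 200, n_case = 10, n_control = 10, seed = 23,
                          planted_fc = c(up1 = 8))
  em <- simulate_dataset(spec)$matrix
  de <- differential_expression(em)
  expect_true(all(de$q_value >= de$p_value - 1e-15))
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
  up <- de$deg_call == "up"
  expect_true(all(de$FC[up] > 1.3 & de$q_value[up] < 0.01))
})

test_that("not-expressed genes are excluded from testing", {
  set.seed(24)
  m <- rbind(matrix(rnorm(40, 6), 2, 20), matrix(rnorm(20, 0, 0.1), 1, 20))
  em <- make_em(m)
  fl <- mark_expressed(em, 3)
  de <- differential_expression(em, expressed = fl)
  expect_true(is.na(de$p_value[3]) && is.na(de$q_value[3]))
  expect_identical(de$heatmap_call[3], "not_expressed")
  expect_false(any(is.na(de$p_value[1:2])))
})

test_that("paired design uses the signed-rank test", {
  set.seed(25)
  ctrl <- matrix(rnorm(30, 5), 3, 10)
  em <- make_em(cbind(ctrl + 1, ctrl), paired = TRUE)
  de <- differential_expression(em)
  # oracle: signed-rank on constant positive differences is the extreme case
  expect_equal(de$p_value,
               rep(suppressWarnings(wilcox.test(rep(1, 10))$p.value), 3))
  expect_error(
    differential_expression(
      make_em(matrix(rnorm(30), 3, 10),
              groups = c(rep("case", 4), rep("control", 6)), paired = TRUE)),
    class = "warburgph_validation_error")
})

test_that("heat-map categories break exactly at |log2FC| = 0.6", {
  n <- 6
  ctrl <- matrix(5, 4, n)
  case <- rbind(5 + 0.7, 5 + 0.0, 5 - 0.61, 5 + 0.6)[, rep(1, n), drop = FALSE] +
    matrix(0, 4, n)
  em <- make_em(cbind(case, ctrl))
  de <- differential_expression(em)
  expect_identical(de$heatmap_call, c("up", "unchanged", "down", "unchanged"))
})

test_that("panel categorization records absent genes as missing", {
  panel <- load_default_panel()
  set.seed(26)
  m <- matrix(rnorm(40, 5), 2, 20,
              dimnames = list(c("SLC4A2", "SLC16A1"), paste0("s", 1:20)))
  em <- make_em(m)
  calls <- categorize_for_heatmap(differential_expression(em), panel)
  expect_identical(nrow(calls), sum(panel$included))
  expect_identical(calls$call[calls$symbol == "SLC9A2"], "missing")
  expect_false(calls$call[calls$symbol == "SLC4A2"] == "missing")
})
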