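# a spec whose matrix carries the Fenton marker genes, optionally linked
fenton_spec <- function(seed, rho, n = 100) {
  substrate <- c("TXN", "TXN2", "GCLC", "GCLM", "TFRC", "TFR2")
  links <- if (rho != 0)
    list(list(set_a = psm_genes(), set_b = substrate, rho = rho)) else list()
  planted <- if (rho == 0)
    setNames(rep(1, length(psm_genes()) + length(substrate)),
             c(psm_genes(), substrate)) else numeric()
  simulation_spec(n_genes = 60, n_case = n / 2, n_control = n / 2, seed = seed,
                  planted_fc = planted, latent_links = links)
}

test_that("a planted product-substrate link is detected", {
  em <- simulate_dataset(fenton_spec(60, rho = 0.8))$matrix
  v <- assess_fenton(em)
  expect_true(v$predicted)
  expect_gt(v$r, 0.5)
  expect_false(v$superoxide_included)
})

test_that("identical proxy submatrices give r = 1", {
  set.seed(61)
  sub <- matrix(rnorm(4 * 30, 6), 4, 30)
  vals <- rbind(sub, sub)
  rownames(vals) <- c("TXN", "TXN2", "GCLC", "GCLM", paste0("oh", 1:4))
  colnames(vals) <- paste0("s", 1:30)
  em <- make_em(vals)
  cfg <- fenton_marker_config(
    oh_proxy = gene_set("oh", paste0("oh", 1:4)),
    h2o2_proxy = gene_set("h2o2", c("TXN", "TXN2")),
    iron_proxy = gene_set("iron", c("GCLC", "GCLM")))
  v <- assess_fenton(em, cfg)
  expect_equal(v$r, 1, tolerance = 1e-10)
  expect_true(v$predicted)
})

test_that("scores are invariant to sample order and per-gene rescaling", {
  em <- simulate_dataset(fenton_spec(62, rho = 0.8))$matrix
  v <- assess_fenton(em)
  perm <- sample(ncol(em$values))
  em_perm <- expression_matrix(em$values[, perm], em$groups[perm])
  v_perm <- assess_fenton(em_perm)
  expect_equal(abs(v$r), abs(v_perm$r), tolerance = 1e-10)
  # doubling one gene's scale: standardization makes it irrelevant
  em_scaled <- em
  em_scaled$values["PSMA1", ] <- 2 * em_scaled$values["PSMA1", ]
  expect_equal(assess_fenton(em_scaled)$r, v$r, tolerance = 1e-10)
})

test_that("superoxide proxy is optional but must be disjoint when supplied", {
  em <- simulate_dataset(fenton_spec(63, rho = 0.8))$matrix
  expect_error(
    fenton_marker_config(superoxide_proxy = gene_set("sox", c("TFRC", "NOX1"))),
    class = "warburgph_validation_error")
  cfg <- fenton_marker_config(superoxide_proxy = gene_set("sox", "gene_0001"))
  v <- assess_fenton(em, cfg)
  expect_true(v$superoxide_included)
})

test_that("transporter coupling recovers planted loader-proteasome links", {
  loaders <- c("SLC4A1AP", "SLC4A2", "SLC4A3", "SLC26A6", "ATP6V0B", "ATP6V0C")
  spec <- simulation_spec(
    n_genes = 80, n_case = 50, n_control = 50, seed = 64,
    latent_links = list(list(set_a = psm_genes(), set_b = loaders, rho = 0.8)),
    planted_fc = setNames(rep(1, 6), c("TXN", "TXN2", "GCLC", "GCLM", "TFRC", "TFR2")))
  em <- simulate_dataset(spec)$matrix
  panel <- load_default_panel()
  tab <- suppressMessages(fenton_transporter_coupling(em, panel))
  lr <- tab$r[tab$role == "acid_loader"]
  expect_true(all(lr > 0))
  expect_gt(median(lr), 0.5)
})

test_that("a panel gene inside a proxy set is rejected", {
  em <- simulate_dataset(fenton_spec(65, rho = 0))$matrix
  panel <- load_default_panel()
  cfg <- fenton_marker_config(h2o2_proxy = gene_set("h2o2", c("TXN", "SLC4A2")))
  expect_error(fenton_transporter_coupling(em, panel, cfg),
               class = "warburgph_validation_error")
})
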