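test_that("simulation is bit-reproducible under a fixed seed", {
  spec <- simulation_spec(n_genes = 200, n_case = 10, n_control = 10, seed = 11,
                          planted_fc = c(LDHA = 4),
                          latent_links = list(list(set_a = c("a1", "a2"),
                                                   set_b = c("b1", "b2"),
                                                   rho = 0.5)))
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$matrix$values, s2$matrix$values)
})

test_that("planted fold changes are recovered empirically", {
  spec <- simulation_spec(n_genes = 200, n_case = 50, n_control = 50, seed = 1,
                          planted_fc = c(LDHA = 4.0))
  em <- simulate_dataset(spec)$matrix
  fc <- 2^(mean(em$values["LDHA", em$groups == "case"]) -
           mean(em$values["LDHA", em$groups == "control"]))
  expect_gte(fc, 3.2)
  expect_lte(fc, 5.0)
})

test_that("without latent links genes are uncorrelated on average", {
  spec <- simulation_spec(n_genes = 50, n_case = 100, n_control = 100, seed = 2)
  em <- simulate_dataset(spec)$matrix
  cm <- cor(t(em$values))
  off <- abs(cm[upper.tri(cm)])
  expect_lt(mean(off), 0.1)
})

test_that("latent links plant the requested cross-set correlation", {
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  spec <- simulation_spec(n_genes = 20, n_case = 200, n_control = 200, seed = 3,
                          latent_links = list(list(set_a = a, set_b = b, rho = 0.8)))
  em <- simulate_dataset(spec)$matrix
  cross <- cor(t(em$values[a, ]), t(em$values[b, ]))
  expect_equal(mean(cross), 0.8, tolerance = 0.05)
  # negative rho flips the sign
  spec2 <- simulation_spec(n_genes = 20, n_case = 200, n_control = 200, seed = 3,
                           latent_links = list(list(set_a = a, set_b = b, rho = -0.6)))
  em2 <- simulate_dataset(spec2)$matrix
  expect_equal(mean(cor(t(em2$values[a, ]), t(em2$values[b, ]))), -0.6,
               tolerance = 0.05)
})

test_that("marginal log2 values form a two-mode mixture", {
  spec <- simulation_spec(n_genes = 2000, n_case = 20, n_control = 20, seed = 4)
  em <- simulate_dataset(spec)$matrix
  thr <- find_expression_threshold(em)
  expect_gt(thr$threshold, spec$mode_low[[1]])
  expect_lt(thr$threshold, spec$mode_high[[1]])
})

test_that("contradictory or malformed specs are rejected", {
  expect_error(simulation_spec(mode_low = c(5, 1), mode_high = c(0, 1)),
               class = "warburgph_validation_error")
  expect_error(simulation_spec(planted_fc = c(LDHA = -1)),
               class = "warburgph_validation_error")
  expect_error(
    simulation_spec(latent_links = list(
      list(set_a = "x", set_b = "y", rho = 0.5),
      list(set_a = "x", set_b = "z", rho = -0.5))),
    class = "warburgph_validation_error")
  expect_error(
    simulation_spec(latent_links = list(list(set_a = "x", set_b = "x", rho = 1))),
    class = "warburgph_validation_error")
})

test_that("noiseless time-course trends are monotone per segment", {
  spec <- simulation_spec(seed = 5, timecourse = list(
    trends = c(up = "rising", down = "falling", bump = "peak_then_decline"),
    noise_sd = 0))
  tc <- simulate_timecourse(spec)
  expect_identical(dim(tc), c(3L, 19L))
  sm <- segment_means(tc)
  expect_true(all(diff(sm["up", ]) > 0))
  expect_true(all(diff(sm["down", ]) < 0))
  peak <- which.max(sm["bump", ])
  expect_true(peak > 1 && peak < ncol(sm))
  # reproducible under the seed even with noise
  spec2 <- simulation_spec(seed = 5, timecourse = list(trends = c(g = "rising")))
  expect_identical(simulate_timecourse(spec2), simulate_timecourse(spec2))
  expect_error(simulation_spec(timecourse = list(n_timepoints = 5,
                                                 trends = c(g = "rising"))),
               class = "warburgph_validation_error")
})
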