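point_specs <- function(conc) {
  lapply(conc, function(v) dist_spec("point", value = v))
}

test_that("draw summaries use the linear-interpolation percentile convention", {
  s <- summarize_draws(1:100)
  expect_equal(s$p95, 95.05)
  expect_equal(s$p5, 5.95)
  expect_equal(s$mean, 50.5)
  expect_identical(s$quantile_type, 7L)
  s2 <- summarize_draws(rep(3.2, 50))
  expect_equal(unlist(s2[c("mean", "median", "p5", "p90", "p95")]),
               rep(3.2, 5), ignore_attr = TRUE)
  expect_equal(s2$sd, 0)
  expect_equal(summarize_draws(c(0, 10))$median, 5)
})

test_that("exceedance probability is the strict empirical tail fraction", {
  set.seed(4)
  u <- runif(20000, 0, 2)
  expect_equal(exceedance_probability(u, 1), 0.5, tolerance = 0.02)
  expect_equal(exceedance_probability(u, -1), 1)
  expect_equal(exceedance_probability(u, 3), 0)
  expect_equal(exceedance_probability(c(1, 2), 2), 0)  # strict
})

test_that("all-point specs reproduce the deterministic risk exactly", {
  conc <- c(Cr = 3.250, Ni = 0.684, As = 0.055, Cd = 0.149, Pb = 0.039, F = 4.539)
  sim <- run_simulation(conc_specs = point_specs(conc), n_iterations = 50, seed = 1)
  kid <- children()
  for (el in names(conc)) {
    tx <- tox_row(el)
    if (!is.na(tx$rfd)) {
      expect_identical(unique(sim$draws$children$HQ[, el]),
                       hazard_quotient(conc[[el]], kid, tx))
    }
    if (tx$carcinogenic) {
      expect_identical(unique(sim$draws$children$CR[, el]),
                       carcinogenic_risk(conc[[el]], kid, tx))
    }
  }
  expect_equal(sd(sim$draws$children$HI), 0)
  expect_identical(unique(sim$draws$children$TCR),
                   sum(vapply(c("Cr", "As", "Cd", "Pb"),
                              function(el) carcinogenic_risk(conc[[el]], kid, tox_row(el)), 1)))
})

test_that("a single iteration summarizes to the single draw", {
  sim <- run_simulation(conc_specs = point_specs(c(As = 0.055)),
                        n_iterations = 1, seed = 5)
  s <- sim$summary
  expect_equal(s$mean, s$median)
  expect_equal(s$mean, s$p95)
  expect_equal(s$sd, rep(0, nrow(s)))
})

test_that("identical seeds give bit-identical simulations", {
  tab <- suppressWarnings(generate_concentrations(seed = 3))
  s1 <- run_simulation(tab, n_iterations = 500, seed = 77)
  s2 <- run_simulation(tab, n_iterations = 500, seed = 77)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$summary, s2$summary)
  s3 <- run_simulation(tab, n_iterations = 500, seed = 78)
  expect_false(identical(s1$draws$children$HI, s3$draws$children$HI))
})

test_that("per-variable substreams isolate elements from one another", {
  specs <- list(As = dist_spec("lognormal", meanlog = -2.9, sdlog = 0.2),
                Cd = dist_spec("lognormal", meanlog = -2.1, sdlog = 0.66))
  s1 <- run_simulation(conc_specs = specs["As"], n_iterations = 300, seed = 9)
  s2 <- run_simulation(conc_specs = specs, n_iterations = 300, seed = 9)
  expect_identical(s1$inputs$C[, "As"], s2$inputs$C[, "As"])
})

test_that("HI and TCR are within-draw sums of the element endpoints", {
  tab <- suppressWarnings(generate_concentrations(seed = 3))
  sim <- run_simulation(tab, n_iterations = 400, seed = 21,
                        exposure = "probabilistic")
  for (g in names(sim$draws)) {
    expect_equal(sim$draws[[g]]$HI, rowSums(sim$draws[[g]]$HQ))
    expect_equal(sim$draws[[g]]$TCR, rowSums(sim$draws[[g]]$CR))
    expect_true(all(sim$draws[[g]]$HI >= 0))
  }
})

test_that("Monte Carlo means converge to the analytic fitted means", {
  spec <- dist_spec("lognormal", meanlog = -2.92, sdlog = 0.198)
  sim <- run_simulation(conc_specs = list(As = spec), n_iterations = 10000, seed = 31)
  kid <- children()
  k <- kid$ef * kid$ir / (kid$bw * 365 * tox_row("As")$rfd)
  hq <- sim$draws$children$HQ[, "As"]
  mcse <- sd(hq) / sqrt(length(hq))
  expect_lt(abs(mean(hq) - dist_mean(spec) * k), 3 * mcse)
})

test_that("joint concentration sampling preserves the rank dependence", {
  tab <- suppressWarnings(generate_concentrations(seed = 6))
  sim <- run_simulation(tab, n_iterations = 4000, seed = 13, conc_sampling = "joint")
  rho_data <- spearman_matrix(tab)$rho["Cr", "Pb"]
  rho_sim <- cor(sim$inputs$C[, "Cr"], sim$inputs$C[, "Pb"], method = "spearman")
  expect_lt(abs(rho_sim - rho_data), 0.08)
  sim_ind <- run_simulation(tab, n_iterations = 4000, seed = 13)
  rho_ind <- cor(sim_ind$inputs$C[, "Cr"], sim_ind$inputs$C[, "Pb"], method = "spearman")
  expect_lt(abs(rho_ind), 0.06)
})

test_that("simulation refuses to run without a seed or fittable elements", {
  tab <- suppressWarnings(generate_concentrations(seed = 3))
  expect_error(run_simulation(tab, n_iterations = 10), "seed")
  expect_error(run_simulation(conc_specs = list(), n_iterations = 10, seed = 1))
})
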