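test_that("a lone driving input takes the whole contribution", {
  set.seed(1)
  x <- rlnorm(500)
  rep <- suppressWarnings(contribution_to_variance(
    list(x = x, k1 = rep(2, 500), k2 = rep(7, 500)), output = 3 * x))
  expect_equal(rep$contribution[rep$variable == "x"], 100)
  expect_equal(rep$contribution[rep$variable == "k1"], 0)
  expect_equal(sum(abs(rep$contribution)), 100)
})

test_that("a symmetric ratio model splits contributions +50 / -50", {
  set.seed(2)
  n <- 10000
  x <- rlnorm(n, 0, 0.4); y <- rlnorm(n, 0, 0.4)
  rep <- contribution_to_variance(list(X = x, Y = y), output = x / y)
  cx <- rep$contribution[rep$variable == "X"]
  cy <- rep$contribution[rep$variable == "Y"]
  expect_equal(cx, 50, tolerance = 0.06)
  expect_equal(cy, -50, tolerance = 0.06)
  expect_equal(abs(cx) + abs(cy), 100)
})

test_that("contributions are invariant under monotone transforms of inputs", {
  set.seed(3)
  n <- 2000
  x <- rlnorm(n); y <- rlnorm(n)
  out <- x * 2 + y
  r1 <- contribution_to_variance(list(a = x, b = y), out)
  r2 <- contribution_to_variance(list(a = log(x), b = y^3), out)
  expect_equal(r1$contribution, r2$contribution)
})

test_that("signs follow the analytic direction of the risk model", {
  set.seed(4)
  n <- 10000
  conc <- rlnorm(n, 0, 0.5)
  bw <- rnorm(n, 60, 9)
  out <- conc * 0.16 * 365 / (bw * 365 * 0.001)  # HQ = C k / BW
  rep <- contribution_to_variance(list(C = conc, BW = bw), out)
  expect_gt(rep$contribution[rep$variable == "C"], 0)
  expect_lt(rep$contribution[rep$variable == "BW"], 0)
})

test_that("degenerate inputs and outputs are handled explicitly", {
  x <- rlnorm(200)
  expect_warning(rep <- contribution_to_variance(
    list(x = x, k = rep(1, 200)), output = x), "constant")
  expect_equal(rep$contribution[rep$variable == "k"], 0)
  expect_error(contribution_to_variance(list(x = x), output = rep(1, 200)),
               "constant")
  expect_error(contribution_to_variance(list(x = x[1:100]), output = x[1:150]),
               "length")
  expect_error(contribution_to_variance(list(x = x[1:50]), output = x[1:50]),
               "100")
})

test_that("pooling concentrations sums squared rank correlations first", {
  rep <- structure(data.frame(
    variable = c("C_a", "C_b", "IR"),
    rho = c(sqrt(0.2), sqrt(0.3), sqrt(0.5)),
    contribution = NA_real_), class = c("sensitivity_report", "data.frame"))
  pooled <- aggregate_concentration_sensitivity(rep)
  expect_equal(pooled$contribution[pooled$variable == "C"], 50)
  expect_equal(pooled$contribution[pooled$variable == "IR"], 50)
  # single concentration variable: pooling is the identity
  one <- structure(data.frame(variable = c("C_a", "BW"),
                              rho = c(0.6, -0.8), contribution = NA_real_),
                   class = c("sensitivity_report", "data.frame"))
  p1 <- aggregate_concentration_sensitivity(one)
  expect_equal(p1$contribution, c(100 * 0.36, -100 * 0.64), tolerance = 1e-12)
  # only BW correlated: it takes the full (negative) share
  bw <- structure(data.frame(variable = c("C_a", "BW"),
                             rho = c(0, -0.5), contribution = NA_real_),
                  class = c("sensitivity_report", "data.frame"))
  expect_equal(aggregate_concentration_sensitivity(bw)$contribution, c(0, -100))
})

test_that("full probabilistic run ranks concentration first with negative BW", {
  tab <- suppressWarnings(generate_concentrations(seed = 2))
  sim <- run_simulation(tab, n_iterations = 3000, seed = 17,
                        exposure = "probabilistic", conc_sampling = "joint")
  for (ep in c("HI", "TCR")) {
    rep <- sensitivity_report(sim, "children", ep)
    expect_identical(rep$variable[which.max(abs(rep$contribution))], "C")
    expect_lt(rep$contribution[rep$variable == "BW"], 0)
    expect_equal(sum(abs(rep$contribution)), 100, tolerance = 1e-6)
  }
})

test_that("point-exposure runs give the exposure parameters zero contribution", {
  tab <- suppressWarnings(generate_concentrations(seed = 2))
  sim <- run_simulation(tab, n_iterations = 500, seed = 19, exposure = "point")
  rep <- suppressWarnings(sensitivity_report(sim, "children", "HI"))
  expect_equal(rep$contribution[rep$variable %in% c("BW", "IR", "ED")],
               rep(0, 3))
})
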