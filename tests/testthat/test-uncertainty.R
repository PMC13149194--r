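# Fast analytic model closure for sensitivity-analysis tests: traces are
# fixed; only the economics re-evaluates per draw (survival parameters are
# outside the PSA scope).
psa_fixture <- local({
  h <- model_horizon()
  mk <- function(scale_pfs, scale_os) {
    run_markov(build_schedule(
      function(t) pweibull(t, 1.3, scale_pfs, lower.tail = FALSE),
      function(t) pweibull(t, 1.3, scale_os, lower.tail = FALSE), h), h)
  }
  tr_exp <- mk(7, 15)
  tr_ctrl <- mk(3.5, 10)
  list(model_fn = function(ip) run_cea(tr_exp, tr_ctrl, ip))
})

test_that("one-way DSA orders tornado entries and flags ignored parameters", {
  inp <- make_reference_config()
  dsa <- one_way_dsa(inp, psa_fixture$model_fn)
  expect_setequal(dsa$name, param_ranges(inp)$name)
  expect_true(all(diff(dsa$width) <= 1e-9))
  expect_false(any(dsa$failed))
  # a parameter with a degenerate range produces a zero-width bar
  zero <- dsa[dsa$name == "ae_risk_rash_control", ]
  expect_equal(zero$width, 0)
  # each bar equals the difference of two direct re-evaluations
  i <- which(dsa$name == "u_pfs")
  lo <- psa_fixture$model_fn(set_param(inp, "u_pfs", dsa$low[i]))$icer
  hi <- psa_fixture$model_fn(set_param(inp, "u_pfs", dsa$high[i]))$icer
  expect_equal(dsa$width[i], abs(hi - lo))
})

test_that("DSA of a linear toy model has the closed-form bar width", {
  inp <- make_reference_config()
  a <- 10000; b <- 40000; dE <- 0.27
  mf <- function(ip) cea_compare(c(a + b * ip$price_factor, 0.93),
                                 c(14000, 0.66))
  ranges <- data.frame(name = "price_factor", base = 1, low = 0.5, high = 1,
                       dist = "beta")
  dsa <- one_way_dsa(inp, mf, ranges)
  expect_equal(dsa$width, b * (1 - 0.5) / dE)
})

test_that("moment-matched sampling reproduces means within tolerance", {
  ranges <- data.frame(
    name = c("drug_cost_experimental", "u_pfs"),
    base = c(3635.34, 0.85),
    low = c(2726.51, 0.64),
    high = c(4544.18, 1),
    dist = c("gamma", "beta"))
  draws <- sample_parameters(ranges, 10000, seed = 5L)
  expect_lt(abs(mean(draws[, 1]) - 3635.34) / 3635.34, 0.02)
  expect_lt(abs(mean(draws[, 2]) - 0.85), 0.01)
  expect_true(all(draws[, 2] > 0 & draws[, 2] < 1))
  # the gamma moments themselves
  sd_target <- (4544.18 - 2726.51) / 3.92
  expect_lt(abs(sd(draws[, 1]) - sd_target) / sd_target, 0.05)

  # degenerate range -> all draws at base
  degen <- data.frame(name = "x", base = 10, low = 10, high = 10,
                      dist = "gamma")
  expect_true(all(sample_parameters(degen, 50, seed = 1L) == 10))

  # infeasible beta moments are clamped with a record
  wide <- data.frame(name = "p", base = 0.5, low = -3, high = 4,
                     dist = "beta")
  d <- sample_parameters(wide, 100, seed = 1L)
  expect_identical(attr(d, "clamped"), "p")
  expect_true(all(d > 0 & d < 1))
})

test_that("PSA is reproducible and degenerate ranges return the base case", {
  inp <- make_reference_config()
  p1 <- run_psa(inp, psa_fixture$model_fn, n = 25, seed = 7L)
  p2 <- run_psa(inp, psa_fixture$model_fn, n = 25, seed = 7L)
  expect_identical(p1, p2)

  base <- psa_fixture$model_fn(inp)
  rng0 <- param_ranges(inp)
  rng0$low <- rng0$base
  rng0$high <- rng0$base
  p0 <- run_psa(inp, psa_fixture$model_fn, n = 1, seed = 1L, ranges = rng0)
  expect_equal(p0$delta_cost, base$delta_cost)
  expect_equal(p0$delta_qaly, base$delta_qaly)
})

test_that("a costlier-and-more-effective arm keeps all samples north-east", {
  inp <- make_reference_config()
  psa <- run_psa(inp, psa_fixture$model_fn, n = 200, seed = 11L)
  expect_false(any(psa$failed))
  expect_true(all(psa$delta_cost > 0))
  expect_true(all(psa$delta_qaly > 0))
})

test_that("the acceptability curve follows the net-monetary-benefit rule", {
  samples <- data.frame(delta_cost = c(100, 200, 300),
                        delta_qaly = c(0.1, 0.2, 0.3), failed = FALSE)
  expect_equal(ceac(samples, 0)$prob_cost_effective, 0)      # all dC > 0
  expect_equal(ceac(samples, 1e9)$prob_cost_effective, 1)    # all dE > 0
  grid <- seq(0, 5000, by = 100)
  cv <- ceac(samples, grid)
  expect_true(all(diff(cv$prob_cost_effective) >= 0))

  # degenerate samples: step function jumping at the ICER, ties not CE
  one <- data.frame(delta_cost = 250, delta_qaly = 0.25, failed = FALSE)
  icer <- 1000
  expect_equal(ceac(one, icer - 1)$prob_cost_effective, 0)
  expect_equal(ceac(one, icer)$prob_cost_effective, 0)
  expect_equal(ceac(one, icer + 1)$prob_cost_effective, 1)
  expect_error(ceac(one, numeric(0)), "non-empty")
})
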