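# Trace pair used by several comparison tests: experimental arm with longer
# PFS and OS, built from closed-form Weibull curves.
econ_traces <- local({
  h <- model_horizon()
  mk <- function(scale_pfs, scale_os) {
    run_markov(build_schedule(
      function(t) pweibull(t, 1.3, scale_pfs, lower.tail = FALSE),
      function(t) pweibull(t, 1.3, scale_os, lower.tail = FALSE), h), h)
  }
  list(exp = mk(7, 15), ctrl = mk(3.5, 10), horizon = h)
})

test_that("discount factors follow the continuous-time convention", {
  expect_equal(discount_factor(0, 0.045), 1)
  expect_equal(discount_factor(c(0, 100, 400), 0), rep(1, 3))
  expect_equal(discount_factor(365.25, 0.045), 1 / 1.045)
  expect_error(discount_factor(10, -0.01), "non-negative")
})

test_that("drug cost accrues per progression-free cycle at the cycle price", {
  inp <- inputs_no_ae()
  inp$discount_annual <- 0
  tr <- manual_trace(pfs = c(1, 1), pd = c(0, 0))  # one cycle, all in PFS
  bd <- attr(arm_costs(tr, inp, "experimental"), "breakdown")
  expect_equal(bd[["drug"]], 3635.34)
  bd_c <- attr(arm_costs(tr, inp, "control"), "breakdown")
  expect_equal(bd_c[["drug"]], 402.23)
  # no PD occupancy and no deaths -> those components vanish
  expect_equal(bd[["post_progression"]], 0)
  expect_equal(bd[["end_of_life"]], 0)
})

test_that("the adverse-event cost is the risk-weighted sum of the unit costs", {
  inp <- make_reference_config()
  inp$discount_annual <- 0
  tr <- manual_trace(pfs = c(1, 1), pd = c(0, 0))
  # independent spreadsheet-style summation of the printed rows
  hand_exp <- 0.29 * 924.89 + 0.35 * 684.18 + 0.28 * 452.17 +
    0.13 * 1484.53 + 0.038 * 745.43 + 0.10 * 30.94 + 0.02 * 160.38
  hand_ctrl <- 0.06 * 924.89 + 0.47 * 684.18 + 0.36 * 452.17 +
    0.04 * 1484.53 + 0 * 745.43 + 0.01 * 30.94 + 0.01 * 160.38
  expect_equal(attr(arm_costs(tr, inp, "experimental"),
                    "breakdown")[["adverse_events"]], hand_exp)
  expect_equal(attr(arm_costs(tr, inp, "control"),
                    "breakdown")[["adverse_events"]], hand_ctrl)
})

test_that("QALY accrual matches hand computation", {
  inp <- inputs_no_ae()
  inp$discount_annual <- 0

  tr2 <- manual_trace(pfs = c(1, 0.5, 0.5), pd = c(0, 0.5, 0.5))
  hand <- (0.85 + 0.5 * 0.85 + 0.5 * 0.52) * 28 / 365.25
  expect_equal(arm_qalys(tr2, inp, "experimental"), hand)

  # a year pinned in PFS is ~0.85 QALYs (boundary-count convention)
  yr <- manual_trace(pfs = rep(1, 14), pd = rep(0, 14))
  expect_lt(abs(arm_qalys(yr, inp, "experimental") - 0.85), 0.01)

  inp0 <- inp
  inp0$u_pfs <- 0
  inp0$u_pd <- 0
  expect_equal(arm_qalys(tr2, inp0, "experimental"), 0)
})

test_that("incremental comparisons reproduce printed table arithmetic", {
  base <- cea_compare(c(43708.75, 0.93), c(14063.87, 0.66))
  expect_equal(round_half_up(base$delta_cost, 2), 29644.88)
  expect_equal(round_half_up(base$delta_qaly, 2), 0.27)
  expect_equal(round_half_up(base$icer, 2), 109795.85)

  nego <- cea_compare(c(14411.14, 0.93), c(14063.87, 0.66))
  expect_equal(round_half_up(nego$delta_cost, 2), 347.27)
  expect_equal(round_half_up(nego$icer, 2), 1286.19)

  same <- cea_compare(c(100, 1), c(100, 1))
  expect_identical(same$status, "equivalent")
  expect_true(is.na(same$icer))

  costlier <- cea_compare(c(200, 1), c(100, 1))
  expect_identical(costlier$status, "dominated")
  cheaper <- cea_compare(c(50, 1.2), c(100, 1))
  expect_identical(cheaper$status, "dominant")
})

test_that("the ICER identity holds for computed comparisons", {
  inp <- make_reference_config()
  ce <- run_cea(econ_traces$exp, econ_traces$ctrl, inp)
  expect_lt(abs(ce$icer * ce$delta_qaly - ce$delta_cost), 1e-6)
  expect_gt(ce$delta_qaly, 0)
  expect_gt(ce$delta_cost, 0)
})

test_that("zero discounting reproduces direct undiscounted sums", {
  inp <- inputs_no_ae()
  inp$discount_annual <- 0
  tr <- econ_traces$exp
  K <- nrow(tr$occupancy) - 1
  occ <- tr$occupancy[1:K, ]
  # direct summation oracle
  q_direct <- sum((0.85 * occ[, "pfs"] + 0.52 * occ[, "pd"]) * 28 / 365.25)
  expect_equal(arm_qalys(tr, inp, "experimental"), q_direct)
  pd_unit <- 0.51 * 585.62 + (1 - 0.51) * 807.68
  eol_direct <- 2330.28 * sum(tr$new_deaths)
  bd <- attr(arm_costs(tr, inp, "experimental"), "breakdown")
  expect_equal(bd[["post_progression"]], pd_unit * sum(occ[, "pd"]))
  expect_equal(bd[["end_of_life"]], eol_direct)
})

test_that("the assistance-program pattern is 2 paid, 2 free from cycle 1", {
  expect_equal(pap_pay(1:6), c(1, 1, 0, 0, 1, 1))
  expect_equal(sum(pap_pay(1:10)) / 10, 0.6)  # hand count on 10 cycles
  expect_equal(pap_pay(1:8, scheme_on = FALSE), rep(1, 8))
  expect_error(pap_pay(0), ">= 1")
})

test_that("the assistance program never costs more than list price", {
  base <- make_reference_config("base_case")
  pap <- make_reference_config("pap")
  c_base <- arm_costs(econ_traces$exp, base, "experimental")
  c_pap <- arm_costs(econ_traces$exp, pap, "experimental")
  expect_lt(as.numeric(c_pap), as.numeric(c_base))
  expect_equal(as.numeric(c_pap) - attr(c_pap, "breakdown")[["drug"]],
               as.numeric(c_base) - attr(c_base, "breakdown")[["drug"]])
})

test_that("experimental-arm cost is strictly increasing in the price factor", {
  inp <- make_reference_config()
  costs <- vapply(c(0.2, 0.5, 0.8, 1), function(f) {
    ipf <- inp
    ipf$price_factor <- f
    as.numeric(arm_costs(econ_traces$exp, ipf, "experimental"))
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
  qalys <- vapply(c(0.2, 1), function(f) {
    ipf <- inp
    ipf$price_factor <- f
    run_cea(econ_traces$exp, econ_traces$ctrl, ipf)$delta_qaly
  }, numeric(1))
  expect_equal(qalys[1], qalys[2])  # effects invariant to price
})

test_that("threshold search matches the analytic root of a linear model", {
  a <- 10000; b <- 40000; ctrl <- c(14000, 0.66); dE <- 0.27
  mf <- function(f) cea_compare(c(a + b * f, 0.66 + dE), ctrl)
  wtp <- 26933.61
  th <- threshold_price(mf, wtp, tol_icer = 1e-9)
  f_closed <- (wtp * dE - (a - ctrl[1])) / b
  expect_lt(abs(th$f_star - f_closed), 1e-6)
  expect_lte(abs(th$icer - wtp), 1e-6)
})

test_that("threshold fractions are ordered by willingness-to-pay", {
  inp <- make_reference_config()
  mf <- function(f) {
    ipf <- inp
    ipf$price_factor <- f
    run_cea(econ_traces$exp, econ_traces$ctrl, ipf)
  }
  th_nat <- threshold_price(mf, inp$wtp_national)
  th_reg <- threshold_price(mf, inp$wtp_regional)
  expect_identical(th_nat$status, "ok")
  expect_lte(abs(th_nat$icer - inp$wtp_national), 0.01)
  expect_lte(abs(th_reg$icer - inp$wtp_regional), 0.01)
  expect_lte(th_reg$f_star, th_nat$f_star)
})

test_that("an unreachable threshold is reported as infeasible", {
  mf <- function(f) cea_compare(c(20000 + 1000 * f, 1.1), c(100, 1))
  th <- threshold_price(mf, wtp = 10)
  expect_identical(th$status, "infeasible")
  expect_true(is.na(th$f_star))
})
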