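test_that("the exponential MLE matches its closed form", {
  spec <- simulation_spec("a", 300, list(family = "exponential", rate = 0.1),
                          censor_model = list(family = "exponential",
                                              rate = 0.02),
                          admin_cutoff = Inf, seed = 7L)
  ipd <- simulate_arm(spec)
  f <- fit_survival(ipd, "exponential")
  closed <- sum(ipd$event) / sum(ipd$time)
  expect_lt(abs(f$params[["rate"]] - closed) / closed, 1e-6)
})

test_that("Weibull parameters are recovered on simulated data", {
  spec <- simulation_spec("a", 500, list(family = "weibull", shape = 1.5,
                                         scale = 10),
                          censor_model = list(family = "exponential",
                                              rate = 0.02),
                          admin_cutoff = Inf, seed = 21L)
  f <- fit_survival(simulate_arm(spec), "weibull")
  expect_gte(f$params[["shape"]], 1.35)
  expect_lte(f$params[["shape"]], 1.65)
})

test_that("all seven standard families recover their parameters", {
  cases <- list(
    exponential = list(model = list(family = "exponential", rate = 0.08),
                       true = c(rate = 0.08), med = log(2) / 0.08),
    weibull = list(model = list(family = "weibull", shape = 1.5, scale = 10),
                   true = c(shape = 1.5, scale = 10), med = 10 * log(2)^(1 / 1.5)),
    gompertz = list(model = list(family = "gompertz", shape = 0.1, rate = 0.05),
                    true = c(shape = 0.1, rate = 0.05), med = 8),
    lognormal = list(model = list(family = "lognormal", meanlog = 2, sdlog = 0.7),
                     true = c(meanlog = 2, sdlog = 0.7), med = exp(2)),
    loglogistic = list(model = list(family = "loglogistic", shape = 1.8, scale = 9),
                       true = c(shape = 1.8, scale = 9), med = 9),
    gamma = list(model = list(family = "gamma", shape = 1.6, rate = 0.16),
                 true = c(shape = 1.6, rate = 0.16), med = 8),
    # generated at the lognormal special case of the generalized gamma (Q = 0)
    generalized_gamma = list(model = list(family = "lognormal", meanlog = 2,
                                          sdlog = 0.7),
                             true = c(mu = 2, sigma = 0.7, Q = 0), med = exp(2)))
  for (fam in names(cases)) {
    cs <- cases[[fam]]
    spec <- simulation_spec(fam, 500, cs$model,
                            censor_model = list(family = "exponential",
                                                rate = 0.25 * log(2) / cs$med),
                            admin_cutoff = Inf, risk_grid = c(0, 1),
                            seed = 99L)
    ipd <- simulate_arm(spec)
    cens <- 1 - mean(ipd$event)
    expect_gt(cens, 0.10)
    expect_lt(cens, 0.30)
    f <- fit_survival(ipd, fam)
    expect_s3_class(f, "cua_survfit")
    est <- f$params[names(cs$true)]
    relerr <- ifelse(cs$true == 0, abs(est), abs(est - cs$true) / abs(cs$true))
    expect_lt(max(relerr), 0.15, label = paste(fam, "max relative error"))
    # information-criteria arithmetic identities
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
    expect_equal(f$bic, f$k * log(f$n_obs) - 2 * f$loglik)
    # extrapolated survival well-behaved on a 10-year grid
    g <- seq(0, 120, by = 1)
    s <- survival_at(f, g)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(s[1], 1)
  }
})

test_that("the generalized gamma never fits worse than its nested Weibull", {
  ipd <- simulate_arm(simulation_spec("a", 250,
                                      list(family = "weibull", shape = 1.4,
                                           scale = 9),
                                      admin_cutoff = 24, seed = 13L))
  fw <- fit_survival(ipd, "weibull")
  fg <- fit_survival(ipd, "generalized_gamma")
  expect_gte(fg$loglik, fw$loglik - 1e-4)
})

test_that("fractional polynomials nest correctly and search the power grid", {
  ipd <- exp_ipd(150, 0.1, seed = 31L)
  fp1 <- fit_fracpoly(ipd, 1)
  fp2 <- fit_fracpoly(ipd, 2)
  expect_true(all(fp1$powers %in% c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)))
  expect_true(all(fp2$powers %in% c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)))
  expect_gte(fp2$loglik, fp1$loglik - 1e-4)
  expect_equal(fp1$k, 2)
  expect_equal(fp2$k, 3)
  fexp <- fit_survival(ipd, "exponential")
  expect_gte(fp1$loglik, fexp$loglik - 1e-4)  # FP1 contains the exponential
})

test_that("an FP1 model with p = 0 and zero slope is the exponential", {
  ipd <- exp_ipd(300, 0.1, seed = 7L)
  fexp <- fit_survival(ipd, "exponential")
  m <- survcua:::new_survfit("fp1",
                             c(beta0 = log(fexp$params[["rate"]]), beta1 = 0),
                             fexp$loglik, 2, nrow(ipd), sum(ipd$event), TRUE,
                             powers = 0)
  g <- seq(0, 60, by = 0.5)
  expect_lt(max(abs(survival_at(m, g) - survival_at(fexp, g))), 1e-3)
})

test_that("FP survival quadrature is stable under grid refinement", {
  ipd <- exp_ipd(200, 0.1, seed = 17L)
  fp <- fit_fracpoly(ipd, 1, powers = 0.5)
  g <- seq(0, 120, by = 1)
  s_ref <- survival_at(fp, g)
  s_fine <- survival_at(fp, g, fp_step = (12 / 365.25) / 10)
  expect_lt(max(abs(s_ref - s_fine)), 1e-4)
})

test_that("model selection ranks by AIC with the documented tie-breaks", {
  ipd <- exp_ipd(500, 0.12, seed = 23L)
  fits <- list(fit_survival(ipd, "exponential"),
               fit_survival(ipd, "generalized_gamma"))
  rk <- select_model(fits)
  expect_identical(rk$family[1], "exponential")  # parsimony under true model

  single <- select_model(fits[1])
  expect_identical(single$family, "exponential")

  # equal AIC -> fewer parameters first
  a <- survcua:::new_survfit("weibull", c(shape = 1, scale = 1), -10, 2,
                             100, 80, TRUE)
  b <- survcua:::new_survfit("exponential", c(rate = 1), -11, 1, 100, 80, TRUE)
  expect_equal(a$aic, b$aic)
  rk2 <- select_model(list(a, b))
  expect_identical(rk2$family[1], "exponential")

  expect_error(select_model(list()), "no fits")
})

test_that("survival evaluation honours closed forms and domain checks", {
  ipd <- exp_ipd(400, 0.1, seed = 29L)
  f <- fit_survival(ipd, "exponential")
  lam <- f$params[["rate"]]
  expect_lt(abs(survival_at(f, log(2) / lam) - 0.5), 1e-3)
  expect_equal(survival_at(f, 0), 1)
  expect_error(survival_at(f, -1), "non-negative")
})

test_that("hazard-ratio adjustment is proportional hazards", {
  ipd <- exp_ipd(400, 0.1, seed = 29L)
  f <- fit_survival(ipd, "exponential")
  lam <- f$params[["rate"]]
  g <- seq(0, 60, by = 0.5)

  id <- adjust_by_hazard_ratio(f, 1)
  expect_equal(id(g), survival_at(f, g), tolerance = 1e-12)

  dbl <- adjust_by_hazard_ratio(f, 2)
  expect_lt(max(abs(dbl(g) - exp(-2 * lam * g))), 1e-9)
  expect_true(all(dbl(g) <= survival_at(f, g) + 1e-12))

  expect_error(adjust_by_hazard_ratio(f, 0), "positive")
  expect_error(adjust_by_hazard_ratio(f, -1), "positive")
})

test_that("simulate() draws from the fitted distribution", {
  ipd <- exp_ipd(500, 0.1, seed = 3L)
  f <- fit_survival(ipd, "exponential")
  x <- simulate(f, nsim = 400, seed = 8L)
  expect_identical(x, simulate(f, nsim = 400, seed = 8L))
  expect_lt(abs(median(x) - log(2) / f$params[["rate"]]), 1.2)
})
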