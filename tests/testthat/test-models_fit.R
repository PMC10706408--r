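test_that("single-step chain has the textbook closed form", {
  t <- c(0, 5, 50, 1e3)
  expect_equal(crc_model(t, k = 0.1), 1 - exp(-0.1 * t), tolerance = 1e-12)
  expect_equal(crc_model(0, k = 0.3, A = 2, B = 5), 5)
  expect_equal(crc_model(1e6, k = 0.3, A = 2, B = 5), 7, tolerance = 1e-6)
})

test_that("Bateman closed form matches the integrated chain ODEs", {
  t <- seq(0, 600, 2)
  ya <- crc_model(t, k = c(0.1, 0.02), kr = 0.005, f_rem = 0.7)
  expect_lt(max(abs(ya - crc_ode_oracle(t, c(0.1, 0.02), 0.005, 0.7))), 1e-6)
  set.seed(71)
  for (i in 1:20) {
    m <- sample(1:3, 1)
    k <- exp(runif(m, log(1e-3), log(1)))
    kr <- exp(runif(1, log(1e-3), log(1)))
    f <- runif(1)
    expect_lt(max(abs(crc_model(t, k, kr, f) - crc_ode_oracle(t, k, kr, f))),
              1e-6)
  }
})

test_that("chain asymptotics split removable and non-removable pools", {
  t_inf <- 1e6
  # fully removable: decays back to baseline
  expect_equal(crc_model(t_inf, k = c(0.1, 0.02), kr = 0.01, f_rem = 1,
                         A = 2, B = 3), 3, tolerance = 1e-6)
  # partially removable: plateau B + A (1 - f_rem)
  expect_equal(crc_model(t_inf, k = c(0.1, 0.02), kr = 0.01, f_rem = 0.7,
                         A = 2, B = 3), 3 + 2 * 0.3, tolerance = 1e-6)
})

test_that("coincident rates are handled continuously, never an exception", {
  t <- seq(0, 300, 1)
  expect_silent(y_eq <- crc_model(t, k = c(0.1, 0.1), kr = 0.1))
  expect_true(all(is.finite(y_eq)))
  y1 <- crc_model(t, k = c(0.1, 0.1 * (1 + 1e-6)), kr = 0.005)
  y2 <- crc_model(t, k = c(0.1, 0.1 * (1 + 1e-5)), kr = 0.005)
  expect_lt(max(abs(y1 - y2)), 1e-4)
})

test_that("exponential decay model and its half-life identity", {
  expect_equal(exp_decay_model(0, A = 2, k = 0.1, C = 1), 3)
  expect_equal(exp_decay_model(1e9, A = 2, k = 0.1, C = 1), 1)
  expect_equal(exp_decay_model(log(2) / 0.1, A = 2, k = 0.1, C = 1) - 1, 1)
  fit <- fit_model("expdecay",
                   kinetics_curve(0:100, exp_decay_model(0:100, 2, 0.05, 1)),
                   initials = c(A = 3, k = 0.02, C = 0.2))
  expect_equal(unname(coef(fit)), c(2, 0.05, 1), tolerance = 1e-4)
})

test_that("FRAP models: endpoints, degeneracies, half-time, mobile fraction", {
  ps <- frap_params("single", F0 = 0.2, Finf = 0.9, k = 0.027)
  expect_equal(frap_model(0, ps), 0.2)
  expect_equal(frap_model(1e9, ps), 0.9)
  expect_equal(frap_half_time(ps), log(2) / 0.027)      # about 25.67 s
  expect_equal(frap_half_time(ps), 25.67, tolerance = 1e-3)

  pd0 <- frap_params("double", F0 = 0.2, B1 = 0.7, B2 = 0, k1 = 0.05,
                     k2 = 0.003)
  t <- seq(0, 400, 1)
  expect_equal(frap_model(t, pd0),
               frap_model(t, frap_params("single", F0 = 0.2, Finf = 0.9,
                                         k = 0.05)))
  expect_equal(frap_half_time(pd0), log(2) / 0.05, tolerance = 1e-5)

  pd <- frap_params("double", F0 = 0.2, B1 = 0.5, B2 = 0.2, k1 = 0.06,
                    k2 = 0.004)
  th <- frap_half_time(pd)
  expect_lt(abs(frap_model(th, pd) - (0.2 + 0.9) / 2), 1e-9 * 0.7)

  expect_equal(mobile_fraction(frap_params("single", F0 = 0.2, Finf = 1,
                                           k = 0.1, F_pre = 1)), 1)
  expect_equal(mobile_fraction(frap_params("single", F0 = 0.2, Finf = 0.2 + 1e-12,
                                           k = 0.1, F_pre = 1)), 0,
               tolerance = 1e-9)
  expect_equal(mobile_fraction(frap_params("single", F0 = 0.2, Finf = 0.964,
                                           k = 0.1, F_pre = 1)), 0.955)
  expect_error(frap_params("double", F0 = 0.2, B1 = 0.5, B2 = 0.2,
                           k1 = 0.06, k2 = 0.004, Finf = 1.5),
               class = "cellkin_consistency_error")
  expect_error(frap_half_time(frap_params("single", F0 = 0.5, Finf = 0.5,
                                          k = 0.1)),
               class = "cellkin_input_error")
})

test_that("diffusion recovery: series oracle, limits, effective D", {
  # power-series oracle for e^-x (I0(x) + I1(x)), summed in log space
  # with enough terms to converge over the whole tested range
  series_ebi <- function(x) {
    n <- 0:200
    t0 <- exp(2 * n * log(x / 2) - 2 * lgamma(n + 1) - x)
    t1 <- exp((2 * n + 1) * log(x / 2) - lgamma(n + 1) - lgamma(n + 2) - x)
    sum(t0) + sum(t1)
  }
  xs <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20, 50)
  for (x in xs)
    expect_lt(abs(cellkin:::ebessel_sum(x) - series_ebi(x)), 1e-9)

  p <- list(tau_D = 16.89, M = 0.964, F0 = 0.2)
  expect_equal(diffusion_model(1e9, p$tau_D, p$M, p$F0), p$M, tolerance = 1e-4)
  expect_equal(diffusion_model(0, p$tau_D, p$M, p$F0), p$F0)
  expect_true(all(diff(diffusion_model(seq(1, 2000, 1), p$tau_D, p$M, p$F0)) > 0))
  expect_equal(effective_diffusion(1.0, 16.89), 1 / (4 * 16.89))
  expect_equal(effective_diffusion(1.0, 16.89), 0.0148, tolerance = 1e-3)
  expect_error(diffusion_model(1, -1, 0.9, 0.2), class = "cellkin_input_error")
})

test_that("expression models reproduce built-ins and reject unknowns", {
  t <- seq(0, 100, 1)
  m1 <- parse_model("C + A*exp(-k*t)", params = c(A = 1, k = 0.1, C = 0))
  expect_equal(m1$fn(t, c(A = 2, k = 0.05, C = 1)),
               exp_decay_model(t, 2, 0.05, 1))
  m2 <- parse_model("A*(1-exp(-k*t))", params = c(A = 1, k = 0.1))
  expect_equal(m2$fn(t, c(A = 1, k = 0.1)), crc_model(t, k = 0.1),
               tolerance = 1e-12)
  expect_error(parse_model("A*exp(-q*t)", params = c(A = 1)),
               regexp = "'q'", class = "cellkin_parse_error")
})

test_that("the packaged model library loads and evaluates correctly", {
  lib <- load_model_library(system.file("extdata", "crc_models.txt",
                                        package = "cellkin"))
  expect_true(all(c("crc1", "crc2", "expdecay", "frap_double") %in% names(lib)))
  t <- seq(0, 400, 2)
  pars2 <- c(A = 1, k1 = 0.1, k2 = 0.02, kr = 0.005, f = 0.7, B = 0)
  expect_equal(lib$crc2$fn(t, pars2),
               crc_model(t, k = c(0.1, 0.02), kr = 0.005, f_rem = 0.7),
               tolerance = 1e-9)
  pars1 <- c(A = 1, k1 = 0.05, kr = 0.004, f = 0.6, B = 0.1)
  expect_equal(lib$crc1$fn(t, pars1),
               crc_model(t, k = 0.05, kr = 0.004, f_rem = 0.6, B = 0.1),
               tolerance = 1e-9)
})

test_that("self-fits recover parameters from badly perturbed initials", {
  t <- seq(0, 500, 2)
  cv <- kinetics_curve(t, exp_decay_model(t, A = 3, k = 0.02, C = 0.5))
  set.seed(72)
  for (i in 1:3) {
    init <- c(A = 3, k = 0.02, C = 0.5) * runif(3, 0.5, 1.5)
    fit <- fit_model("expdecay", cv, initials = init)
    expect_equal(unname(coef(fit)), c(3, 0.02, 0.5), tolerance = 1e-4)
    expect_lt(fit$rss, 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }

  # two-step chain with removal: rates recovered within 1% (301 points)
  tc <- seq(0, 600, 2)
  truth <- c(k1 = 0.1, k2 = 0.02, kr = 0.005, f_rem = 0.8, A = 1, B = 0)
  ycrc <- crc_model(tc, k = c(0.1, 0.02), kr = 0.005, f_rem = 0.8)
  set.seed(73)
  fitc <- fit_model("crc2", kinetics_curve(tc, ycrc),
                    initials = truth * runif(6, 0.8, 1.2))
  rel <- abs(coef(fitc)[c("k1", "k2", "kr")] - truth[c("k1", "k2", "kr")]) /
    truth[c("k1", "k2", "kr")]
  expect_true(all(rel < 0.01))
})

test_that("noisy replicate fits have small median rate bias", {
  tc <- seq(0, 600, 2)
  ytrue <- crc_model(tc, k = c(0.1, 0.02), kr = 0.005, f_rem = 0.8)
  amp <- diff(range(ytrue))
  set.seed(74)
  est <- replicate(100, {
    y <- ytrue + rnorm(length(tc), 0, 0.02 * amp)
    fit <- fit_model("crc2", kinetics_curve(tc, y),
                     initials = c(k1 = 0.1, k2 = 0.02, kr = 0.005,
                                  f_rem = 0.8, A = 1, B = 0) *
                       runif(6, 0.9, 1.1))
    coef(fit)[c("k1", "k2", "kr")]
  })
  bias <- abs(apply(est, 1, stats::median) - c(0.1, 0.02, 0.005)) /
    c(0.1, 0.02, 0.005)
  expect_true(all(bias < 0.05))
})

test_that("derived FRAP quantities are invariant to affine intensity rescaling", {
  ref <- simulate_frap_experiment(scene_config("bard1_reference"))
  cv <- crop_after_event(ref$curve, "bleach")
  p <- ref$truth$params
  init <- c(F0 = p$F0, B1 = p$B1, B2 = p$B2, k1 = p$k1, k2 = p$k2)
  fit1 <- fit_model("frap2", cv, initials = init)
  d1 <- frap_derive(fit1, F_pre = 1)
  a <- 37; b <- 5                                   # affine rescale
  cv2 <- kinetics_curve(cv$t, a * cv$y + b)
  fit2 <- fit_model("frap2", cv2,
                    initials = c(F0 = a * p$F0 + b, B1 = a * p$B1,
                                 B2 = a * p$B2, k1 = p$k1, k2 = p$k2) *
                      runif(5, 0.9, 1.1))
  d2 <- frap_derive(fit2, F_pre = a * 1 + b)
  expect_equal(d2$half_time_s, d1$half_time_s, tolerance = 1e-4)
  expect_equal(d2$mobile_fraction, d1$mobile_fraction, tolerance = 1e-4)
})

test_that("fit results behave like standard model objects", {
  t <- seq(0, 100, 1)
  cv <- kinetics_curve(t, exp_decay_model(t, 2, 0.05, 1) + 0)
  fit <- fit_model("expdecay", cv, initials = c(A = 1, k = 0.1, C = 0))
  expect_s3_class(fit, "kin_fit")
  expect_named(coef(fit), c("A", "k", "C"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = list(t = 0)), 3, tolerance = 1e-6)
  expect_equal(unname(residuals(fit)), unname(cv$y - fitted(fit)))
  expect_output(print(fit), "expdecay")
  expect_output(print(summary(fit)), "R-squared")
  expect_error(fit_model("expdecay", kinetics_curve(1:3, c(1, 2, 3))),
               class = "cellkin_input_error")
})
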