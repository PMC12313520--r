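test_that("initial_rate recovers exact lines and flat series", {
  t_s <- seq(0, 4 * 3600, 300)
  th <- t_s / 3600
  rf <- initial_rate(t_s, 1.01 * th, limiting0 = 100)
  expect_equal(rf$rate, 1.01, tolerance = 1e-10)
  expect_lt(diff(rf$ci95), 1e-8)
  expect_equal(initial_rate(t_s, rep(2, length(t_s)), limiting0 = 10)$rate,
               0, tolerance = 1e-12)
  expect_error(initial_rate(c(0, 1, 2), c(0, 1, 2)), "5 points")
})

test_that("initial_rate is within 3% on a saturating curve at 10% cap", {
  # closed form x = Pmax (1 - exp(-r t / Pmax)), sampled every 5 min
  r <- 2; p_max <- 10
  t_s <- seq(0, 8 * 3600, 300)
  x <- p_max * (1 - exp(-r * (t_s / 3600) / p_max))
  rf <- initial_rate(t_s, x, max_conversion = 0.1, limiting0 = p_max)
  expect_lt(abs(rf$rate - r) / r, 0.03)
  # window ends near 10% conversion of the limiting species
  expect_lt(rf$window[2L], -log(0.88) * p_max / r * 3600)
})

test_that("estimate_tof divides by T0 and rejects template-free input", {
  t_s <- seq(0, 4 * 3600, 300)
  tf <- estimate_tof(t_s, 2 * t_s / 3600, T0 = 2, limiting0 = 100)
  expect_equal(tf$tof, 1, tolerance = 1e-10)
  expect_error(estimate_tof(t_s, t_s, T0 = 0), "T0")
})

test_that("estimate_ic50 is exact on noiseless model data and equivariant", {
  P0 <- c(0, 2, 5, 10, 20, 50)
  tofs <- 1 / (1 + P0 / 10)
  fit <- estimate_ic50(P0, tofs)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 10, tolerance = 1e-2)
  expect_equal(fit$tof0, 1, tolerance = 1e-3)
  # scale equivariance: preloads x c -> ic50 x c
  fit3 <- estimate_ic50(P0 * 3, tofs)
  expect_equal(fit3$ic50, 30, tolerance = 1e-2)
  # flat curve: no inhibition detected, lower bound reported
  flat <- estimate_ic50(P0, rep(0.8, 6))
  expect_false(flat$converged)
  expect_true(is.na(flat$ic50))
  expect_equal(flat$ic50_lower_bound, 50)
  expect_error(estimate_ic50(c(1, 2, 3), c(1, 1, 1)), "preload")
})

test_that("fit_leak_rate recovers k from noiseless closed forms", {
  t_s <- seq(0, 40 * 3600, 300)
  # equal concentrations, k = 0.32 M^-1 s^-1
  k <- 0.32e-9
  x_eq <- 100^2 * k * t_s / (1 + 100 * k * t_s)
  fit <- fit_leak_rate(t_s, x_eq, 100, 100)
  expect_lt(abs(fit$k - 0.32) / 0.32, 1e-3)
  # unequal concentrations, k = 1 M^-1 s^-1
  k2 <- 1e-9; A0 <- 100; B0 <- 75
  e <- exp((A0 - B0) * k2 * t_s)
  x_un <- A0 * B0 * (e - 1) / (A0 * e - B0)
  fit2 <- fit_leak_rate(t_s, x_un, A0, B0)
  expect_lt(abs(fit2$k - 1) / 1, 1e-3)
  # degenerate inputs
  expect_equal(fit_leak_rate(t_s, rep(0, length(t_s)), 100, 100)$k, 0)
  expect_error(fit_leak_rate(t_s, x_eq, -1, 100), "A0")
})

test_that("fit_tof_linearity recovers slope and intercept", {
  T0 <- c(0.25, 0.5, 1, 2.5, 5)
  rate <- 2 * T0 + 0.01
  lf <- fit_tof_linearity(T0, rate)
  expect_equal(lf$slope, 2, tolerance = 1e-10)
  expect_equal(lf$intercept, 0.01, tolerance = 1e-10)
  expect_error(fit_tof_linearity(c(1, 1, 1), c(1, 1, 1)), "distinct")
  # intercept of noiseless mechanistically-anchored points recovers the
  # untemplated background k_leak * A0 * B0
  leak_rate <- 0.32e-9 * 100 * 100 * 3600  # nM/h
  st <- seq(0, 40 * 3600, 300)
  rates2 <- vapply(T0, function(t0) {
    pp <- pheno_params(3.6, T0 = t0, p_max = 100, ic50_true = 100,
                       leak_k = 0.32, noise_cv = 0, replicates = 1L)
    out <- generate_phenomenological(pp, st)
    initial_rate(out$times, out$clean, limiting0 = 100)$rate
  }, numeric(1L))
  lf2 <- fit_tof_linearity(T0, rates2)
  expect_lt(abs(lf2$intercept - leak_rate) / leak_rate, 0.25)
})

test_that("TOF screening surface has an interior optimum in handhold", {
  p <- calibrated$params
  tofs <- vapply(6:10, function(v) mech_tof(6, v, p), numeric(1L))
  names(tofs) <- sprintf("6t/%dh", 6:10)
  best <- which.max(tofs)
  expect_true(best > 1L && best < 5L)  # interior in v
  expect_gt(max(tofs["6t/8h"], tofs["6t/9h"]), tofs["6t/10h"])
})

test_that("estimators recover the shipped fixture ground truths", {
  scr <- generate_screening_dataset(seed = 2)
  d9 <- scr$data[["6t/9h"]]
  tf9 <- estimate_tof(d9$times, d9$conc, 1, limiting0 = 10)
  expect_lt(abs(tf9$tof - 1.01) / 1.01, 0.05)
  d8 <- scr$data[["6t/8h"]]
  tf8 <- estimate_tof(d8$times, d8$conc, 1, limiting0 = 10)
  expect_lt(abs(tf8$tof - 0.622) / 0.622, 0.05)
  inh <- generate_inhibition_dataset(seed = 2)
  tofs <- lapply(inh$data, function(d)
    estimate_tof(d$times, d$conc, d$truth$T0, limiting0 = d$truth$p_max))
  ic <- estimate_ic50(inh$preloads, tofs)
  expect_true(ic$converged)
  expect_lt(abs(ic$ic50 - 11) / 11, 0.15)
})
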