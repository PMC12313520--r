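test_that("phenomenological generator matches its closed forms", {
  st <- seq(0, 20 * 3600, 600)
  # no inhibition: P = p_max (1 - exp(-tof T0 t / p_max))
  pp <- pheno_params(tof_true = 1.01, T0 = 1, p_max = 10, noise_cv = 0,
                     replicates = 1L, seed = 3)
  out <- generate_phenomenological(pp, st)
  closed <- 10 * (1 - exp(-1.01 * 1 * (st / 3600) / 10))
  expect_lt(max(abs(out$clean - closed)), 1e-8)
  # t -> 0 slope equals tof_true * T0
  slope0 <- (out$clean[2L] - out$clean[1L]) / (st[2L] / 3600)
  expect_equal(slope0, 1.01, tolerance = 0.01)
  # preload at ic50 halves the initial slope
  pp2 <- pheno_params(1, T0 = 1, p_max = 1e5, ic50_true = 10, preload = 10,
                      noise_cv = 0, replicates = 1L)
  out2 <- generate_phenomenological(pp2, st)
  s2 <- (out2$clean[2L] - out2$clean[1L]) / (st[2L] / 3600)
  expect_equal(s2, 0.5, tolerance = 0.01)
  # fixed seed regeneration is bit-identical
  a <- generate_phenomenological(pheno_params(1, 1, 10, seed = 9), st)
  b <- generate_phenomenological(pheno_params(1, 1, 10, seed = 9), st)
  expect_identical(a, b)
})

test_that("screening dataset covers the grid with published ground truths", {
  scr <- generate_screening_dataset(seed = 4, render = FALSE)
  gt <- scr$manifest$ground_truth
  expect_equal(nrow(gt), 25L)   # full 5 x 5 grid
  expect_equal(gt$tof_true[gt$label == "6t/9h"], 1.01)
  expect_equal(gt$tof_true[gt$label == "6t/8h"], 0.622)
  expect_true(all(gt$tof_true > 0))
  # the 6t/9h clean curve's initial slope is 1.01 nM/h per nM template
  d <- scr$data[["6t/9h"]]
  s0 <- (d$clean[2L] - d$clean[1L]) / (d$times[2L] / 3600)
  expect_equal(s0, 1.01, tolerance = 0.01)
  expect_error(generate_screening_dataset(u_range = integer(0)), "grid")
})

test_that("inhibition dataset halves TOF at the true IC50 and is ordered", {
  inh <- generate_inhibition_dataset("6t8h", preloads = c(0, 11, 22, 44),
                                     seed = 4)
  sl <- vapply(inh$data, function(d) {
    (d$clean[2L] - d$clean[1L]) / (d$times[2L] / 3600)
  }, numeric(1L))
  expect_equal(unname(sl[2L] / sl[1L]), 0.5, tolerance = 0.02)
  # shipped IC50 ordering follows the published values
  ics <- vapply(c("6t8h", "6t9h", "6t10h"), function(lbl)
    generate_inhibition_dataset(lbl, seed = 1)$manifest$ground_truth$ic50_true,
    numeric(1L))
  expect_true(ics[["6t8h"]] > ics[["6t9h"]] &&
                ics[["6t9h"]] > ics[["6t10h"]])
  expect_error(generate_inhibition_dataset(preloads = c(1, 2, 3, 4)), "0")
})

test_that("fixtures regenerate bit-identically from their manifests", {
  a <- generate_screening_dataset(seed = 6, u_range = 5:7, v_range = 7:9,
                                  render = FALSE)
  b <- regenerate_fixture(a$manifest)
  expect_identical(a, b)
  a2 <- generate_turnover_dataset(seed = 6)
  b2 <- regenerate_fixture(a2$manifest)
  expect_identical(a2, b2)
})

test_that("pheno and mechanistic generators agree on the initial slope", {
  # configure the phenomenological law to the mechanistically measured TOF
  p <- calibrated$params
  tof_m <- mech_tof(6, 8, p)
  pp <- pheno_params(tof_true = tof_m, T0 = 1, p_max = 10, noise_cv = 0,
                     replicates = 1L)
  st <- seq(0, 3 * 3600, 300)
  out <- generate_phenomenological(pp, st)
  tof_p <- estimate_tof(st, out$clean, 1, limiting0 = 10)$tof
  expect_lt(abs(tof_p - tof_m) / tof_m, 0.02)
})

test_that("specificity dataset reproduces the published well layout", {
  spec <- generate_specificity_dataset(seed = 8, duration = 6 * 3600)
  expect_length(spec$trajectories, 10L)   # 9 templates + no-template
  expect_equal(sum(spec$plate$wells$role == "sample"), 10L)
  expect_equal(sum(spec$plate$wells$role == "positive"), 9L)
  expect_equal(sum(spec$plate$wells$role == "negative"), 1L)
  # template-free well shows only leak-level product
  none <- spec$trajectories[["none"]]
  prods <- sprintf("M%dN%d", rep(1:3, 3), rep(1:3, each = 3))
  total_leak <- sum(none$conc[nrow(none$conc), prods])
  expect_lt(total_leak, 1)   # nM, essentially negligible vs 75 nM pools
  # templated wells enrich the correct product
  cm <- product_distribution(spec$endpoints)
  expect_gt(accuracy(cm)$min, 50)  # short 6 h run; full check in acceptance
})
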