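test_that("dimerization network has the expected structure and rates", {
  p <- rate_params()
  d <- design_variant(6, 8)
  net <- build_dimerization_network(d, p, include_TN_sequestration = FALSE)
  expect_equal(nrow(net$species), 7L)
  expect_equal(nrow(net$reactions), 6L)
  net_tn <- build_dimerization_network(d, p)
  expect_equal(nrow(net_tn$species), 8L)
  expect_true("TN" %in% net_tn$species$id)
  # toehold-free design displaces at the leak-level rate
  net0 <- build_dimerization_network(design_variant(0, 8), p)
  expect_equal(net0$reactions$k[net0$reactions$id == "R1f"], 0.32)
  # interconversion channel is off by default, on by flag
  expect_false("R6" %in% net_tn$reactions$id)
  net_ic <- build_dimerization_network(d, p, include_interconversion = TRUE)
  expect_equal(net_ic$reactions$k[net_ic$reactions$id == "R6"],
               1e-3 * p$k_on)
})

test_that("strand conservation and detailed balance hold for all builders", {
  p <- calibrated$params
  nets <- list(
    build_dimerization_network(design_variant(6, 8), p,
                               include_interconversion = TRUE),
    build_competition_network(c(1, 3), design_variant(6, 8), p,
                              include_interconversion = TRUE),
    build_competition_network(c(2, 2), design_variant(6, 9), p),
    build_trimer_network(c("TAB11", "TBC11", "TAB22", "TBC22"), 1:2,
                         design_variant(6, 8), p))
  for (net in nets) {
    expect_true(all(check_strand_conservation(net)))
    db <- check_detailed_balance(net)
    expect_true(all(db$ok))
    expect_true(all(abs(db$dG_implied - db$dG) <=
                      1e-12 * pmax(1, abs(db$dG))))
  }
})

test_that("detailed balance matches independently recomputed reaction dGs", {
  p <- rate_params()
  d <- design_variant(6, 8)
  net <- build_dimerization_network(d, p)
  rx <- net$reactions
  # toehold exchange: gain toehold u, lose secondary toehold s, eliminate
  # one mismatch, clamp contribution
  dG1 <- -(duplex_dG(d$u, p) - duplex_dG(d$s, p)) - p$ddG_mm + p$dG_clamp
  expect_equal(rx$dG[rx$id == "R1f"], dG1)
  expect_equal(log(rx$k[rx$id == "R1f"] / rx$k[rx$id == "R1r"]), -dG1)
  # product rebinding: bi -> uni with C0 standard state
  dGp <- duplex_dG(d$u, p) + duplex_dG(d$v, p) + p$dG_coop
  expect_equal(rx$dG[rx$id == "R3f"], dGp)
  expect_equal(log(rx$k[rx$id == "R3f"] * p$C0 / rx$k[rx$id == "R3r"]), -dGp)
})

test_that("competition network wires cross-channels at zero-length rates", {
  p <- rate_params()
  d <- design_variant(6, 8)
  net <- build_competition_network(c(1, 3), d, p)
  expect_equal(sum(net$species$role == "product"), 9L)
  rx <- net$reactions
  # matched toehold at full TMSD rate, mismatched at rate_tmsd(0)
  expect_equal(rx$k[rx$id == "TMSD1f"], rate_tmsd(6, p))
  expect_equal(rx$k[rx$id == "TMSD2f"], rate_tmsd(0, p))
  # matched handhold at full HMSD rate, mismatched at rate_hmsd(0)
  expect_equal(rx$k[rx$id == "HMSD13"], rate_hmsd(8, p))
  expect_equal(rx$k[rx$id == "HMSD12"], rate_hmsd(0, p))
  expect_equal(sum(grepl("^LEAK", rx$id)), 9L)
  expect_error(build_competition_network(c(0, 3)), "template")
})

test_that("removing the template leaves only the leak channel", {
  p <- calibrated$params
  net <- build_dimerization_network(design_variant(6, 8), p)
  prot <- protocol(c(ML = 100, N = 100), list(), 6 * 3600,
                   seq(0, 6 * 3600, 600))
  tr <- simulate(net, prot)
  k <- p$k_leak * 1e-9
  closed <- 100^2 * k * tr$times / (1 + 100 * k * tr$times)
  expect_lt(max(abs(tr$conc[, "MN"] - closed)), 1e-6)
  expect_true(all(tr$conc[, c("MT", "TMN")] == 0))
})

test_that("trimer network matches hand enumeration and yields trimers", {
  p <- calibrated$params
  d <- design_variant(6, 8)
  # 1-index system with both templates, enumerated by hand:
  # species: AL1 BL1 C1 LA LB TAB11 TBC11 A1.TAB11 AB11L B1.TBC11
  #          AB11.TBC11 BC11 ABC111                         -> 13
  # reactions: 3 TMSD pairs (6), 4 HMSD channels, 4 leaks    -> 14
  tn <- build_trimer_network(c("TAB11", "TBC11"), 1, d, p)
  expect_equal(nrow(tn$species), 13L)
  expect_equal(nrow(tn$reactions), 14L)
  # no templates: leak channels only
  tn0 <- build_trimer_network(character(0), 1, d, p)
  expect_true(all(grepl("^LK", tn0$reactions$id)))
  # both index-1 templates make ABC111 reachable; leak-only barely any
  prot <- protocol(c(A1L = 10, B1L = 10, C1 = 10, TAB11 = 2, TBC11 = 2),
                   list(), 48 * 3600, seq(0, 48 * 3600, 3600))
  tr <- simulate(tn, prot)
  expect_gt(tr$conc[nrow(tr$conc), "ABC111"], 1)
  prot0 <- protocol(c(A1L = 10, B1L = 10, C1 = 10), list(), 48 * 3600,
                    seq(0, 48 * 3600, 3600))
  tr0 <- simulate(tn0, prot0)
  expect_lt(tr0$conc[nrow(tr0$conc), "ABC111"], 1e-3)
  # mixed pools with all four templates produce both intended trimers
  tall <- build_trimer_network(c("TAB11", "TBC11", "TAB22", "TBC22"), 1:2,
                               d, p)
  init <- c(A1L = 10, B1L = 10, C1 = 10, A2L = 10, B2L = 10, C2 = 10,
            TAB11 = 2, TBC11 = 2, TAB22 = 2, TBC22 = 2)
  tra <- simulate(tall, protocol(init, list(), 48 * 3600,
                                 seq(0, 48 * 3600, 3600)))
  expect_gt(tra$conc[nrow(tra$conc), "ABC111"], 0.5)
  expect_gt(tra$conc[nrow(tra$conc), "ABC222"], 0.5)
  expect_error(build_trimer_network("TAB12"), "subset")
})

test_that("network CSV edge list roundtrips", {
  net <- build_dimerization_network(design_variant(6, 8), rate_params())
  f <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, f)
  df <- read_network_csv(f)
  expect_equal(nrow(df), nrow(net$reactions))
  expect_equal(as.numeric(df$k), net$reactions$k, tolerance = 1e-10)
  expect_setequal(df$units, c("M-1 s-1", "s-1"))
})
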