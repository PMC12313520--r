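test_that("forward model is exact without noise and drift", {
  net <- build_dimerization_network(design_variant(6, 8), rate_params())
  calib <- default_calibration(net)
  times <- seq(0, 3600, 600)
  tr <- toy_trajectory(times, list(MN = seq(0, 5, length.out = 7)))
  # pad missing species with zeros via rendering against full calib
  conc <- matrix(0, 7, nrow(calib$phi),
                 dimnames = list(NULL, rownames(calib$phi)))
  conc[, "MN"] <- tr$conc[, "MN"]
  pl <- render_fluorescence(list(times = times, conc = conc), calib,
                            noise = FALSE)
  i <- which(pl$wells$role == "sample")
  expect_equal(pl$signal[i, "AF488", ],
               unname(calib$baseline["AF488"] +
                        calib$phi["MN", "AF488"] * conc[, "MN"]))
  # quenched locked monomer barely responds; free/displaced M fully
  expect_lt(calib$phi["ML", "AF488"], 0.05 * calib$phi["MT", "AF488"])
  expect_error(render_fluorescence(
    list(times = times,
         conc = matrix(1, 7, 1, dimnames = list(NULL, "ghost"))), calib),
    "ghost")
})

test_that("fixed seed renders bitwise-identical noise", {
  net <- build_dimerization_network(design_variant(6, 8), rate_params())
  calib <- default_calibration(net)
  prot <- screening_protocol(duration = 3600, by = 600)
  tr <- simulate(net, prot)
  a <- render_fluorescence(tr, calib, seed = 11)
  b <- render_fluorescence(tr, calib, seed = 11)
  expect_identical(a$signal, b$signal)
  c_ <- render_fluorescence(tr, calib, seed = 12)
  expect_false(identical(a$signal, c_$signal))
})

test_that("control correction removes drift and baseline exactly", {
  net <- build_dimerization_network(design_variant(6, 8), rate_params())
  calib <- default_calibration(net)
  times <- seq(0, 7200, 300)
  conc <- matrix(0, length(times), nrow(calib$phi),
                 dimnames = list(NULL, rownames(calib$phi)))
  conc[, "MN"] <- 5 * (1 - exp(-times / 3600))
  drift <- function(t) 1 + 0.1 * sin(t / 1800)
  pl <- render_fluorescence(list(times = times, conc = conc), calib,
                            drift = drift, noise = FALSE,
                            positive_control = c(MN = 8))
  cor <- correct_controls(pl)
  i <- which(cor$wells$role == "sample")
  expect_equal(cor$signal[i, "AF488", ],
               unname(calib$phi["MN", "AF488"] * conc[, "MN"]),
               tolerance = 1e-10)
  # without drift the correction is identity up to baseline subtraction
  pl2 <- render_fluorescence(list(times = times, conc = conc), calib,
                             noise = FALSE, positive_control = c(MN = 8))
  cor2 <- correct_controls(pl2)
  expect_equal(cor2$signal[i, "AF488", ],
               pl2$signal[i, "AF488", ] - unname(calib$baseline["AF488"]),
               tolerance = 1e-10)
  # degenerate controls: positive identical to negative
  pl3 <- pl
  pl3$signal[pl3$wells$role == "positive", , ] <-
    pl3$signal[pl3$wells$role == "negative", , ]
  expect_error(correct_controls(pl3), "degenerate")
})

test_that("noiseless render -> correct -> unmix roundtrip is exact", {
  p <- calibrated$params
  net <- build_competition_network(c(1, 3), design_variant(6, 8), p)
  calib <- default_calibration(net)
  times <- seq(0, 3600, 600)
  species <- c("M1N3", "M1N1", "M1N2", "M2N1", "M3N2")
  conc <- matrix(0, length(times), nrow(calib$phi),
                 dimnames = list(NULL, rownames(calib$phi)))
  for (i in seq_along(species))
    conc[, species[i]] <- i * seq(0, 1, length.out = length(times))
  drift <- function(t) 1 + 0.05 * sin(t / 900)
  pl <- render_fluorescence(list(times = times, conc = conc), calib,
                            drift = drift, noise = FALSE,
                            positive_control = stats::setNames(
                              rep(50, length(species)), species))
  um <- unmix(correct_controls(pl), calib, species)
  expect_length(um$unidentifiable, 0L)
  rel <- abs(um$conc[-1L, species] - conc[-1L, species]) /
    pmax(conc[-1L, species], 1e-9)
  expect_lt(max(rel[conc[-1L, species] > 0]), 1e-6)
  expect_lt(max(um$residual), 1e-8)
})

test_that("M2N2 is flagged unidentifiable from the default calibration", {
  p <- calibrated$params
  net <- build_competition_network(c(2, 2), design_variant(6, 8), p)
  calib <- default_calibration(net)
  # M2 and N2 share AF546 with no FRET distinction: the dimer's column is
  # a scalar multiple of its constituent monomer's
  flags <- unidentifiable_species(calib, c("M1N2", "M2N1", "N2", "M2N2"))
  expect_identical(flags, "M2N2")
  um_species <- c("M1N2", "M2N1", "N2", "M2N2")
  times <- seq(0, 1800, 600)
  conc <- matrix(0, length(times), nrow(calib$phi),
                 dimnames = list(NULL, rownames(calib$phi)))
  conc[, "N2"] <- 10
  pl <- render_fluorescence(list(times = times, conc = conc), calib,
                            noise = FALSE,
                            positive_control = c(M1N2 = 20, M2N1 = 20))
  um <- unmix(correct_controls(pl), calib, um_species)
  expect_identical(um$unidentifiable, "M2N2")
  expect_true(all(is.na(um$conc[, "M2N2"])))
  # identifiability is a function of the calibration only
  expect_identical(unidentifiable_species(calib, um_species),
                   unidentifiable_species(calib, um_species))
  # a fully dark subset is an error
  expect_error(unmix(correct_controls(pl), calib, c("L1", "T22")),
               "rank deficient")
})

test_that("unmixing error shrinks with replicate averaging", {
  p <- calibrated$params
  net <- build_competition_network(c(1, 3), design_variant(6, 8), p)
  calib <- default_calibration(net)
  times <- seq(0, 3600, 300)
  species <- c("M1N3", "M2N1", "M3N2")
  conc <- matrix(0, length(times), nrow(calib$phi),
                 dimnames = list(NULL, rownames(calib$phi)))
  for (i in seq_along(species)) conc[, species[i]] <- 10 * i / 3
  err_for <- function(nrep, seed) {
    set.seed(seed)
    wells <- c(list(sample1 = NULL), rep(list(NULL), nrep - 1L))
    # render nrep independent sample wells by repeated noisy rendering
    plates <- lapply(seq_len(nrep), function(r)
      render_fluorescence(list(times = times, conc = conc), calib,
                          noise = TRUE,
                          positive_control = stats::setNames(
                            rep(50, length(species)), species)))
    # average the corrected sample signals across plates
    cors <- lapply(plates, correct_controls)
    ums <- lapply(cors, function(cp) unmix(cp, calib, species)$conc)
    avg <- Reduce(`+`, ums) / nrep
    sqrt(mean((avg[, species] - conc[, species])^2))
  }
  e1 <- mean(vapply(1:6, function(s) err_for(1L, s), numeric(1L)))
  e9 <- mean(vapply(1:6, function(s) err_for(9L, s + 100L), numeric(1L)))
  # standard-error scaling 1/sqrt(9) = 3x, within a factor 2
  expect_lt(e9, e1 / 1.5)
  expect_gt(e9, e1 / 6)
})

test_that("plate and calibration CSVs roundtrip", {
  net <- build_dimerization_network(design_variant(6, 8), rate_params())
  calib <- default_calibration(net)
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(calib, f)
  back <- read_calibration_csv(f)
  expect_equal(back$phi[rownames(calib$phi), colnames(calib$phi)],
               calib$phi)
  expect_equal(unname(back$baseline), unname(calib$baseline))
  prot <- screening_protocol(duration = 1800, by = 600)
  tr <- simulate(net, prot)
  pl <- render_fluorescence(tr, calib, seed = 5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(pl, f2)
  df <- read_plate_csv(f2)
  expect_equal(nrow(df), length(pl$times) * length(pl$channels) *
                 nrow(pl$wells))
  one <- df[df$well == "sample1" & df$channel == "AF488", ]
  expect_equal(as.numeric(one$value[order(one$time_s)]),
               pl$signal["sample1", "AF488", ], tolerance = 1e-11)
})
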