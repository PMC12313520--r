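# shared fixtures built in code

calibrated <- shipped_params("6t8h")

screening_protocol <- function(M0 = 10, N0 = 10, T0 = 1,
                               duration = 3 * 3600, by = 300) {
  init <- c(ML = M0)
  if (T0 > 0) init["T"] <- T0
  protocol(init, list(list(time = 0, add = c(N = N0), dilution = 1)),
           duration = duration, sample_times = seq(0, duration, by))
}

# screening-regime mechanistic TOF for a design, with optional product
# preload (used by the non-monotonicity and IC50-invariance properties)
mech_tof <- function(u, v, params, M0 = 10, N0 = 10, T0 = 1, preload = 0,
                     duration = 3 * 3600) {
  net <- build_dimerization_network(design_variant(u, v), params)
  init <- c(ML = M0, T = T0)
  if (preload > 0) init <- c(init, MN = preload)
  prot <- protocol(init, list(list(time = 0, add = c(N = N0), dilution = 1)),
                   duration = duration,
                   sample_times = seq(0, duration, 300))
  tr <- simulate(net, prot)
  estimate_tof(tr$times, tr$conc[, "MN"] + tr$conc[, "TMN"] - preload, T0,
               limiting0 = min(M0, N0))$tof
}

# a trajectory-shaped object holding only the given species (for exact
# render/unmix roundtrips)
toy_trajectory <- function(times, conc_list) {
  conc <- do.call(cbind, conc_list)
  colnames(conc) <- names(conc_list)
  list(times = times, conc = conc)
}
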