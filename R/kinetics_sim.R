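# Deterministic and stochastic integration of reaction networks under an
# experimental protocol (initial mix + timed injections with dilution).

#' Define an experimental protocol
#'
#' @param initial_mix Named numeric vector, species -> concentration (nM),
#'   present before t = 0.
#' @param injections List of injections, each a list with `time` (s),
#'   `add` (named numeric vector of added concentrations, nM, final-volume
#'   basis) and `dilution` (factor in (0, 1] applied to everything already
#'   present; 0.75 mirrors injecting 50 ul into 150 ul).
#' @param duration Total duration (s).
#' @param sample_times Sorted sampling times (s); defaults to every 5 min.
#' @return An object of class `protocol`.
#' @examples
#' protocol(c(ML = 10, T = 1), list(list(time = 0, add = c(N = 10))),
#'          duration = 3600)
#' @export
protocol <- function(initial_mix, injections = list(), duration,
                     sample_times = NULL) {
  if (any(initial_mix < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.null(names(initial_mix)) && length(initial_mix))
    stop("'initial_mix' must be named", call. = FALSE)
  for (inj in injections) {
    if (is.null(inj$time) || inj$time < 0 || inj$time > duration)
      stop("injection times must lie in [0, duration]", call. = FALSE)
    dil <- inj$dilution %||% 1
    if (dil <= 0 || dil > 1)
      stop("dilution factor must be in (0, 1]", call. = FALSE)
    if (!is.null(inj$add) && any(inj$add < 0))
      stop("injected concentrations must be >= 0", call. = FALSE)
  }
  if (is.null(sample_times))
    sample_times <- seq(0, duration, by = min(300, duration / 10))
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("'sample_times' must be strictly increasing", call. = FALSE)
  structure(list(initial_mix = initial_mix, injections = injections,
                 duration = duration, sample_times = sample_times),
            class = "protocol")
}

# ---- shared machinery ----------------------------------------------------

network_matrices <- function(net) {
  sp <- net$species$id
  rx <- net$reactions
  ns <- length(sp); nr <- nrow(rx)
  S <- matrix(0, ns, nr, dimnames = list(sp, rx$id))
  ri <- matrix(-1L, 2L, nr)
  for (j in seq_len(nr)) {
    re <- stats::na.omit(c(rx$r1[j], rx$r2[j]))
    pr <- stats::na.omit(c(rx$p1[j], rx$p2[j], rx$p3[j]))
    for (s in re) S[s, j] <- S[s, j] - 1
    for (s in pr) S[s, j] <- S[s, j] + 1
    ri[seq_along(re), j] <- match(re, sp) - 1L
  }
  list(S = S, ri = ri)
}

initial_state <- function(net, prot) {
  sp <- net$species$id
  unknown <- setdiff(names(prot$initial_mix), sp)
  for (inj in prot$injections)
    unknown <- union(unknown, setdiff(names(inj$add), sp))
  if (length(unknown))
    stop("protocol refers to unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  y0 <- stats::setNames(numeric(length(sp)), sp)
  y0[names(prot$initial_mix)] <- prot$initial_mix
  y0
}

# split [0, duration] into segments separated by injection events
protocol_segments <- function(prot) {
  inj <- prot$injections
  tt <- vapply(inj, `[[`, 0, "time")
  ord <- order(tt)
  list(times = tt[ord], injections = inj[ord])
}

#' Integrate a network deterministically (stiff mass-action ODEs)
#'
#' Solves the mass-action rate equations with an L-stable Rosenbrock 4(3)
#' method and analytic Jacobian; at each injection the present mix is
#' instantaneously diluted and the injected species added, then integration
#' resumes.
#'
#' @param network A `reaction_network`.
#' @param prot A [protocol()].
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-6 nM).
#' @return A `trajectory`: list with `times` (s), `conc` (time x species
#'   matrix, nM) and the `network`.
#' @export
simulate <- function(network, prot, rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(network, "reaction_network"), inherits(prot, "protocol"))
  mats <- network_matrices(network)
  ksim <- network$reactions$k * ifelse(network$reactions$order == 2L, 1e-9, 1)
  y <- initial_state(network, prot)
  seg <- protocol_segments(prot)
  st <- prot$sample_times
  conc <- matrix(NA_real_, length(st), length(y),
                 dimnames = list(NULL, names(y)))
  t_now <- 0
  ev_times <- c(seg$times, Inf)
  # apply any t = 0 injections before integrating
  iev <- 1L
  while (iev <= length(seg$times) && seg$times[iev] <= 0) {
    y <- apply_injection(y, seg$injections[[iev]])
    iev <- iev + 1L
  }
  done <- logical(length(st))
  while (t_now < prot$duration) {
    t_end <- min(ev_times[iev], prot$duration)
    sel <- which(!done & st > t_now - 1e-12 & st <= t_end + 1e-12)
    zero_sel <- which(!done & st <= t_now + 1e-12)
    if (length(zero_sel)) {
      conc[zero_sel, ] <- matrix(y, length(zero_sel), length(y), byrow = TRUE)
      done[zero_sel] <- TRUE
      sel <- setdiff(sel, zero_sel)
    }
    if (length(sel)) {
      res <- cpp_rosenbrock(mats$S, mats$ri, ksim, y, t_now,
                            c(st[sel], t_end), rtol, atol)
      conc[sel, ] <- res[seq_along(sel), , drop = FALSE]
      y <- stats::setNames(res[nrow(res), ], names(y))
      done[sel] <- TRUE
    } else if (t_end > t_now) {
      res <- cpp_rosenbrock(mats$S, mats$ri, ksim, y, t_now, t_end,
                            rtol, atol)
      y <- stats::setNames(res[nrow(res), ], names(y))
    }
    t_now <- t_end
    if (is.finite(ev_times[iev]) && ev_times[iev] <= t_now + 1e-12) {
      y <- apply_injection(y, seg$injections[[iev]])
      iev <- iev + 1L
    }
  }
  tail_sel <- which(!done)
  if (length(tail_sel)) {
    conc[tail_sel, ] <- matrix(y, length(tail_sel), length(y), byrow = TRUE)
  }
  structure(list(times = st, conc = conc, network = network),
            class = "trajectory")
}

apply_injection <- function(y, inj) {
  dil <- inj$dilution %||% 1
  y <- y * dil
  if (!is.null(inj$add)) y[names(inj$add)] <- y[names(inj$add)] + inj$add
  y
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d time points x %d species, t in [%g, %g] s>\n",
              length(x$times), ncol(x$conc), min(x$times), max(x$times)))
  invisible(x)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Converts the protocol to copy numbers in a reaction volume, runs the
#' direct-method SSA (using R's RNG, so results are reproducible under
#' `set.seed()`), and returns concentrations in nM on the protocol's sample
#' grid.
#'
#' @param network A `reaction_network`.
#' @param prot A [protocol()].
#' @param volume Reaction volume in litres (default 1e-14; keeps copy
#'   numbers modest at nM concentrations while staying near the
#'   large-volume limit where the SSA mean tracks the ODE).
#' @param seed Optional integer seed (applied via `set.seed`).
#' @return A `trajectory` (concentration scale, nM).
#' @export
simulate_ssa <- function(network, prot, volume = 1e-14, seed = NULL) {
  stopifnot(inherits(network, "reaction_network"), inherits(prot, "protocol"))
  if (!is.null(seed)) set.seed(seed)
  NA_V <- 6.02214076e23 * volume
  to_copies <- function(c_nM) round(c_nM * 1e-9 * NA_V)
  if (max(to_copies(sum(prot$initial_mix))) > 1e6)
    stop("volume too large: initial copy numbers exceed 1e6", call. = FALSE)
  mats <- network_matrices(network)
  # stochastic rate constants on copy numbers
  cstoch <- ifelse(network$reactions$order == 2L,
                   network$reactions$k / NA_V, network$reactions$k)
  n <- to_copies(initial_state(network, prot))
  seg <- protocol_segments(prot)
  st <- prot$sample_times
  conc <- matrix(NA_real_, length(st), length(n),
                 dimnames = list(NULL, names(n)))
  t_now <- 0; iev <- 1L
  while (iev <= length(seg$times) && seg$times[iev] <= 0) {
    inj <- seg$injections[[iev]]
    n <- round(n * (inj$dilution %||% 1))
    if (!is.null(inj$add))
      n[names(inj$add)] <- n[names(inj$add)] + to_copies(inj$add)
    iev <- iev + 1L
  }
  done <- logical(length(st))
  ev_times <- c(seg$times, Inf)
  repeat {
    t_end <- min(ev_times[iev], prot$duration)
    sel <- which(!done & st <= t_end + 1e-12)
    res <- cpp_ssa(mats$S, mats$ri, cstoch, n, t_now, c(st[sel], t_end))
    if (length(sel)) {
      conc[sel, ] <- res[seq_along(sel), , drop = FALSE]
      done[sel] <- TRUE
    }
    n <- stats::setNames(res[nrow(res), ], names(n))
    t_now <- t_end
    if (t_end >= prot$duration) break
    inj <- seg$injections[[iev]]
    n <- round(n * (inj$dilution %||% 1))
    if (!is.null(inj$add))
      n[names(inj$add)] <- n[names(inj$add)] + to_copies(inj$add)
    iev <- iev + 1L
  }
  conc <- conc / (1e-9 * NA_V)
  structure(list(times = st, conc = conc, network = network),
            class = "trajectory")
}

#' Turnover: products formed per template
#'
#' @param traj A `trajectory`.
#' @param T0 Template concentration (nM, > 0).
#' @param product_species Species counted as product (free + template-bound;
#'   default `c("MN", "TMN")`).
#' @param preload Product concentration present at t = 0 (nM).
#' @return Products formed per template (dimensionless).
#' @export
turnover <- function(traj, T0, product_species = c("MN", "TMN"),
                     preload = 0) {
  if (!is.numeric(T0) || T0 <= 0) stop("'T0' must be > 0", call. = FALSE)
  ps <- intersect(product_species, colnames(traj$conc))
  endp <- sum(traj$conc[nrow(traj$conc), ps])
  (endp - preload) / T0
}

#' Per-strand totals along a trajectory
#'
#' Sums, for every constituent strand, the concentrations of all complexes
#' containing it (with multiplicity). Between injections each total is a
#' conserved quantity of the mass-action dynamics.
#'
#' @param traj A `trajectory`.
#' @return Matrix time x strand (nM).
#' @export
strand_totals <- function(traj) {
  cons <- traj$network$constituents
  strands <- sort(unique(unlist(cons, use.names = FALSE)))
  out <- matrix(0, nrow(traj$conc), length(strands),
                dimnames = list(NULL, strands))
  for (sp in colnames(traj$conc)) {
    for (s in cons[[sp]]) out[, s] <- out[, s] + traj$conc[, sp]
  }
  out
}

#' Write / read a trajectory as long-format CSV
#'
#' Columns `time_s`, `species`, `conc_nM`, at 12 significant digits.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `read_trajectory_csv()` returns a list with `times` and `conc`
#'   (no network attached).
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(
    time_s = rep(traj$times, times = ncol(traj$conc)),
    species = rep(colnames(traj$conc), each = length(traj$times)),
    conc_nM = format(as.vector(traj$conc), digits = 12, scientific = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  times <- sort(unique(df$time_s))
  species <- unique(df$species)
  conc <- matrix(NA_real_, length(times), length(species),
                 dimnames = list(NULL, species))
  for (sp in species) {
    sub <- df[df$species == sp, ]
    conc[match(sub$time_s, times), sp] <- as.numeric(sub$conc_nM)
  }
  list(times = times, conc = conc)
}
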