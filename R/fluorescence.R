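# Forward model from concentrations to multichannel plate-reader signals,
# and the inverse: control-based drift/baseline correction plus
# non-negative least-squares unmixing against a per-species calibration.

FLUOR_CHANNELS <- c("AF488", "AF546", "AF647",
                    "FRET488_546", "FRET488_647", "FRET546_647")

# dye assignment of the labeled strands; locks carry the matching quencher
DYE_OF <- c(M1 = "AF488", M2 = "AF546", M3 = "AF647",
            N1 = "AF647", N2 = "AF546", N3 = NA,
            M = "AF488", N = NA,  # generic single-design system (M1/N3)
            A1 = "AF488", A2 = "AF488", B1 = "AF546", B2 = "AF546",
            C1 = "AF647", C2 = "AF647")
DYE_WAVELENGTH <- c(AF488 = 488, AF546 = 546, AF647 = 647)

#' Construct a calibration matrix
#'
#' @param phi Species x channel matrix of responses (fluorescence units per
#'   nM); rownames are species ids, colnames the channel names.
#' @param baseline Per-channel additive baseline (fluorescence units).
#' @param sigma Per-channel Gaussian noise scale (fluorescence units).
#' @return An object of class `calibration_matrix`.
#' @export
calibration_matrix <- function(phi, baseline = rep(10, ncol(phi)),
                               sigma = rep(1, ncol(phi))) {
  stopifnot(is.matrix(phi), !is.null(rownames(phi)), !is.null(colnames(phi)))
  if (any(phi < 0)) stop("'phi' must be non-negative", call. = FALSE)
  structure(list(phi = phi, channels = colnames(phi),
                 baseline = stats::setNames(baseline, colnames(phi)),
                 sigma = stats::setNames(sigma, colnames(phi))),
            class = "calibration_matrix")
}

#' @export
print.calibration_matrix <- function(x, ...) {
  cat(sprintf("<calibration_matrix: %d species x %d channels>\n",
              nrow(x$phi), length(x$channels)))
  invisible(x)
}

#' Default calibration for a reaction network
#'
#' Encodes the labeling scheme: M1 = AF488 (FQ quencher on its lock),
#' M2 = AF546 (BHQ2), M3 = AF647 (RQ), N1 = AF647, N2 = AF546, N3 dark.
#' Any complex containing both a labeled M strand and its own lock responds
#' at `quench_factor` of the free response. A complex carrying two distinct
#' dyes additionally responds in the corresponding FRET channel with
#' transfer coefficient `fret_coef` taken from the donor (shorter
#' wavelength) dye, whose direct channel is reduced by the same fraction.
#' Unlabeled species (locks, templates, N3-containing-only) get zero rows.
#' Per-strand brightnesses differ (as in real calibrations, where each
#' labelled complex is calibrated individually), which is what lets
#' same-dye-pair complexes such as M2N1 and M3N2 be told apart. Structural
#' degeneracies remain for per-timepoint unmixing: species whose entire
#' response lives in one shared channel (e.g. M2N2 vs its constituent N2,
#' both pure AF546) are scalar multiples of each other and cannot be
#' separated without kinetic information.
#'
#' @param network A `reaction_network` (its constituent multisets determine
#'   each complex's dye content).
#' @param strand_phi Named per-strand response (units per nM of the
#'   unquenched strand).
#' @param fret_coef FRET transfer coefficient (fraction of donor response).
#' @param quench_factor Residual response of a quenched dye.
#' @param baseline,sigma Per-channel baseline and noise scale.
#' @return A `calibration_matrix` with one row per network species.
#' @export
default_calibration <- function(network,
                                strand_phi = c(M1 = 1, M2 = 0.8, M3 = 1.2,
                                               N1 = 1.1, N2 = 0.9, M = 1,
                                               A1 = 1, A2 = 1.05,
                                               B1 = 0.8, B2 = 0.85,
                                               C1 = 1.2, C2 = 1.25),
                                fret_coef = 0.3, quench_factor = 0.02,
                                baseline = rep(10, 6), sigma = rep(1, 6)) {
  sp <- network$species$id
  phi <- matrix(0, length(sp), length(FLUOR_CHANNELS),
                dimnames = list(sp, FLUOR_CHANNELS))
  for (s in sp) {
    cons <- network$constituents[[s]]
    labeled <- list()  # unquenched dyed strands: list of (dye, phi)
    for (strand in cons) {
      dye <- DYE_OF[strand]
      if (is.na(dye) || is.na(strand_phi[strand] %||% NA)) next
      # quenched if the complex also carries this strand's own lock
      lock <- paste0("L", sub("^[A-Z]+", "", strand))
      if (strand %in% c("M", "N")) lock <- "L"
      if (startsWith(strand, "A")) lock <- "LA"
      if (startsWith(strand, "B")) lock <- "LB"
      quenched <- lock %in% cons
      resp <- unname(strand_phi[strand]) *
        if (quenched) quench_factor else 1
      phi[s, dye] <- phi[s, dye] + resp
      if (!quenched)
        labeled <- c(labeled, list(list(dye = unname(dye),
                                        phi = unname(strand_phi[strand]))))
    }
    udyes <- unique(vapply(labeled, `[[`, "", "dye"))
    if (length(labeled) == 2L && length(udyes) == 2L) {
      wl <- DYE_WAVELENGTH[udyes]
      donor_i <- which.min(wl[vapply(labeled, `[[`, "", "dye")])
      donor <- labeled[[donor_i]]
      fret_ch <- sprintf("FRET%d_%d", min(wl), max(wl))
      transfer <- fret_coef * donor$phi
      phi[s, fret_ch] <- phi[s, fret_ch] + transfer
      phi[s, donor$dye] <- phi[s, donor$dye] - transfer
    }
  }
  calibration_matrix(phi, baseline, sigma)
}

#' Render a trajectory as a multichannel plate read
#'
#' Forward model: `signal_c(t) = drift(t) * (baseline_c +
#' sum_s phi[s, c] * conc_s(t)) + N(0, sigma_c^2)`. A negative-control
#' (buffer) well and a positive-control well at fixed concentrations are
#' rendered alongside the sample well(s); extra constant-concentration
#' wells (e.g. annealed-product controls) can be added.
#'
#' @param traj A `trajectory` (or a list with `times` and `conc` matrix).
#' @param calib A `calibration_matrix`; every species in `traj` must have a
#'   calibration row.
#' @param drift A function of time (s) returning the multiplicative drift
#'   (default: none, identically 1). Drift is referenced to t = 0
#'   (`drift(0) = 1`), matching the control-based correction, which
#'   rescales every channel to its t = 0 response.
#' @param noise Logical; add Gaussian channel noise (default `TRUE`).
#' @param seed Optional integer seed; fixed seed gives bitwise-identical
#'   noise.
#' @param positive_control Named concentration vector for the positive
#'   control well; defaults to 50 nM of the brightest calibrated species.
#' @param extra_wells Named list of constant-concentration wells
#'   (name -> named concentration vector); rendered with role "sample"
#'   unless the name starts with "pos" or "neg".
#' @param well_id Id for the trajectory's own well.
#' @return A `plate_read`: list(times, wells (data.frame id, role),
#'   signal (well x channel x time array)).
#' @export
render_fluorescence <- function(traj, calib, drift = NULL, noise = TRUE,
                                seed = NULL, positive_control = NULL,
                                extra_wells = list(), well_id = "sample1") {
  stopifnot(inherits(calib, "calibration_matrix"))
  missing_sp <- setdiff(colnames(traj$conc), rownames(calib$phi))
  if (length(missing_sp))
    stop("no calibration row for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  if (is.null(drift)) drift <- function(t) rep(1, length(t))
  if (!is.null(seed)) set.seed(seed)
  times <- traj$times
  dr <- drift(times)
  if (is.null(positive_control)) {
    bright <- rownames(calib$phi)[which.max(rowSums(calib$phi))]
    positive_control <- stats::setNames(50, bright)
  }
  wells <- list()
  wells[[well_id]] <- list(role = "sample", conc = traj$conc)
  const_conc <- function(v) {
    m <- matrix(0, length(times), nrow(calib$phi),
                dimnames = list(NULL, rownames(calib$phi)))
    m[, names(v)] <- matrix(v, length(times), length(v), byrow = TRUE)
    m
  }
  wells[["pos1"]] <- list(role = "positive", conc = const_conc(positive_control))
  wells[["neg1"]] <- list(role = "negative",
                          conc = matrix(0, length(times), nrow(calib$phi),
                                        dimnames = list(NULL, rownames(calib$phi))))
  for (nm in names(extra_wells)) {
    role <- if (startsWith(nm, "pos")) "positive"
            else if (startsWith(nm, "neg")) "negative" else "sample"
    wells[[nm]] <- list(role = role, conc = const_conc(extra_wells[[nm]]))
  }
  render_plate(times, wells, calib, dr, noise)
}

# shared renderer: wells is a named list of list(role, conc matrix); the
# drift vector `dr` is already evaluated on `times`. Consumes the current
# RNG stream when noise = TRUE.
render_plate <- function(times, wells, calib, dr, noise) {
  nw <- length(wells); nc <- length(calib$channels); nt <- length(times)
  signal <- array(0, dim = c(nw, nc, nt),
                  dimnames = list(names(wells), calib$channels, NULL))
  for (i in seq_len(nw)) {
    conc <- wells[[i]]$conc
    clean <- conc[, rownames(calib$phi), drop = FALSE] %*% calib$phi
    clean <- sweep(clean, 2L, calib$baseline, `+`)
    clean <- clean * dr
    if (noise)
      clean <- clean + matrix(stats::rnorm(nt * nc), nt, nc) *
        rep(calib$sigma, each = nt)
    signal[i, , ] <- t(clean)
  }
  structure(list(times = times,
                 wells = data.frame(id = names(wells),
                                    role = vapply(wells, `[[`, "", "role"),
                                    stringsAsFactors = FALSE),
                 signal = signal, channels = calib$channels,
                 corrected = FALSE),
            class = "plate_read")
}

#' @export
print.plate_read <- function(x, ...) {
  cat(sprintf("<plate_read%s: %d wells x %d channels x %d times>\n",
              if (isTRUE(x$corrected)) " (corrected)" else "",
              nrow(x$wells), length(x$channels), length(x$times)))
  invisible(x)
}

#' Correct a plate read with its positive and negative controls
#'
#' Per channel and time point,
#' `corrected = (raw - neg(t)) * (pos(0) - neg(0)) / (pos(t) - neg(t))`,
#' which removes the shared multiplicative drift and the additive baseline
#' exactly (controls are averaged over wells of each role). Channels in
#' which the positive control does not respond above `min_response` at
#' t = 0 only get the additive correction `raw - neg(t)` (there is no
#' drift reference there). If no channel responds, or the pos/neg
#' difference collapses at a later time, a degenerate-controls error is
#' raised. Control wells pass through unchanged as diagnostics.
#'
#' @param plate A `plate_read`.
#' @param min_response Floor on |pos(0) - neg(0)| below which a channel is
#'   deemed unreferenced (default 1e-8). The effective threshold also
#'   adapts to the channel noise, estimated from the temporal increments
#'   of the negative control.
#' @return A corrected `plate_read`.
#' @export
correct_controls <- function(plate, min_response = 1e-8) {
  stopifnot(inherits(plate, "plate_read"))
  posw <- which(plate$wells$role == "positive")
  negw <- which(plate$wells$role == "negative")
  if (!length(posw) || !length(negw))
    stop("plate must contain positive and negative control wells",
         call. = FALSE)
  nt <- length(plate$times)
  pos <- apply(plate$signal[posw, , , drop = FALSE], c(2, 3), mean)
  neg <- apply(plate$signal[negw, , , drop = FALSE], c(2, 3), mean)
  d0 <- pos[, 1L] - neg[, 1L]
  # per-channel noise floor from negative-control increments
  noise <- if (nt >= 3L)
    apply(neg, 1L, function(v) stats::mad(diff(v)) / sqrt(2)) else
      rep(0, length(d0))
  responsive <- abs(d0) > pmax(min_response, 8 * noise)
  if (!any(responsive))
    stop("degenerate controls: positive and negative controls coincide",
         call. = FALSE)
  d <- pos - neg
  # sustained collapse of the pos-neg difference (drift reference lost)
  dsm <- t(apply(d, 1L, function(v)
    if (length(v) >= 5L) stats::runmed(v, 5L) else v))
  bad <- responsive & (apply(abs(dsm), 1L, min) < 0.05 * abs(d0))
  if (any(bad))
    stop("degenerate controls: pos(t) ~ neg(t) in channel(s) ",
         paste(plate$channels[bad], collapse = ", "), call. = FALSE)
  out <- plate
  for (i in which(plate$wells$role == "sample")) {
    raw <- plate$signal[i, , ]
    cor <- raw - neg
    for (c_ in which(responsive)) cor[c_, ] <- cor[c_, ] * d0[c_] / d[c_, ]
    out$signal[i, , ] <- cor
  }
  out$corrected <- TRUE
  out
}

## ---- non-negative least squares (Lawson-Hanson active set) --------------

nnls_solve <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(n)
      z[passive] <- drop(qr.coef(qr(Ap), b))
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Unmix a corrected plate read into species concentrations
#'
#' Per time point, solves the non-negative least-squares problem
#' `min ||signal - phi^T conc||, conc >= 0` over the requested species.
#' Before solving, species whose calibration columns are (numerically)
#' collinear with the others are flagged unidentifiable and excluded: while
#' the condition number of the calibration submatrix exceeds `cond_max`,
#' the species whose column is best explained by the remaining columns is
#' dropped (ties broken by dropping later-listed species, so products are
#' dropped before their constituent monomers under the default ordering).
#' The flag depends only on the calibration, never on the data.
#'
#' @param plate A corrected `plate_read` (see [correct_controls()]).
#' @param calib The `calibration_matrix` used to render it.
#' @param species Character vector of species to estimate.
#' @param wells Sample well ids to use (default: all sample wells);
#'   corrected signals are averaged across them before unmixing.
#' @param cond_max Condition-number threshold for identifiability (1e6).
#' @return An `unmix_result`: list(times, conc (time x species, NA columns
#'   for flagged species), residual (per time), unidentifiable (character)).
#' @export
unmix <- function(plate, calib, species, wells = NULL, cond_max = 1e6) {
  stopifnot(inherits(plate, "plate_read"), inherits(calib, "calibration_matrix"))
  if (!isTRUE(plate$corrected))
    warning("unmixing an uncorrected plate read")
  if (!identical(plate$channels, calib$channels))
    stop("plate channels do not match calibration channels", call. = FALSE)
  missing_sp <- setdiff(species, rownames(calib$phi))
  if (length(missing_sp))
    stop("no calibration row for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  flagged <- unidentifiable_species(calib, species, cond_max)
  keep <- setdiff(species, flagged)
  if (!length(keep))
    stop("calibration is rank deficient: no resolvable species in subset",
         call. = FALSE)
  if (is.null(wells)) wells <- plate$wells$id[plate$wells$role == "sample"]
  widx <- match(wells, plate$wells$id)
  if (anyNA(widx)) stop("unknown well id(s)", call. = FALSE)
  sig <- apply(plate$signal[widx, , , drop = FALSE], c(2, 3), mean)
  A <- t(calib$phi[keep, , drop = FALSE])  # channels x species
  nt <- length(plate$times)
  conc <- matrix(NA_real_, nt, length(species),
                 dimnames = list(NULL, species))
  resid <- numeric(nt)
  for (ti in seq_len(nt)) {
    b <- sig[, ti]
    x <- nnls_solve(A, b)
    conc[ti, keep] <- x
    resid[ti] <- sqrt(sum((b - A %*% x)^2))
  }
  structure(list(times = plate$times, conc = conc, residual = resid,
                 unidentifiable = flagged),
            class = "unmix_result")
}

#' Which species of a calibration subset are unidentifiable?
#'
#' Pure function of the calibration matrix (see [unmix()]).
#'
#' @inheritParams unmix
#' @return Character vector of flagged species (possibly empty).
#' @export
unidentifiable_species <- function(calib, species, cond_max = 1e6) {
  phi <- t(calib$phi[species, , drop = FALSE])
  flagged <- character()
  keep <- species
  repeat {
    A <- phi[, keep, drop = FALSE]
    # all-zero columns can never be resolved
    zero <- colSums(abs(A)) == 0
    if (any(zero)) {
      flagged <- c(flagged, keep[zero])
      keep <- keep[!zero]
      next
    }
    if (length(keep) <= 1L) break
    sv <- svd(A, nu = 0, nv = 0)$d
    if (sv[length(sv)] > 0 && sv[1L] / sv[length(sv)] <= cond_max) break
    # drop the column best explained by the others (largest R^2);
    # ties go to the later-listed species
    r2 <- vapply(seq_along(keep), function(j) {
      others <- A[, -j, drop = FALSE]
      fit <- qr.fitted(qr(others), A[, j])
      1 - sum((A[, j] - fit)^2) / max(sum(A[, j]^2), 1e-300)
    }, numeric(1L))
    j <- max(which(r2 >= max(r2) - 1e-12))
    flagged <- c(flagged, keep[j])
    keep <- keep[-j]
  }
  flagged
}

#' Write / read a plate read as long-format CSV
#'
#' Columns `time_s`, `well`, `channel`, `value`.
#'
#' @param plate A `plate_read`.
#' @param path File path.
#' @export
write_plate_csv <- function(plate, path) {
  nt <- length(plate$times)
  df <- expand.grid(time_i = seq_len(nt), channel = plate$channels,
                    well = plate$wells$id, stringsAsFactors = FALSE)
  df$value <- format(as.vector(aperm(plate$signal, c(3, 2, 1))),
                     digits = 12, scientific = TRUE)
  df$time_s <- plate$times[df$time_i]
  utils::write.csv(df[, c("time_s", "well", "channel", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a calibration matrix as long-format CSV
#'
#' Columns `species`, `channel`, `phi`; baselines and sigmas are stored as
#' pseudo-species rows `.baseline` and `.sigma`.
#'
#' @param calib A `calibration_matrix`.
#' @param path File path.
#' @export
write_calibration_csv <- function(calib, path) {
  long <- expand.grid(species = rownames(calib$phi),
                      channel = calib$channels, stringsAsFactors = FALSE)
  long$phi <- as.vector(calib$phi)
  extra <- data.frame(
    species = rep(c(".baseline", ".sigma"), each = length(calib$channels)),
    channel = rep(calib$channels, 2L),
    phi = c(unname(calib$baseline), unname(calib$sigma)))
  utils::write.csv(rbind(long, extra), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- df$species %in% c(".baseline", ".sigma")
  body <- df[!meta, ]
  sp <- unique(body$species); ch <- unique(body$channel)
  phi <- matrix(0, length(sp), length(ch), dimnames = list(sp, ch))
  phi[cbind(body$species, body$channel)] <- body$phi
  base <- df[df$species == ".baseline", ]
  sig <- df[df$species == ".sigma", ]
  calibration_matrix(phi,
                     baseline = base$phi[match(ch, base$channel)],
                     sigma = sig$phi[match(ch, sig$channel)])
}
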