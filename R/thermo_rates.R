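# Free-energy bookkeeping and rate-constant models at the domain level.
# Energies are in units of kBT at a fixed 25 C; lengths in nucleotides;
# bimolecular rate constants in M^-1 s^-1, unimolecular in s^-1.

#' Define a toehold/handhold design variant
#'
#' A design variant fixes the domain lengths of one templated-dimerization
#' system: the primary toehold length `u` on the M monomer, the handhold
#' length `v` on the N monomer, the short secondary toehold `s` revealed by
#' the first (toehold-exchange) displacement step, the number of programmed
#' mismatches in the locked M duplex, and whether edge clamps are present.
#' The conventional display name is `"{u}t/{v}h"`, e.g. `"6t/8h"`.
#'
#' @param u Primary toehold length (nt, integer >= 0).
#' @param v Handhold length (nt, integer >= 0).
#' @param s Secondary toehold length (nt, default 2).
#' @param n_mm Number of programmed mismatches in the M-lock duplex
#'   (default 2; one is eliminated per displacement step).
#' @param clamps Logical; edge clamps on the M-lock duplex (default `TRUE`).
#' @param label Display name; derived as `"{u}t/{v}h"` when omitted.
#' @return An object of class `design_variant`.
#' @examples
#' design_variant(6, 8)
#' @export
design_variant <- function(u, v, s = 2L, n_mm = 2L, clamps = TRUE,
                           label = NULL) {
  for (nm in c("u", "v", "s", "n_mm")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  if (is.null(label)) label <- sprintf("%dt/%dh", as.integer(u), as.integer(v))
  structure(list(u = as.integer(u), v = as.integer(v), s = as.integer(s),
                 n_mm = as.integer(n_mm), clamps = isTRUE(clamps),
                 label = label),
            class = "design_variant")
}

#' @export
print.design_variant <- function(x, ...) {
  cat(sprintf("<design_variant %s: u=%d v=%d s=%d n_mm=%d clamps=%s>\n",
              x$label, x$u, x$v, x$s, x$n_mm, x$clamps))
  invisible(x)
}

#' Rate and free-energy parameters
#'
#' Collects every tunable of the kinetic/thermodynamic model. Displacement
#' rate laws are exponential-with-cap phenomenologies; duplex free energies
#' are a lengths-only model (per-nt term + initiation penalty + mismatch
#' destabilization), deliberately ignoring nearest-neighbour sequence detail.
#'
#' @param k_on Duplex association rate constant (M^-1 s^-1).
#' @param k_max_tmsd Plateau toehold-mediated displacement rate (M^-1 s^-1).
#' @param k0_toe Zero-toehold displacement rate (M^-1 s^-1); anchored to the
#'   measured template-free leak, 0.32 M^-1 s^-1.
#' @param b_toe Fold acceleration of displacement per toehold nucleotide.
#' @param n_star Toehold length at which the TMSD rate plateaus (nt).
#' @param k_max_hmsd Plateau handhold-mediated displacement rate (M^-1 s^-1).
#' @param v_star Handhold length at which the HMSD rate plateaus (nt).
#' @param dG_nt Hybridization free energy per nucleotide (kBT, negative).
#' @param dG_init Duplex initiation penalty (kBT, positive).
#' @param ddG_mm Destabilization per programmed mismatch (kBT, ~ +9).
#' @param dG_coop Penalty for simultaneous toehold+handhold binding of the
#'   product to the template (loop closure; kBT).
#' @param dG_clamp Clamp contribution to the first displacement step (kBT;
#'   used only when a design has clamps).
#' @param k_leak Template-free dimerization (leak) rate (M^-1 s^-1).
#' @param temperature_C Temperature (deg C); energies are in kBT at this T.
#' @param C0 Reference concentration (M) for standard-state bookkeeping.
#' @return An object of class `rate_params`.
#' @examples
#' p <- rate_params()
#' rate_tmsd(6, p)
#' @export
rate_params <- function(k_on = 3e6, k_max_tmsd = 3e6, k0_toe = 0.32,
                        b_toe = 15, n_star = 6L, k_max_hmsd = 1e6,
                        v_star = 8L, dG_nt = -2.5, dG_init = 3,
                        ddG_mm = 9, dG_coop = 2, dG_clamp = -4,
                        k_leak = 0.32, temperature_C = 25, C0 = 1) {
  p <- list(k_on = k_on, k_max_tmsd = k_max_tmsd, k0_toe = k0_toe,
            b_toe = b_toe, n_star = as.integer(n_star),
            k_max_hmsd = k_max_hmsd, v_star = as.integer(v_star),
            dG_nt = dG_nt, dG_init = dG_init, ddG_mm = ddG_mm,
            dG_coop = dG_coop, dG_clamp = dG_clamp, k_leak = k_leak,
            temperature_C = temperature_C, C0 = C0)
  rates <- c("k_on", "k_max_tmsd", "k0_toe", "b_toe", "k_max_hmsd", "k_leak")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be > 0", call. = FALSE)
  if (p$dG_nt >= 0) stop("'dG_nt' must be negative", call. = FALSE)
  if (p$ddG_mm <= 0) stop("'ddG_mm' must be positive", call. = FALSE)
  if (p$k0_toe > p$k_max_tmsd)
    stop("'k0_toe' must not exceed 'k_max_tmsd'", call. = FALSE)
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Duplex hybridization free energy (lengths-only model)
#'
#' `n_nt * dG_nt + dG_init + n_mismatch * ddG_mm` for `n_nt >= 1`; an empty
#' duplex (`n_nt = 0`) has zero free energy by convention. Additive:
#' `duplex_dG(a + b) = duplex_dG(a) + duplex_dG(b) - dG_init` for a, b >= 1.
#'
#' @param n_nt Duplex length (nt, >= 0).
#' @param params A [rate_params()] object.
#' @param n_mismatch Number of mismatches carried by the duplex (>= 0).
#' @return Free energy in kBT (negative = stable).
#' @export
duplex_dG <- function(n_nt, params = rate_params(), n_mismatch = 0) {
  if (any(n_nt < 0)) stop("'n_nt' must be >= 0", call. = FALSE)
  if (any(n_mismatch < 0)) stop("'n_mismatch' must be >= 0", call. = FALSE)
  ifelse(n_nt == 0, 0,
         n_nt * params$dG_nt + params$dG_init + n_mismatch * params$ddG_mm)
}

#' Toehold-mediated strand-displacement rate constant
#'
#' Exponential acceleration with toehold length, capped at a plateau:
#' `min(k_max_tmsd, k0_toe * b_toe^n)`. With the default parameters the
#' zero-toehold rate equals the measured leak (0.32 M^-1 s^-1) and the cap
#' engages at n = 6, reproducing the plateau observed at ~6-7 nt.
#'
#' @param n_toehold Toehold length (nt, >= 0); vectorized.
#' @param params A [rate_params()] object.
#' @return Bimolecular rate constant (M^-1 s^-1).
#' @export
rate_tmsd <- function(n_toehold, params = rate_params()) {
  if (any(n_toehold < 0)) stop("'n_toehold' must be >= 0", call. = FALSE)
  pmin(params$k_max_tmsd, params$k0_toe * params$b_toe^n_toehold)
}

#' Handhold-mediated strand-displacement rate constant
#'
#' Same exponential-with-plateau phenomenology as [rate_tmsd()], anchored at
#' the plateau: `k_max_hmsd * b_toe^(v - v_star)` capped above at
#' `k_max_hmsd` and floored below at `k_leak` (a zero-length handhold gives
#' no recognition and reduces to toehold-free displacement).
#'
#' @param n_handhold Handhold length (nt, >= 0); vectorized.
#' @param params A [rate_params()] object.
#' @return Bimolecular rate constant (M^-1 s^-1).
#' @export
rate_hmsd <- function(n_handhold, params = rate_params()) {
  if (any(n_handhold < 0)) stop("'n_handhold' must be >= 0", call. = FALSE)
  pmin(params$k_max_hmsd,
       pmax(params$k_leak,
            params$k_max_hmsd * params$b_toe^(n_handhold - params$v_star)))
}

#' Dissociation rate of the template-product complex
#'
#' The released dimer can rebind the template cooperatively through both its
#' toehold and handhold; the complex dissociates at
#' `koff = k_on * C0 * exp(duplex_dG(u) + duplex_dG(v) + dG_coop)`,
#' so that the paired `kon = k_on` gives `Kd = C0 * exp(dG_bind)`.
#' Strictly decreasing in both u and v: longer recognition domains mean
#' stronger product inhibition.
#'
#' @param design A [design_variant()].
#' @param params A [rate_params()] object.
#' @return Unimolecular dissociation rate (s^-1).
#' @export
product_off_rate <- function(design, params = rate_params()) {
  stopifnot(inherits(design, "design_variant"))
  dG <- product_binding_dG(design, params)
  params$k_on * params$C0 * exp(dG)
}

# Standard-state binding free energy of product to template (kBT).
product_binding_dG <- function(design, params) {
  duplex_dG(design$u, params) + duplex_dG(design$v, params) + params$dG_coop
}

# Reaction free energy of the toehold-exchange step ML + T -> MT + L (kBT).
# Gains the primary toehold, loses the secondary toehold, eliminates one
# programmed mismatch, and pays/releases the clamp term when clamps are on.
tmsd_exchange_dG <- function(design, params) {
  -(duplex_dG(design$u, params) - duplex_dG(design$s, params)) -
    (if (design$n_mm > 0) params$ddG_mm else 0) +
    (if (design$clamps) params$dG_clamp else 0)
}

## ---- YAML serialization -------------------------------------------------

#' Read/write design variants and rate parameters as YAML
#'
#' Flat YAML mappings; `write_params_yaml()` stores a `rate_params` (and
#' optionally the design it was calibrated for), `read_params_yaml()`
#' restores it. Files `params/default.yaml`, `params/6t8h.yaml`,
#' `params/6t9h.yaml` and `params/6t10h.yaml` ship with the package under
#' `system.file("params", package = "hmsdcat")`.
#'
#' @param params A [rate_params()] object.
#' @param path File path.
#' @param design Optional [design_variant()] stored alongside.
#' @return `read_params_yaml()` returns a list with elements `params` and
#'   (if present in the file) `design`.
#' @export
write_params_yaml <- function(params, path, design = NULL) {
  stopifnot(inherits(params, "rate_params"))
  out <- list(params = unclass(params))
  if (!is.null(design)) out$design <- unclass(design)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop("no such params file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$params)) stop("params file lacks a 'params' mapping",
                                call. = FALSE)
  out <- list(params = do.call(rate_params, raw$params))
  if (!is.null(raw$design)) {
    d <- raw$design
    out$design <- design_variant(d$u, d$v, s = d$s %||% 2L,
                                 n_mm = d$n_mm %||% 2L,
                                 clamps = d$clamps %||% TRUE,
                                 label = d$label)
  }
  out
}

#' Load a shipped parameter set
#'
#' @param name One of `"default"`, `"6t8h"`, `"6t9h"`, `"6t10h"`.
#' @return As [read_params_yaml()].
#' @export
shipped_params <- function(name = "6t8h") {
  path <- system.file("params", paste0(name, ".yaml"), package = "hmsdcat")
  if (!nzchar(path)) stop("no shipped parameter set '", name, "'",
                          call. = FALSE)
  read_params_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
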