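---
title: "Models and methods behind hmsdcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hmsdcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmsdcat)
```

# The system

hmsdcat models an enzyme-free catalytic templating cycle built from DNA
strand displacement. A locked monomer `M·L` carries a hidden dimerization
domain (sequestered by the quencher-bearing lock `L`, with two programmed
mismatches and edge clamps), a template `T` carries the complements of
`M`'s primary toehold (u nt) and of `N`'s handhold (v nt), and a free
monomer `N` finishes the cycle:

1. **Toehold exchange (TMSD).** `M·L + T -> M·T + L`. The template invades
   through the u-nt toehold and strips the lock, eliminating one mismatch
   and exposing a short (s = 2 nt) secondary toehold. The step is
   reversible: the lock can re-invade through the secondary toehold.
2. **Handhold-mediated displacement (HMSD).** `M·T + N -> M·N + T`. `N`
   binds `M`'s exposed handhold-complement region on the template complex,
   displaces the template from the dimerization domain, eliminates the
   second mismatch, and the product dimer detaches, regenerating the
   template. Treated as irreversible: product release plus mismatch
   elimination makes the reverse flux negligible.
3. **Product inhibition.** `M·N + T <-> T·MN`. The released dimer can
   rebind the template cooperatively through both recognition domains;
   this competitive rebinding is the sole inhibition channel.
4. **Leak.** `M·L + N -> M·N + L`, second-order, toehold-free; the clamps
   keep it slow.
5. **Template sequestration (optional, default on).** `T + N <-> T·N`
   through the handhold alone. It only matters when `[N]` approaches the
   `T·N` dissociation constant (it does at v = 9-10).
6. **Product interconversion (optional, default off).** A slow
   `M·N + T -> M·T + N` stripping channel through which an empty template
   can exchange the N identity of a product; rate `1e-3 * k_on`.

All reactions are elementary, lumped, mass-action steps: no explicit
branch-migration intermediates, consistent with treating TMSD/HMSD as
effective bimolecular reactions.

# Free energies and rate laws

Energies are in units of kBT at 25 °C, at the domain level only (no
nearest-neighbour sequence dependence): a duplex of n nt contributes
`n * dG_nt + dG_init` (defaults −2.5 kBT/nt, +3 kBT initiation), each
programmed mismatch destabilizes by `ddG_mm = +9` kBT, clamps contribute
`dG_clamp = −4` kBT to the locked state, and simultaneous two-domain
binding of product to template pays a loop-closure penalty
`dG_coop` (+2 kBT uncalibrated).

Displacement rates are exponential-with-plateau phenomenologies:

* TMSD: `k(u) = min(k_max_tmsd, k0_toe * b_toe^u)`. With defaults the
  zero-toehold rate equals the measured leak (0.32 M⁻¹ s⁻¹) and the cap
  (3×10⁶ M⁻¹ s⁻¹) engages at u = 6, reproducing the known plateau at ~6-7
  nt.
* HMSD: `k(v) = min(k_max_hmsd, max(k_leak, k_max_hmsd * b_toe^(v - v_star)))`
  — the same exponential shape anchored at its plateau (v_star = 8),
  floored at the leak rate for a vanishing handhold.

Reversible steps get their reverse rate from thermodynamic consistency,
`ln(kf/kr · C0^(Δorder)) = −ΔG/kBT` with C0 = 1 M, and every builder is
checked programmatically for strand-multiset conservation and detailed
balance (tolerance 1e−12 relative). The toehold-exchange reaction free
energy is `−[dG(u) − dG(s)] − ddG_mm + dG_clamp` (−3 kBT at 6t/8h
defaults: mildly forward-driven by the mismatch), and product binding is
`dG(u) + dG(v) + dG_coop`. One consequence of the initiation penalty is
that `product_off_rate` is strictly decreasing per added nucleotide only
from length 1 upward; the 0→1 step can be slightly uphill.

Cross-interactions in the nine-template competition network follow one
rule: a mismatched recognition domain is a zero-length domain, so every
cross channel falls to the toehold-free rate. Orthogonality of the
recognition sequences is a design assumption, not a fitted quantity.

# Calibration of the 6t/8h parameter set

With uncalibrated defaults the lumped cycle is far faster than the real
system (displacement caps of 10⁶–3×10⁶ M⁻¹ s⁻¹ give initial TOFs of
hundreds per hour), because the effective rate of toehold *exchange*
against a thermodynamically nearly-balanced lock is much lower than the
plateau rate of simple TMSD. Rather than introduce mechanism we do not
model, `tools/calibrate_6t8h.R` least-squares tunes three knobs —
`b_toe`, `k_max_hmsd`, `dG_coop` — on log scale against the three published
readouts (screening TOF 0.622 h⁻¹ at 1 nM template / 10 nM monomers;
IC50 11 nM in that regime; 100 nM-regime TOF 3.6 h⁻¹) and freezes the
result in `inst/params/6t8h.yaml` (b_toe ≈ 9.1, k_max_hmsd ≈ 1.9×10⁴
M⁻¹ s⁻¹, dG_coop ≈ +9.4 kBT). Because the cycle is bimolecular in both
monomers, the two TOF targets are linearly coupled (TOF_100 ≈ 10 ×
TOF_screen), so the optimum splits their residuals (≈0.49 and ≈4.6 h⁻¹)
while matching IC50 essentially exactly. The calibrated set drives every
mechanistic scenario: turnover (≥20 products per template at a 1:400
template:monomer ratio), the interior TOF optimum in handhold length at
u = 6 (v = 8-9 beats v = 10, where product rebinding and `T·N`
sequestration bite), IC50 invariance across template concentration, and
nine-template specificity above 80 % correct product.

# Kinetics integration

Networks are integrated in seconds/nM units by a 4th-order, L-stable
Rosenbrock method (Kaps–Rentrop, Shampine coefficients) with analytic
mass-action Jacobians, implemented in C++ (deSolve is not available in
the target environment). Default tolerances are rtol = 1e−8,
atol = 1e−6 nM; the leak-only system agrees with the integrated
second-order law to ~1e−15 relative. Injections are instantaneous: all
present species are diluted by the protocol's dilution factor (0.75 for
50 µl into 150 µl), then the injected species are added; drift of
conserved strand totals stays below 1e−6 relative over 40 h. A
Gillespie direct-method SSA (also C++, driven by R's RNG so `set.seed`
gives bitwise reproducibility) serves as an independent stochastic
oracle; at the default 10 fL volume its 150-200-run mean tracks the ODE
within 3 standard errors. Much smaller volumes reveal genuine
finite-copy-number deviations from the ODE and are not a solver
discrepancy.

# Fluorescence model and unmixing

The forward model is
`signal_c(t) = drift(t) · (baseline_c + Σ_s φ[s,c]·conc_s(t)) + N(0, σ_c²)`
over six channels (AF488, AF546, AF647 and the three FRET pairs). The
default calibration encodes the labelling scheme (M1 = AF488 + FQ on its
lock, M2 = AF546 + BHQ2, M3 = AF647 + RQ, N1 = AF647, N2 = AF546, N3
dark), with quenched complexes at 2 % response, per-strand brightnesses
(as in real per-complex calibrations), and a FRET transfer coefficient of
0.3 diverted from the donor channel of two-dye complexes.

Correction uses both controls per channel and time:
`corrected = (raw − neg(t)) · (pos(0) − neg(0)) / (pos(t) − neg(t))`,
which removes the additive baseline and the shared multiplicative drift
exactly; drift is by convention referenced to t = 0. Channels where the
positive control does not respond above the (noise-adaptive) threshold
receive the additive correction only; a sustained collapse of the
pos–neg difference raises a degenerate-controls error. Note the
reference uses `pos(0) − neg(0)`, not bare `pos(0)`: with a nonzero
baseline only the differenced form makes the correction an exact inverse
of the forward model.

Unmixing solves, per time point, non-negative least squares against the
calibration submatrix of the requested species (Lawson–Hanson active
set; the matrices are 6 × ≤6). Identifiability is decided from the
calibration alone: while the submatrix condition number exceeds 1e6, the
species whose column is best explained by the others is dropped and
flagged (ties drop later-listed species, so products drop before their
constituent monomers). The M2·N2 dimer — pure AF546, a scalar multiple
of its constituent N2 — is the canonical flagged case. Per-timepoint
unmixing cannot rescue such degeneracies without kinetic information, so
6-channel data can resolve at most six species at a time and subsets
must be chosen per experiment; no temporal smoothing is applied.

# Estimators

* **Initial rate**: window `[0, t*]`, `t*` = first crossing of 10 %
  conversion of the limiting species (fallback: first 2 h; minimum 5
  points), then OLS of `a + b·t + c·t²` with `b` reported. The quadratic
  term matters: a straight-line fit over a 10 %-conversion window is
  biased low by ~conversion/2 (≈5 %), while the quadratic's linear
  coefficient is exact on lines and accurate to well under 3 % on
  saturating curves. 95 % CIs are 1.96 × the coefficient SE.
* **TOF** = initial rate / T0, in h⁻¹, CI propagated linearly.
* **IC50**: weighted NLS of the single-site competitive form
  `TOF(P0) = tof0 / (1 + P0/ic50)` (not a 4PL — the inhibition is
  mechanistically strictly competitive). A flat dose-response (span
  < 15 %) or an optimum pushed far beyond the probed range reports
  `converged = FALSE` with a lower bound instead of a point estimate.
* **Leak**: NLS of the integrated second-order law (equal and unequal
  initial-concentration branches), k in M⁻¹ s⁻¹.
* **TOF linearity**: inverse-variance-weighted regression of initial
  rate on template concentration; the slope is the regime TOF, the
  intercept the untemplated background (`k_leak·A0·B0` ≈ 0.0115 nM/h at
  100 nM).

# The synthetic-data world

Two generator modes deliberately coexist:

* **Phenomenological** curves integrate
  `dP/dt = tof·T0·(1 − P/p_max)/(1 + (P + preload)/ic50) + k_leak(A0−P)(B0−P)`
  (exact implicit solution when the leak is off; RK4 on a fine sub-grid
  otherwise) and carry their ground truth directly from the published
  values: screening TOFs 0.622 / 1.01 h⁻¹, IC50s 11 / 4 / 2 nM, regime
  TOF 3.6 h⁻¹, leak 0.32 M⁻¹ s⁻¹. This keeps estimator-recovery
  acceptance independent of the emergent mechanistic calibration.
  Screening fixtures use `ic50 = Inf`: the published TOF already
  summarizes whatever inhibition those wells experienced, and the
  fixture's sole job is to carry that initial slope. The turnover series
  uses `ic50 = 100 nM`, following the observation that IC50 stays
  comparable to the monomer concentration in the 100 nM regime. The
  6t/10h screening TOF (0.40 h⁻¹) has no published value and is an invented
  value consistent with the reported decline above 9 nt. Noise is 1 % CV
  multiplicative (published noise magnitudes are not available),
  sampling every 5 min, 3 replicates, all seeds derived deterministically
  from one master seed, and every fixture regenerates bit-identically
  from its manifest.
* **Mechanistic** scenarios run the calibrated competition network at the
  published concentrations (5 nM template, 100 nM each locked M, 75 nM
  each N injected at t = 0 with 0.75 dilution; ten sample wells, nine
  annealed-dimer positive controls at 75 nM, one buffer blank).

What a green test does establish: the estimators recover the quantities
the generators encode, at the stated noise, and the mechanistic model
reproduces the published orderings and bounds. What it does not: the
generators do not emulate pipetting error, photobleaching, instrument
gain drift beyond the smooth multiplicative model, gel electrophoresis,
or the authors' exact (unpublished) fitting procedures; and the measured
2.45-bit mutual information is not reproducible without their per-pair
product distribution, so it is not asserted anywhere.

# Information metrics

Product distributions condition on product formation (unreacted material
is excluded; rows below a minimum total are rejected). Accuracy is the
matched diagonal in percent. Mutual information is the plug-in estimator
`I = Σ_t π_t Σ_p P(p|t) log2[P(p|t)/Σ_t' π_t' P(p|t')]` with `0·log 0 = 0`
and a uniform template prior by default; perfect 9-way copying gives
log2 9 ≈ 3.17 bits. Property tests cover the bounds, label-permutation
invariance and the data-processing inequality under column merging. When
fed unmixing output, the unidentifiable M2·N2 product may be imputed as
similar to its peers or excluded; the choice is recorded in the result.

# Numerical choices and limitations

* Tolerances: ODE rtol 1e−8 / atol 1e−6 nM; detailed balance 1e−12;
  identifiability condition number 1e6; NNLS tolerance scaled to the
  matrix norm.
* Tie-breaks: collinear calibration columns drop later-listed species
  first; the initial-rate window extends to 5 points when sampling is
  coarse and flags the fallback.
* Degenerate inputs: zero product traces fit k = 0; all-zero
  confusion-matrix rows raise errors naming the template; identical
  positive and negative controls raise degenerate-control errors.
* The trimerization builder covers both assembly orders with the shared
  rate model and leak channels, but omits product rebinding to the
  trimer templates: it is used for yield questions, not inhibition.
* The lumped two-step cycle cannot satisfy both published TOF regimes at
  once (they differ by a non-linear factor the full mechanism must
  contain); the calibration splits the difference and no acceptance
  quantity depends on the absolute mechanistic TOF.
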