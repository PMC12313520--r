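# Compile domain-level designs into balanced mass-action reaction networks.
#
# A network is a list with:
#   species      data.frame(id, role)
#   constituents named list: species id -> character multiset of strands
#   reactions    data.frame(id, r1, r2, p1, p2, p3, k, order, reverse_of, dG)
#   design, params, and (for competition networks) the template index.
# Rate constants k are kept in M^-1 s^-1 (bimolecular) or s^-1
# (unimolecular); conversion to nM happens once, at simulation time.
# dG (kBT) is stored on the forward member of each reversible pair and obeys
# ln(kf/kr * C0^(order_f - order_r)) = -dG.

new_species <- function(id, role, constituents) {
  list(id = id, role = role, constituents = constituents)
}

new_reaction <- function(id, reactants, products, k, reverse_of = NA_character_,
                         dG = NA_real_) {
  stopifnot(length(reactants) >= 1L, length(reactants) <= 2L,
            length(products) >= 1L, length(products) <= 3L, k > 0)
  data.frame(id = id,
             r1 = reactants[1L], r2 = if (length(reactants) > 1L) reactants[2L] else NA_character_,
             p1 = products[1L],
             p2 = if (length(products) > 1L) products[2L] else NA_character_,
             p3 = if (length(products) > 2L) products[3L] else NA_character_,
             k = k, order = length(reactants), reverse_of = reverse_of,
             dG = dG, stringsAsFactors = FALSE)
}

assemble_network <- function(species, reactions, design, params, extra = list()) {
  sp <- data.frame(id = vapply(species, `[[`, "", "id"),
                   role = vapply(species, `[[`, "", "role"),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(sp$id)) stop("duplicate species ids", call. = FALSE)
  constituents <- lapply(species, `[[`, "constituents")
  names(constituents) <- sp$id
  net <- c(list(species = sp, constituents = constituents,
                reactions = do.call(rbind, reactions),
                design = design, params = params), extra)
  class(net) <- "reaction_network"
  ok <- check_strand_conservation(net)
  if (!all(ok))
    stop("strand multiset not conserved in reaction(s): ",
         paste(net$reactions$id[!ok], collapse = ", "), call. = FALSE)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %d species, %d reactions>\n",
              nrow(x$species), nrow(x$reactions)))
  invisible(x)
}

reaction_sides <- function(net) {
  rx <- net$reactions
  lapply(seq_len(nrow(rx)), function(i) {
    list(reactants = stats::na.omit(c(rx$r1[i], rx$r2[i])),
         products = stats::na.omit(c(rx$p1[i], rx$p2[i], rx$p3[i])))
  })
}

#' Check strand-multiset conservation of every reaction
#'
#' Each species carries a multiset of constituent strands; a balanced
#' reaction must carry the same multiset on both sides.
#'
#' @param net A `reaction_network`.
#' @return Logical vector, one entry per reaction.
#' @export
check_strand_conservation <- function(net) {
  sides <- reaction_sides(net)
  vapply(sides, function(s) {
    lhs <- sort(unlist(net$constituents[s$reactants], use.names = FALSE))
    rhs <- sort(unlist(net$constituents[s$products], use.names = FALSE))
    identical(lhs, rhs)
  }, logical(1L))
}

#' Check detailed balance of every reversible pair
#'
#' For each reaction pair (forward with stored reaction free energy dG,
#' reverse marked by `reverse_of`), verifies
#' `ln(kf/kr * C0^(order_f - order_r)) = -dG` to within `tol` relative error.
#'
#' @param net A `reaction_network`.
#' @param tol Relative tolerance (default 1e-12).
#' @return Data frame with one row per reversible pair: ids, stored dG,
#'   dG implied by the rate constants, and a logical `ok`.
#' @export
check_detailed_balance <- function(net, tol = 1e-12) {
  rx <- net$reactions
  rev_idx <- which(!is.na(rx$reverse_of))
  out <- lapply(rev_idx, function(i) {
    f <- match(rx$reverse_of[i], rx$id)
    dG <- rx$dG[f]
    implied <- -(log(rx$k[f] / rx$k[i]) +
                   (rx$order[f] - rx$order[i]) * log(net$params$C0))
    data.frame(forward = rx$id[f], reverse = rx$id[i], dG = dG,
               dG_implied = implied,
               ok = abs(implied - dG) <= tol * max(1, abs(dG)))
  })
  do.call(rbind, out)
}

# reverse rate constant from forward k and reaction dG (kBT), honouring
# standard-state factors for unequal molecularity.
reverse_rate <- function(k_f, dG, order_f, order_r, C0) {
  k_f * C0^(order_f - order_r) * exp(dG)
}

## ---- single-design dimerization cycle -----------------------------------

#' Build the templated-dimerization reaction network
#'
#' Compiles one design variant into the full catalytic cycle: toehold
#' exchange of the locked monomer onto the template (reversible), handhold
#' -mediated displacement by the second monomer that releases the dimer and
#' regenerates the template (irreversible), competitive rebinding of the
#' product to the template (reversible), the template-free leak channel,
#' and (optionally) sequestration of the template by the free N monomer via
#' its handhold, and a slow template-mediated product-stripping channel that
#' models the observed product interconversion.
#'
#' Species: `ML` (locked monomer), `L` (lock), `T` (template), `MT`
#' (template-monomer intermediate), `N` (monomer), `MN` (product), `TMN`
#' (template-product complex), and `TN` when sequestration is on.
#'
#' @param design A [design_variant()].
#' @param params A [rate_params()].
#' @param include_TN_sequestration Include `T + N <-> TN` (default `TRUE`).
#' @param include_interconversion Include the slow `MN + T -> MT + N`
#'   stripping channel (default `FALSE`); its rate is
#'   `k_interconv_frac * k_on`.
#' @param k_interconv_frac Fraction of `k_on` for the stripping channel.
#' @return A `reaction_network`.
#' @examples
#' net <- build_dimerization_network(design_variant(6, 8))
#' net$reactions[, c("id", "k")]
#' @export
build_dimerization_network <- function(design, params = rate_params(),
                                       include_TN_sequestration = TRUE,
                                       include_interconversion = FALSE,
                                       k_interconv_frac = 1e-3) {
  stopifnot(inherits(design, "design_variant"))
  sp <- list(
    new_species("ML", "locked-monomer", c("M", "L")),
    new_species("L", "lock", "L"),
    new_species("T", "template", "T"),
    new_species("MT", "template-monomer", c("M", "T")),
    new_species("N", "monomer", "N"),
    new_species("MN", "product", c("M", "N")),
    new_species("TMN", "template-product", c("M", "N", "T")))
  dG1 <- tmsd_exchange_dG(design, params)
  dGp <- product_binding_dG(design, params)
  k1f <- rate_tmsd(design$u, params)
  rx <- list(
    new_reaction("R1f", c("ML", "T"), c("MT", "L"), k1f, dG = dG1),
    new_reaction("R1r", c("MT", "L"), c("ML", "T"),
                 reverse_rate(k1f, dG1, 2L, 2L, params$C0), reverse_of = "R1f"),
    new_reaction("R2", c("MT", "N"), c("MN", "T"), rate_hmsd(design$v, params)),
    new_reaction("R3f", c("MN", "T"), "TMN", params$k_on, dG = dGp),
    new_reaction("R3r", "TMN", c("MN", "T"), product_off_rate(design, params),
                 reverse_of = "R3f"),
    new_reaction("R4", c("ML", "N"), c("MN", "L"), params$k_leak))
  if (include_TN_sequestration) {
    sp <- c(sp, list(new_species("TN", "template-N", c("T", "N"))))
    dGtn <- duplex_dG(design$v, params)
    rx <- c(rx, list(
      new_reaction("R5f", c("T", "N"), "TN", params$k_on, dG = dGtn),
      new_reaction("R5r", "TN", c("T", "N"),
                   reverse_rate(params$k_on, dGtn, 2L, 1L, params$C0),
                   reverse_of = "R5f")))
  }
  if (include_interconversion)
    rx <- c(rx, list(new_reaction("R6", c("MN", "T"), c("MT", "N"),
                                  k_interconv_frac * params$k_on)))
  assemble_network(sp, rx, design, params)
}

## ---- nine-template competition network ----------------------------------

#' Build the multi-monomer competition network for one template
#'
#' Three locked M monomers (distinct toeholds) and three N monomers
#' (distinct handholds) compete for a single template `T_{x*y*}`; all nine
#' dimers can form. A mismatched recognition domain is treated as a
#' zero-length domain, so cross-channel displacement falls to the
#' toehold-free (leak-level) rate. Product rebinding (and optionally TN
#' sequestration and interconversion) is modeled for the domains that
#' actually match the template.
#'
#' @param template Integer pair `c(x, y)` with x, y in 1..3.
#' @param design A [design_variant()] giving (u, v, s, ...) of the template.
#' @param params A [rate_params()].
#' @param include_TN_sequestration Include `T + N_{y*} <-> TN` (default `TRUE`).
#' @param include_interconversion Include slow stripping of N off
#'   correct-toehold products by the free template (default `FALSE`).
#' @param k_interconv_frac Fraction of `k_on` for the stripping channel.
#' @return A `reaction_network`; extra fields `template` (the index pair)
#'   and `product_species` (3x3 character matrix of dimer ids).
#' @export
build_competition_network <- function(template, design = design_variant(6, 8),
                                      params = rate_params(),
                                      include_TN_sequestration = TRUE,
                                      include_interconversion = FALSE,
                                      k_interconv_frac = 1e-3) {
  if (length(template) != 2L || !all(template %in% 1:3))
    stop("'template' must be a pair (x, y) with x, y in 1..3", call. = FALSE)
  xs <- template[1L]; ys <- template[2L]
  Tid <- sprintf("T%d%d", xs, ys)
  sp <- list(new_species(Tid, "template", Tid))
  for (x in 1:3) {
    sp <- c(sp, list(
      new_species(sprintf("M%dL", x), "locked-monomer",
                  c(sprintf("M%d", x), sprintf("L%d", x))),
      new_species(sprintf("L%d", x), "lock", sprintf("L%d", x)),
      new_species(sprintf("M%dT", x), "template-monomer",
                  c(sprintf("M%d", x), Tid))))
  }
  for (y in 1:3)
    sp <- c(sp, list(new_species(sprintf("N%d", y), "monomer",
                                 sprintf("N%d", y))))
  prod_ids <- outer(1:3, 1:3, function(x, y) sprintf("M%dN%d", x, y))
  for (x in 1:3) for (y in 1:3)
    sp <- c(sp, list(new_species(prod_ids[x, y], "product",
                                 c(sprintf("M%d", x), sprintf("N%d", y)))))

  rx <- list()
  for (x in 1:3) {
    dx <- design_variant(if (x == xs) design$u else 0L, design$v,
                         s = design$s, n_mm = design$n_mm,
                         clamps = design$clamps)
    dG1 <- tmsd_exchange_dG(dx, params)
    k1f <- rate_tmsd(dx$u, params)
    MLx <- sprintf("M%dL", x); Lx <- sprintf("L%d", x); MTx <- sprintf("M%dT", x)
    rx <- c(rx, list(
      new_reaction(sprintf("TMSD%df", x), c(MLx, Tid), c(MTx, Lx), k1f, dG = dG1),
      new_reaction(sprintf("TMSD%dr", x), c(MTx, Lx), c(MLx, Tid),
                   reverse_rate(k1f, dG1, 2L, 2L, params$C0),
                   reverse_of = sprintf("TMSD%df", x))))
    for (y in 1:3) {
      kh <- rate_hmsd(if (y == ys) design$v else 0L, params)
      rx <- c(rx, list(new_reaction(sprintf("HMSD%d%d", x, y),
                                    c(MTx, sprintf("N%d", y)),
                                    c(prod_ids[x, y], Tid), kh)))
    }
  }
  for (x in 1:3) for (y in 1:3)
    rx <- c(rx, list(new_reaction(sprintf("LEAK%d%d", x, y),
                                  c(sprintf("M%dL", x), sprintf("N%d", y)),
                                  c(prod_ids[x, y], sprintf("L%d", x)),
                                  params$k_leak)))
  # rebinding of the fully matched product
  TMN <- sprintf("T%d%d.M%dN%d", xs, ys, xs, ys)
  sp <- c(sp, list(new_species(TMN, "template-product",
                               c(sprintf("M%d", xs), sprintf("N%d", ys), Tid))))
  dGp <- product_binding_dG(design, params)
  rx <- c(rx, list(
    new_reaction("REBINDf", c(prod_ids[xs, ys], Tid), TMN, params$k_on,
                 dG = dGp),
    new_reaction("REBINDr", TMN, c(prod_ids[xs, ys], Tid),
                 product_off_rate(design, params), reverse_of = "REBINDf")))
  if (include_TN_sequestration) {
    TN <- sprintf("T%d%d.N%d", xs, ys, ys)
    sp <- c(sp, list(new_species(TN, "template-N",
                                 c(Tid, sprintf("N%d", ys)))))
    dGtn <- duplex_dG(design$v, params)
    rx <- c(rx, list(
      new_reaction("SEQf", c(Tid, sprintf("N%d", ys)), TN, params$k_on,
                   dG = dGtn),
      new_reaction("SEQr", TN, c(Tid, sprintf("N%d", ys)),
                   reverse_rate(params$k_on, dGtn, 2L, 1L, params$C0),
                   reverse_of = "SEQf")))
  }
  if (include_interconversion) {
    for (y in 1:3)
      rx <- c(rx, list(new_reaction(sprintf("STRIP%d", y),
                                    c(prod_ids[xs, y], Tid),
                                    c(sprintf("M%dT", xs), sprintf("N%d", y)),
                                    k_interconv_frac * params$k_on)))
  }
  assemble_network(sp, rx, design, params,
                   extra = list(template = c(x = xs, y = ys),
                                template_id = Tid,
                                product_species = prod_ids))
}

## ---- trimerization network ----------------------------------------------

#' Build the two-template trimerization network
#'
#' Monomers `A_x.LA`, `B_y.LB` and `C_z` (indices in `indices`, a subset of
#' 1:2) assemble into trimers `ABC_xyz`, templated by the dimerization
#' catalysts `TAB_jj` (joins A and B) and `TBC_jj` (joins B/AB and C) listed
#' in `templates`. Both assembly orders are included with the same rate
#' model as the dimerization cycle: AB first then C, or BC first then A.
#' Mismatched recognition domains are treated as length zero. Without any
#' templates only the leak channels remain. Product rebinding is omitted in
#' this builder (yield, not inhibition, is the question asked of it).
#'
#' @param templates Character subset of
#'   `c("TAB11", "TAB22", "TBC11", "TBC22")`; may be empty.
#' @param indices Monomer indices present in the pool (subset of 1:2).
#' @param design A [design_variant()] used for all templated steps.
#' @param params A [rate_params()].
#' @return A `reaction_network` with extra field `trimer_species`.
#' @export
build_trimer_network <- function(templates = c("TAB11", "TBC11"),
                                 indices = 1:2,
                                 design = design_variant(6, 8),
                                 params = rate_params()) {
  valid <- c("TAB11", "TAB22", "TBC11", "TBC22")
  if (!all(templates %in% valid))
    stop("'templates' must be a subset of ", paste(valid, collapse = ", "),
         call. = FALSE)
  if (!all(indices %in% 1:2) || length(indices) < 1L)
    stop("'indices' must be a non-empty subset of 1:2", call. = FALSE)
  idx <- sort(unique(as.integer(indices)))

  sp <- list(new_species("LA", "lock", "LA"),
             new_species("LB", "lock", "LB"))
  for (i in idx) {
    sp <- c(sp, list(
      new_species(sprintf("A%dL", i), "locked-monomer",
                  c(sprintf("A%d", i), "LA")),
      new_species(sprintf("B%dL", i), "locked-monomer",
                  c(sprintf("B%d", i), "LB")),
      new_species(sprintf("C%d", i), "monomer", sprintf("C%d", i))))
  }
  for (x in idx) for (y in idx)
    sp <- c(sp, list(new_species(sprintf("AB%d%dL", x, y), "product",
                                 c(sprintf("A%d", x), sprintf("B%d", y), "LB"))))
  for (y in idx) for (z in idx)
    sp <- c(sp, list(new_species(sprintf("BC%d%d", y, z), "product",
                                 c(sprintf("B%d", y), sprintf("C%d", z)))))
  for (x in idx) for (y in idx) for (z in idx)
    sp <- c(sp, list(new_species(sprintf("ABC%d%d%d", x, y, z), "product",
                                 c(sprintf("A%d", x), sprintf("B%d", y),
                                   sprintf("C%d", z)))))

  rx <- list()
  tmsd_pair <- function(tag, locked, lock, tmpl, bound, match) {
    d <- design_variant(if (match) design$u else 0L, design$v, s = design$s,
                        n_mm = design$n_mm, clamps = design$clamps)
    dG1 <- tmsd_exchange_dG(d, params)
    k1f <- rate_tmsd(d$u, params)
    list(new_reaction(paste0(tag, "f"), c(locked, tmpl), c(bound, lock),
                      k1f, dG = dG1),
         new_reaction(paste0(tag, "r"), c(bound, lock), c(locked, tmpl),
                      reverse_rate(k1f, dG1, 2L, 2L, params$C0),
                      reverse_of = paste0(tag, "f")))
  }
  hmsd_one <- function(tag, bound, invader, product, tmpl, match) {
    new_reaction(tag, c(bound, invader), c(product, tmpl),
                 rate_hmsd(if (match) design$v else 0L, params))
  }

  for (tp in templates) {
    j <- as.integer(substr(tp, 4L, 4L))
    sp <- c(sp, list(new_species(tp, "template", tp)))
    if (startsWith(tp, "TAB")) {
      for (x in idx) {
        bound <- sprintf("A%d.%s", x, tp)
        sp <- c(sp, list(new_species(bound, "template-monomer",
                                     c(sprintf("A%d", x), tp))))
        rx <- c(rx, tmsd_pair(sprintf("%s.T%d", tp, x), sprintf("A%dL", x),
                              "LA", tp, bound, match = (x == j)))
        for (y in idx) {
          rx <- c(rx, list(hmsd_one(sprintf("%s.H%d%d", tp, x, y), bound,
                                    sprintf("B%dL", y),
                                    sprintf("AB%d%dL", x, y), tp,
                                    match = (y == j))))
          for (z in idx)
            rx <- c(rx, list(hmsd_one(sprintf("%s.G%d%d%d", tp, x, y, z),
                                      bound, sprintf("BC%d%d", y, z),
                                      sprintf("ABC%d%d%d", x, y, z), tp,
                                      match = (y == j))))
        }
      }
    } else {  # TBCjj: joins B (or AB) with C
      for (y in idx) {
        boundB <- sprintf("B%d.%s", y, tp)
        sp <- c(sp, list(new_species(boundB, "template-monomer",
                                     c(sprintf("B%d", y), tp))))
        rx <- c(rx, tmsd_pair(sprintf("%s.T%d", tp, y), sprintf("B%dL", y),
                              "LB", tp, boundB, match = (y == j)))
        for (z in idx)
          rx <- c(rx, list(hmsd_one(sprintf("%s.H%d%d", tp, y, z), boundB,
                                    sprintf("C%d", z), sprintf("BC%d%d", y, z),
                                    tp, match = (z == j))))
        for (x in idx) {
          boundAB <- sprintf("AB%d%d.%s", x, y, tp)
          sp <- c(sp, list(new_species(boundAB, "template-product",
                                       c(sprintf("A%d", x), sprintf("B%d", y),
                                         tp))))
          rx <- c(rx, tmsd_pair(sprintf("%s.U%d%d", tp, x, y),
                                sprintf("AB%d%dL", x, y), "LB", tp, boundAB,
                                match = (y == j)))
          for (z in idx)
            rx <- c(rx, list(hmsd_one(sprintf("%s.I%d%d%d", tp, x, y, z),
                                      boundAB, sprintf("C%d", z),
                                      sprintf("ABC%d%d%d", x, y, z), tp,
                                      match = (z == j))))
        }
      }
    }
  }
  # template-free leak channels
  for (x in idx) for (y in idx)
    rx <- c(rx, list(new_reaction(sprintf("LK.AB%d%d", x, y),
                                  c(sprintf("A%dL", x), sprintf("B%dL", y)),
                                  c(sprintf("AB%d%dL", x, y), "LA"),
                                  params$k_leak)))
  for (y in idx) for (z in idx)
    rx <- c(rx, list(new_reaction(sprintf("LK.BC%d%d", y, z),
                                  c(sprintf("B%dL", y), sprintf("C%d", z)),
                                  c(sprintf("BC%d%d", y, z), "LB"),
                                  params$k_leak)))
  for (x in idx) for (y in idx) for (z in idx)
    rx <- c(rx, list(
      new_reaction(sprintf("LK.ABC%d%d%dc", x, y, z),
                   c(sprintf("AB%d%dL", x, y), sprintf("C%d", z)),
                   c(sprintf("ABC%d%d%d", x, y, z), "LB"), params$k_leak),
      new_reaction(sprintf("LK.ABC%d%d%da", x, y, z),
                   c(sprintf("A%dL", x), sprintf("BC%d%d", y, z)),
                   c(sprintf("ABC%d%d%d", x, y, z), "LA"), params$k_leak)))

  trimers <- as.vector(outer(outer(idx, idx, function(x, y)
    sprintf("ABC%d%d", x, y)), idx, function(a, z) sprintf("%s%d", a, z)))
  assemble_network(sp, rx, design, params,
                   extra = list(templates = templates,
                                trimer_species = trimers))
}

## ---- CSV edge list ------------------------------------------------------

#' Export / import a network edge list as CSV
#'
#' Columns: reaction id, reactants (`+`-joined), products, rate constant,
#' units (`M-1 s-1` or `s-1`), reverse_of, dG (kBT). `read_network_csv()`
#' returns the table (the full network object is not reconstructed).
#'
#' @param net A `reaction_network`.
#' @param path File path.
#' @export
write_network_csv <- function(net, path) {
  sides <- reaction_sides(net)
  df <- data.frame(
    reaction = net$reactions$id,
    reactants = vapply(sides, function(s) paste(s$reactants, collapse = "+"), ""),
    products = vapply(sides, function(s) paste(s$products, collapse = "+"), ""),
    k = format(net$reactions$k, digits = 12),
    units = ifelse(net$reactions$order == 2L, "M-1 s-1", "s-1"),
    reverse_of = net$reactions$reverse_of,
    dG_kBT = net$reactions$dG)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
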