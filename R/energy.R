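#' Electrostatics parameters for the screened-Coulomb term
#'
#' @param I ionic strength, mol/L.
#' @param epsilon_r relative dielectric constant (80 for aqueous solution).
#' @param temperature temperature in Kelvin used for the screening constant.
#' @param cutoff interaction cutoff in Angstrom (`Inf` disables; simulations
#'   in a periodic box use half the box edge).
#' @return An `electrostatics_params` list.
#' @export
electrostatics_params <- function(I = 0.1, epsilon_r = 80,
                                  temperature = 298, cutoff = Inf) {
  if (I < 0) stop("parameter error: ionic strength must be >= 0")
  if (epsilon_r <= 0) stop("parameter error: epsilon_r must be > 0")
  structure(list(I = I, epsilon_r = epsilon_r, temperature = temperature,
                 cutoff = cutoff),
            class = "electrostatics_params")
}

#' Debye screening constant and derived lengths
#'
#' `debye_kappa()` returns the inverse screening length
#' \eqn{\kappa = \sqrt{2 N_A e^2 I \cdot 10^3 / (\epsilon_0 \epsilon_r k_B T)}}
#' in 1/Angstrom; `debye_length()` returns \eqn{1/\kappa} in Angstrom;
#' `bjerrum_length()` the distance at which two unit charges interact with
#' exactly \eqn{k_B T}.
#'
#' @param I ionic strength (mol/L).
#' @param epsilon_r relative dielectric constant.
#' @param temperature Kelvin.
#' @export
debye_kappa <- function(I, epsilon_r = 80, temperature = 298) {
  if (I < 0) stop("parameter error: ionic strength must be >= 0")
  k2 <- 2 * .const$avogadro * .const$e^2 * I * 1e3 /
    (.const$eps0 * epsilon_r * .const$kB * temperature)  # 1/m^2
  sqrt(k2) * 1e-10
}

#' @rdname debye_kappa
#' @export
debye_length <- function(I, epsilon_r = 80, temperature = 298) {
  1 / debye_kappa(I, epsilon_r, temperature)
}

#' @rdname debye_kappa
#' @export
bjerrum_length <- function(epsilon_r = 80, temperature = 298) {
  .const$e^2 / (4 * pi * .const$eps0 * epsilon_r * .const$kB * temperature) * 1e10
}

# Coulomb prefactor e^2/(4 pi eps0) in kcal/mol * Angstrom
.coulomb_kcal <- function() {
  .const$e^2 / (4 * pi * .const$eps0) * 1e10 / .const$cal / 1000 * .const$avogadro
}

# ---------------------------------------------------------------------------
# pair bookkeeping

all_pairs <- function(idx) {
  n <- length(idx)
  if (n < 2) return(cbind(i = integer(), j = integer()))
  prs <- utils::combn(idx, 2)
  cbind(i = prs[1, ], j = prs[2, ])
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Precompute the nonbonded pair lists of a topology
#'
#' Splits all bead pairs into native contacts (12-10 attraction), nonnative
#' repulsive pairs, screened-Coulomb pairs (both charges nonzero, bonded 1-2
#' and angle 1-3 pairs excluded), and crowder pairs.
#'
#' @param top a `cg_topology`.
#' @return list of integer pair matrices `native`, `repulsive`, `charged`,
#'   `crowder_protein`, `crowder_crowder`.
#' @export
build_pair_lists <- function(top) {
  beads <- top$beads
  excl <- c(pair_key(top$bonds$i, top$bonds$j),
            pair_key(top$angles$i, top$angles$k))
  prot <- beads$index[beads$kind %in% c("CA", "SC", "CALCIUM")]
  crow <- beads$index[beads$kind == "CROWDER"]

  pp <- all_pairs(prot)
  if (nrow(pp)) {
    keys <- pair_key(pp[, 1], pp[, 2])
    keep <- !(keys %in% excl)
    pp <- pp[keep, , drop = FALSE]
    keys <- keys[keep]
    nat_keys <- if (nrow(top$contacts)) pair_key(top$contacts$i, top$contacts$j)
                else character()
    is_nat <- keys %in% nat_keys
    native <- pp[is_nat, , drop = FALSE]
    repulsive <- pp[!is_nat, , drop = FALSE]
    q <- beads$charge
    ch_keep <- q[pp[, 1]] != 0 & q[pp[, 2]] != 0
    charged <- pp[ch_keep, , drop = FALSE]
  } else {
    native <- repulsive <- charged <- cbind(i = integer(), j = integer())
  }
  cp <- if (length(crow) && length(prot)) {
    cbind(i = rep(crow, each = length(prot)), j = rep(prot, length(crow)))
  } else cbind(i = integer(), j = integer())
  cc <- all_pairs(crow)
  list(native = native, repulsive = repulsive, charged = charged,
       crowder_protein = cp, crowder_crowder = cc)
}

# ---------------------------------------------------------------------------
# individual terms (all in epsilon units)

#' Bonded energy terms
#'
#' `bond_energy()` evaluates \eqn{\sum k_b (r - r_0)^2},
#' `angle_energy()` \eqn{\sum k_\theta (\theta - \theta_0)^2} (radians), and
#' `dihedral_energy()` the enabled 1-fold + 3-fold cosine terms
#' \eqn{k_1 [1-\cos(\phi-\phi_0)] + k_3 [1-\cos 3(\phi-\phi_0)]}.
#'
#' @param top a `cg_topology`.
#' @param pos n x 3 position matrix (defaults to the topology's reference
#'   coordinates).
#' @return energy in epsilon units.
#' @export
bond_energy <- function(top, pos = positions(top)) {
  b <- top$bonds
  if (!nrow(b)) return(0)
  r <- .pair_dist(pos, b$i, b$j)
  sum(b$kb * (r - b$r0)^2)
}

#' @rdname bond_energy
#' @export
angle_energy <- function(top, pos = positions(top)) {
  a <- top$angles
  if (!nrow(a)) return(0)
  th <- vapply(seq_len(nrow(a)),
               function(r) .bond_angle(pos, a$i[r], a$j[r], a$k[r]), numeric(1))
  sum(a$ktheta * (th - a$theta0)^2)
}

#' @rdname bond_energy
#' @export
dihedral_energy <- function(top, pos = positions(top)) {
  d <- top$dihedrals
  d <- d[d$enabled, , drop = FALSE]
  if (!nrow(d)) return(0)
  phi <- vapply(seq_len(nrow(d)),
                function(r) .dihedral(pos, d$i[r], d$j[r], d$k[r], d$l[r]),
                numeric(1))
  dphi <- phi - d$phi0
  sum(d$k1 * (1 - cos(dphi)) + d$k3 * (1 - cos(3 * dphi)))
}

# soft guard against r -> 0 overflow in inverse-power terms
.guard_r <- function(r, floor = 1e-4) {
  if (any(r < floor)) {
    warning("near-coincident beads: repulsive energy capped")
    r <- pmax(r, floor)
  }
  r
}

#' Strictly repulsive excluded-volume energy
#'
#' \eqn{\sum \epsilon (\bar\sigma_{ij}/r)^{12}} with
#' \eqn{\bar\sigma_{ij} = f (\sigma_i + \sigma_j)} (bead radii, so the energy
#' is epsilon when the spheres touch, scaled by `f`) and scaling factor
#' `f = 0.9` to avoid steric clashes.  Used for calcium-anything pairs and
#' for nonnative protein pairs without an attractive well, and (with the
#' 55 Angstrom radius) for crowder interactions.
#'
#' @param top a `cg_topology`.
#' @param pos position matrix.
#' @param pairs 2-column integer matrix of bead pairs (defaults to the
#'   nonnative repulsive list).
#' @param f steric scaling factor.
#' @param box periodic box edge (NA = non-periodic).
#' @param cutoff pair cutoff in Angstrom.
#' @return energy in epsilon units.
#' @export
repulsive_energy <- function(top, pos = positions(top), pairs = NULL,
                             f = 0.9, box = top$box, cutoff = Inf) {
  if (is.null(pairs)) pairs <- build_pair_lists(top)$repulsive
  if (!nrow(pairs)) return(0)
  r <- .guard_r(.pair_dist(pos, pairs[, 1], pairs[, 2], box))
  sig <- f * (top$beads$sigma[pairs[, 1]] + top$beads$sigma[pairs[, 2]])
  e <- (sig / r)^12
  e[r >= cutoff] <- 0
  sum(e)
}

#' Native-contact attraction (12-10 well)
#'
#' Per contact \eqn{d [5 (r_0/r)^{12} - 6 (r_0/r)^{10}]}, minimum \eqn{-d}
#' at the native distance \eqn{r_0}.
#'
#' @inheritParams repulsive_energy
#' @param contacts contact table (defaults to `top$contacts`).
#' @export
native_energy <- function(top, pos = positions(top), contacts = top$contacts,
                          box = top$box, cutoff = Inf) {
  if (!nrow(contacts)) return(0)
  r <- .guard_r(.pair_dist(pos, contacts$i, contacts$j, box))
  x <- contacts$r0 / r
  e <- contacts$depth * (5 * x^12 - 6 * x^10)
  e[r >= cutoff] <- 0
  sum(e)
}

#' Debye-Hueckel screened electrostatic energy
#'
#' \eqn{V_{ij} = \frac{Z_i Z_j e^2}{4\pi\epsilon_0\epsilon_r r} e^{-\kappa r}}
#' with \eqn{\kappa^2 = 2 N_A e^2 I \cdot 10^3/(\epsilon_0\epsilon_r k_B T)}.
#' Evaluated in physical units (kcal/mol) and converted to reduced units by
#' dividing by epsilon = 0.6 kcal/mol.  Bonded (1-2) and angle (1-3) pairs
#' are excluded by the default pair list.
#'
#' @inheritParams repulsive_energy
#' @param params an [electrostatics_params()] object.
#' @export
debye_huckel_energy <- function(top, pos = positions(top), params,
                                pairs = NULL, box = top$box) {
  if (is.null(pairs)) pairs <- build_pair_lists(top)$charged
  if (!nrow(pairs)) return(0)
  r <- .guard_r(.pair_dist(pos, pairs[, 1], pairs[, 2], box))
  q <- top$beads$charge
  kap <- debye_kappa(params$I, params$epsilon_r, params$temperature)
  v <- .coulomb_kcal() * q[pairs[, 1]] * q[pairs[, 2]] /
    (params$epsilon_r * r) * exp(-kap * r)
  v[r >= params$cutoff] <- 0
  sum(v) / .const$eps_kcal
}

#' Crowder excluded-volume energy
#'
#' Repulsive (sigma/r)^12 interactions of crowder spheres with the protein
#' beads and with each other, under the minimum-image convention.
#'
#' @inheritParams repulsive_energy
#' @return list with components `crowder_protein` and `crowder_crowder`.
#' @export
crowder_energy <- function(top, pos = positions(top), f = 0.9,
                           box = top$box, cutoff = Inf) {
  pl <- build_pair_lists(top)
  list(
    crowder_protein = repulsive_energy(top, pos, pl$crowder_protein, f, box,
                                       cutoff),
    crowder_crowder = repulsive_energy(top, pos, pl$crowder_crowder, f, box,
                                       cutoff)
  )
}

#' Full potential-energy decomposition
#'
#' Evaluates every Hamiltonian term with the half-box cutoff for nonbonded
#' interactions when the topology has a periodic box.
#'
#' @param top a `cg_topology`.
#' @param pos position matrix.
#' @param params an [electrostatics_params()]; `NULL` skips the
#'   electrostatic term.
#' @param pairs cached [build_pair_lists()] result (recomputed if missing).
#' @param f steric scaling factor of the repulsive terms.
#' @return An `energy_breakdown`: list of the per-term energies (epsilon
#'   units) plus their sum `total`.
#' @export
total_energy <- function(top, pos = positions(top), params = NULL,
                         pairs = NULL, f = 0.9) {
  if (is.null(pairs)) pairs <- build_pair_lists(top)
  box <- top$box
  cutoff <- if (is.finite(box %||% NA)) box / 2 else Inf
  if (!is.null(params) && is.finite(box %||% NA)) {
    params <- electrostatics_params(params$I, params$epsilon_r,
                                    params$temperature,
                                    min(params$cutoff, box / 2))
  }
  terms <- list(
    bond = bond_energy(top, pos),
    angle = angle_energy(top, pos),
    dihedral = dihedral_energy(top, pos),
    native_attractive = native_energy(top, pos, box = box, cutoff = cutoff),
    nonnative_repulsive = repulsive_energy(top, pos, pairs$repulsive, f,
                                           box, cutoff),
    debye_huckel = if (is.null(params)) 0 else
      debye_huckel_energy(top, pos, params, pairs$charged, box),
    crowder_protein = repulsive_energy(top, pos, pairs$crowder_protein, f,
                                       box, cutoff),
    crowder_crowder = repulsive_energy(top, pos, pairs$crowder_crowder, f,
                                       box, cutoff)
  )
  terms$total <- sum(unlist(terms))
  class(terms) <- "energy_breakdown"
  terms
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (epsilon units)\n")
  for (nm in setdiff(names(x), "total")) {
    cat(sprintf("  %-20s %12.6f\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-20s %12.6f\n", "total", x$total))
  invisible(x)
}
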