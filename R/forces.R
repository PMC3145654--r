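# Analytic gradients of every Hamiltonian term.  Forces are returned as
# n x 3 matrices, F = -dE/dx, in epsilon/Angstrom.

.acc_rows <- function(F, idx, X) {
  s <- rowsum(X, idx)
  rid <- as.integer(rownames(s))
  F[rid, ] <- F[rid, ] + s
  F
}

# generic radial pair force: g = (dE/dr)/r per pair, applied along the
# (minimum-image) displacement
.radial_forces <- function(F, pos, ii, jj, g, box) {
  d <- .min_image(pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE], box)
  X <- -g * d
  F <- .acc_rows(F, ii, X)
  .acc_rows(F, jj, -X)
}

.bond_forces <- function(F, top, pos) {
  b <- top$bonds
  if (!nrow(b)) return(F)
  r <- .pair_dist(pos, b$i, b$j)
  .radial_forces(F, pos, b$i, b$j, 2 * b$kb * (r - b$r0) / r, NA)
}

.angle_forces <- function(F, top, pos) {
  a <- top$angles
  for (row in seq_len(nrow(a))) {
    i <- a$i[row]; j <- a$j[row]; k <- a$k[row]
    u <- pos[i, ] - pos[j, ]
    v <- pos[k, ] - pos[j, ]
    lu <- .vnorm(u); lv <- .vnorm(v)
    cs <- pmin(1, pmax(-1, sum(u * v) / (lu * lv)))
    sn <- sqrt(max(1 - cs^2, 1e-12))
    th <- acos(cs)
    dEdth <- 2 * a$ktheta[row] * (th - a$theta0[row])
    dthi <- -(v / (lu * lv) - cs * u / lu^2) / sn
    dthk <- -(u / (lu * lv) - cs * v / lv^2) / sn
    F[i, ] <- F[i, ] - dEdth * dthi
    F[k, ] <- F[k, ] - dEdth * dthk
    F[j, ] <- F[j, ] + dEdth * (dthi + dthk)
  }
  F
}

.dihedral_forces <- function(F, top, pos) {
  d <- top$dihedrals
  d <- d[d$enabled, , drop = FALSE]
  for (row in seq_len(nrow(d))) {
    i <- d$i[row]; j <- d$j[row]; k <- d$k[row]; l <- d$l[row]
    b1 <- pos[j, ] - pos[i, ]
    b2 <- pos[k, ] - pos[j, ]
    b3 <- pos[l, ] - pos[k, ]
    n1 <- .cross(b1, b2)
    n2 <- .cross(b2, b3)
    lb2 <- .vnorm(b2)
    phi <- .dihedral(pos, i, j, k, l)
    dphi <- phi - d$phi0[row]
    dEdphi <- d$k1[row] * sin(dphi) + 3 * d$k3[row] * sin(3 * dphi)
    dpi <-  lb2 / sum(n1 * n1) * n1
    dpl <- -lb2 / sum(n2 * n2) * n2
    s12 <- sum(b1 * b2) / lb2^2
    s32 <- sum(b3 * b2) / lb2^2
    dpj <- (-1 - s12) * dpi + s32 * dpl
    dpk <- s12 * dpi + (-1 - s32) * dpl
    F[i, ] <- F[i, ] - dEdphi * dpi
    F[j, ] <- F[j, ] - dEdphi * dpj
    F[k, ] <- F[k, ] - dEdphi * dpk
    F[l, ] <- F[l, ] - dEdphi * dpl
  }
  F
}

.repulsive_pair_forces <- function(F, top, pos, pairs, f, box, cutoff) {
  if (!nrow(pairs)) return(F)
  r <- .guard_r(.pair_dist(pos, pairs[, 1], pairs[, 2], box))
  sig <- f * (top$beads$sigma[pairs[, 1]] + top$beads$sigma[pairs[, 2]])
  e <- (sig / r)^12
  g <- -12 * e / r / r          # (dE/dr)/r
  g[r >= cutoff] <- 0
  .radial_forces(F, pos, pairs[, 1], pairs[, 2], g, box)
}

.native_pair_forces <- function(F, top, pos, box, cutoff) {
  ct <- top$contacts
  if (!nrow(ct)) return(F)
  r <- .guard_r(.pair_dist(pos, ct$i, ct$j, box))
  x <- ct$r0 / r
  g <- -60 * ct$depth * (x^12 - x^10) / r / r
  g[r >= cutoff] <- 0
  .radial_forces(F, pos, ct$i, ct$j, g, box)
}

.dh_pair_forces <- function(F, top, pos, pairs, params, box) {
  if (!nrow(pairs)) return(F)
  r <- .guard_r(.pair_dist(pos, pairs[, 1], pairs[, 2], box))
  q <- top$beads$charge
  kap <- debye_kappa(params$I, params$epsilon_r, params$temperature)
  v <- .coulomb_kcal() * q[pairs[, 1]] * q[pairs[, 2]] /
    (params$epsilon_r * r) * exp(-kap * r) / .const$eps_kcal
  g <- v * (-1 / r - kap) / r
  g[r >= params$cutoff] <- 0
  .radial_forces(F, pos, pairs[, 1], pairs[, 2], g, box)
}

#' Total analytic forces
#'
#' Negative gradient of [total_energy()] with respect to all bead
#' coordinates.  Matches central finite differences; the agreement is
#' exercised by the test suite on random configurations.
#'
#' @inheritParams total_energy
#' @return n x 3 force matrix in epsilon/Angstrom.
#' @export
total_forces <- function(top, pos = positions(top), params = NULL,
                         pairs = NULL, f = 0.9) {
  if (is.null(pairs)) pairs <- build_pair_lists(top)
  box <- top$box
  cutoff <- if (is.finite(box %||% NA)) box / 2 else Inf
  if (!is.null(params) && is.finite(box %||% NA)) {
    params <- electrostatics_params(params$I, params$epsilon_r,
                                    params$temperature,
                                    min(params$cutoff, box / 2))
  }
  F <- matrix(0, nrow(pos), 3)
  F <- .bond_forces(F, top, pos)
  F <- .angle_forces(F, top, pos)
  F <- .dihedral_forces(F, top, pos)
  F <- .native_pair_forces(F, top, pos, box, cutoff)
  F <- .repulsive_pair_forces(F, top, pos, pairs$repulsive, f, box, cutoff)
  if (!is.null(params)) F <- .dh_pair_forces(F, top, pos, pairs$charged,
                                             params, box)
  F <- .repulsive_pair_forces(F, top, pos, pairs$crowder_protein, f, box,
                              cutoff)
  F <- .repulsive_pair_forces(F, top, pos, pairs$crowder_crowder, f, box,
                              cutoff)
  F
}
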