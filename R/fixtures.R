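# Synthetic structure generators: deterministic, desk-scale stand-ins with
# the geometry the coarse-grained machinery assumes.  All are writable as
# standard PDB via write_structure() and re-readable by parse_structure().

# assemble an atom_records table from per-residue CA (+ optional CB) coords
.atoms_from_trace <- function(ca, cb = NULL, resids, resno = seq_len(nrow(ca)),
                              helix = NULL) {
  rows <- list()
  eleno <- 0L
  for (r in seq_len(nrow(ca))) {
    eleno <- eleno + 1L
    rows[[length(rows) + 1]] <- data.frame(
      eleno = eleno, elety = "CA", resid = resids[r], resno = resno[r],
      chain = "A", x = ca[r, 1], y = ca[r, 2], z = ca[r, 3], occ = 1,
      type = "ATOM", stringsAsFactors = FALSE)
    if (!is.null(cb) && resids[r] != "GLY" && !any(is.na(cb[r, ]))) {
      eleno <- eleno + 1L
      rows[[length(rows) + 1]] <- data.frame(
        eleno = eleno, elety = "CB", resid = resids[r], resno = resno[r],
        chain = "A", x = cb[r, 1], y = cb[r, 2], z = cb[r, 3], occ = 1,
        type = "ATOM", stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  attr(atoms, "helix") <- helix %||% data.frame(
    helix = character(), start = integer(), end = integer())
  class(atoms) <- c("atom_records", "data.frame")
  atoms
}

# parametric alpha-helix trace: right-handed, ~3.8 A CA-CA spacing
.helix_trace <- function(n, rise = 1.5, radius = 2.3, turn = -100) {
  t <- (seq_len(n) - 1) * turn * pi / 180
  cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1) * rise)
}

#' Ideal alpha-helix fixture
#'
#' C-alpha trace with a 100 degree turn, 1.5 Angstrom rise and 2.3 Angstrom
#' radius (giving the canonical ~3.8 Angstrom C-alpha spacing), plus
#' radially displaced side-chain pseudo-atoms.
#'
#' @param n number of residues (>= 5).
#' @param sequence optional one-letter sequence (default: all alanine).
#' @param start_resno first residue number.
#' @return an `atom_records` table.
#' @export
make_ideal_helix <- function(n, sequence = NULL, start_resno = 1L) {
  if (n < 5) stop("need at least 5 residues for a helix fixture")
  resids <- if (is.null(sequence)) rep("ALA", n) else aa_three(sequence)
  stopifnot(length(resids) == n)
  ca <- .helix_trace(n)
  t <- (seq_len(n) - 1) * -100 * pi / 180
  cb <- cbind((2.3 + 1.5) * cos(t), (2.3 + 1.5) * sin(t), ca[, 3])
  .atoms_from_trace(ca, cb, resids, resno = start_resno + seq_len(n) - 1L,
                    helix = data.frame(helix = "A", start = start_resno,
                                       end = start_resno + n - 1L))
}

#' Fully extended chain fixture
#'
#' Straight C-alpha trace at 3.8 Angstrom spacing with side-chain
#' pseudo-atoms offset perpendicular to the chain.
#'
#' @param n number of residues.
#' @param sequence optional one-letter sequence (default all alanine).
#' @return an `atom_records` table.
#' @export
make_extended_chain <- function(n, sequence = NULL) {
  resids <- if (is.null(sequence)) rep("ALA", n) else aa_three(sequence)
  stopifnot(length(resids) == n)
  ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  cb <- cbind(ca[, 1], 2.5, 0)
  .atoms_from_trace(ca, cb, resids)
}

# rotation by `angle` about unit axis `ax` (Rodrigues)
rotation_about <- function(ax, angle) {
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# rotation taking unit vector a to unit vector b (Rodrigues)
.rot_a_to_b <- function(a, b) {
  v <- .cross(a, b)
  s <- .vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    ax <- if (abs(a[1]) < 0.9) .cross(a, c(1, 0, 0)) else .cross(a, c(0, 1, 0))
    ax <- ax / .vnorm(ax)
    return(2 * outer(ax, ax) - diag(3))
  }
  Vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + Vx + Vx %*% Vx * ((1 - c_) / s^2)
}

#' Helix-loop-helix fixture
#'
#' Two ideal helices joined by a loop, with the second helix axis at the
#' requested angle to the first.  The loop residues are acidic (Asp) so the
#' fixture doubles as a miniature calcium-binding motif.
#'
#' @param angle interhelix angle in degrees, in (0, 180].
#' @param n_helix residues per helix (default 10).
#' @param n_loop loop residues (default 5).
#' @return an `atom_records` table with helices `A` and `B` annotated.
#' @export
make_helix_loop_helix <- function(angle = 90, n_helix = 10, n_loop = 5) {
  if (angle <= 0 || angle > 180) stop("angle must be in (0, 180]")
  h1 <- .helix_trace(n_helix)
  a <- angle * pi / 180
  u2 <- c(sin(a), 0, cos(a))
  R <- .rot_a_to_b(c(0, 0, 1), u2)
  h2 <- .helix_trace(n_helix) %*% t(R)
  # place helix 2 so the loop bridges the gap at ~3.6 A per residue
  gap <- 3.6 * (n_loop + 1)
  start2 <- h1[n_helix, ] + c(gap * 0.95, 0, 4)
  h2 <- sweep(h2, 2, start2 - h2[1, ], "+")
  loop <- t(vapply(seq_len(n_loop), function(i) {
    f <- i / (n_loop + 1)
    h1[n_helix, ] * (1 - f) + h2[1, ] * f + c(0, 3 * sin(pi * f), 0)
  }, numeric(3)))
  ca <- rbind(h1, loop, h2)
  n <- nrow(ca)
  # side-chain pseudo-atoms: radially outward within the helices (as in the
  # ideal-helix fixture), alternating perpendiculars along the loop
  t_h <- (seq_len(n_helix) - 1) * -100 * pi / 180
  radial <- cbind(cos(t_h), sin(t_h), 0)
  cb1 <- h1 + 1.5 * radial
  shift2 <- start2 - (.helix_trace(n_helix) %*% t(R))[1, ]
  cb2 <- sweep((.helix_trace(n_helix) + 1.5 * radial) %*% t(R), 2, shift2, "+")
  cb_loop <- loop + 2.5 * t(vapply(seq_len(n_loop), function(i) {
    d <- if (i < n_loop) loop[min(i + 1, n_loop), ] - loop[i, ] else
      loop[i, ] - loop[max(i - 1, 1), ]
    d <- d / .vnorm(d)
    perp <- .cross(d, c(0, 0, 1))
    if (.vnorm(perp) < 1e-6) perp <- .cross(d, c(0, 1, 0))
    (-1)^i * perp / .vnorm(perp)
  }, numeric(3)))
  cb <- rbind(cb1, cb_loop, cb2)
  resids <- c(rep("ALA", n_helix), rep("ASP", 2), "SER", rep("ASP", 1),
              rep("SER", n_loop - 4), rep("ALA", n_helix))
  resids <- resids[seq_len(n)]
  helix <- data.frame(helix = c("A", "B"),
                      start = c(1L, n_helix + n_loop + 1L),
                      end = c(n_helix, n))
  .atoms_from_trace(ca, cb, resids, helix = helix)
}

#' Miniature EF-hand fixture
#'
#' A helix-loop-helix motif at the requested interhelix angle with a
#' calcium ion at the centroid of the loop's three acidic side chains.
#'
#' @param angle interhelix angle, degrees.
#' @return list with `atoms` (the motif), `calcium` (1 x 3 position) and
#'   `connectivity` (list `CA1` = the three acidic residue numbers).
#' @export
make_mini_efhand <- function(angle = 90) {
  atoms <- make_helix_loop_helix(angle)
  acidic <- unique(atoms$resno[atoms$resid == "ASP"])
  stopifnot(length(acidic) == 3)
  cb <- atoms[atoms$elety == "CB" & atoms$resno %in% acidic, c("x", "y", "z")]
  calcium <- matrix(colMeans(cb), 1, 3)
  list(atoms = atoms, calcium = calcium,
       connectivity = list(CA1 = acidic))
}

#' Gaussian-perturbed reference ensemble
#'
#' Independent isotropic Gaussian displacements of every bead; `sd = 0`
#' reproduces the reference exactly.  Deterministic per seed.
#'
#' @param ref reference coordinates (n x 3).
#' @param n_frames number of frames.
#' @param sd displacement standard deviation, Angstrom.
#' @param seed RNG seed.
#' @return list of coordinate matrices.
#' @export
make_reference_ensemble <- function(ref, n_frames, sd = 0, seed = 1) {
  stopifnot(sd >= 0)
  set.seed(seed)
  lapply(seq_len(n_frames), function(f) {
    ref + matrix(stats::rnorm(length(ref), sd = sd), ncol = 3)
  })
}

#' Analytic harmonic benchmark system
#'
#' `n` independent particles in isotropic 3-D harmonic wells,
#' \eqn{E = \frac{1}{2} k \sum_i |r_i|^2}: the configurational partition
#' function and \eqn{\langle E_{pot}\rangle = \frac{3}{2} N k_B T} are known
#' in closed form, which makes this the oracle for the Langevin integrator
#' and the WHAM reweighting machinery.
#'
#' @param n number of particles.
#' @param k spring constant (epsilon / Angstrom^2).
#' @param mass particle mass (reduced units).
#' @return a `dynamics_system` with extra fields `k`, `mean_epot(kT)`,
#'   `log_Z(kT)` (configurational) and `sample(n_samples, kT)` drawing
#'   exact Boltzmann configurations.
#' @export
make_harmonic_system <- function(n = 1, k = 1, mass = 1) {
  stopifnot(n >= 1, k > 0)
  structure(list(
    n = n,
    masses = rep(mass, n),
    box = NA_real_,
    mobile = rep(TRUE, n),
    wrap = rep(FALSE, n),
    sigma_min = Inf,
    k = k,
    energy = function(pos) 0.5 * k * sum(pos^2),
    forces = function(pos) -k * pos,
    mean_epot = function(kT) 1.5 * n * kT,
    log_Z = function(kT) (3 * n / 2) * log(2 * pi * kT / k),
    sample = function(n_samples, kT) {
      lapply(seq_len(n_samples), function(s) {
        matrix(stats::rnorm(3 * n, sd = sqrt(kT / k)), ncol = 3)
      })
    }
  ), class = "dynamics_system")
}
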