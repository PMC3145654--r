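# Shared fixtures built in code: a bonded dimer, a random charged test
# system, a synthetic calmodulin-scale chain, and brute-force energy/force
# oracles kept deliberately independent of the package's vectorised paths.

make_dimer_topology <- function(r0 = 3.8, kb = 100) {
  structure(list(
    beads = data.frame(index = 1:2, kind = "CA", resno = 1:2, resid = "ALA",
                       x = c(0, r0), y = 0, z = 0, sigma = 1.9, mass = 1,
                       charge = 0, stringsAsFactors = FALSE),
    bonds = data.frame(i = 1L, j = 2L, r0 = r0, kb = kb),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), ktheta = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), phi0 = numeric(), k1 = numeric(),
                           k3 = numeric(), enabled = logical()),
    contacts = data.frame(i = integer(), j = integer(), r0 = numeric(),
                          depth = numeric()),
    calcium = list(), box = NA_real_), class = "cg_topology")
}

# small random system with every interaction class present
make_random_test_system <- function(n_res = 8, seed = 1, box = NA,
                                    crowders = 0, crowder_radius = 8) {
  set.seed(seed)
  seq1 <- paste(sample(c("A", "D", "K", "L", "E", "F", "R", "S"), n_res,
                       replace = TRUE), collapse = "")
  atoms <- make_ideal_helix(n_res, sequence = seq1)
  top <- coarse_grain(atoms)
  top <- build_native_contacts(atoms, top, cutoff = 6)
  top <- assign_charges(top)
  if (crowders > 0) {
    lim <- if (is.finite(box)) box else 60
    cent <- matrix(stats::runif(3 * crowders, 0.2 * lim, 0.8 * lim),
                   crowders, 3)
    attr(cent, "radius") <- crowder_radius
    top <- add_crowders(top, cent, box = box)
  } else {
    top$box <- box
  }
  top
}

# synthetic calmodulin-scale fixture: the real 148-residue sequence threaded
# onto an ideal helix, with calcium beads at the EF-hand ligand centroids
make_synthetic_cam <- function(holo = TRUE) {
  atoms <- make_ideal_helix(148, sequence = cam_sequence())
  top <- coarse_grain(atoms)
  top <- assign_charges(top)
  if (holo) {
    sites <- cam_calcium_sites()
    pos <- positions(top)
    capos <- t(vapply(sites, function(rs) {
      idx <- top$beads$index[top$beads$kind == "SC" & top$beads$resno %in% rs]
      colMeans(pos[idx, , drop = FALSE]) + c(1, 0, 0)
    }, numeric(3)))
    top <- attach_calcium(top, connectivity = sites,
                          calcium_positions = capos)
  }
  list(atoms = atoms, top = top)
}

# --- brute-force oracles: plain double loops, no shared helpers -----------

oracle_dist <- function(p, i, j, box = NA) {
  d <- p[i, ] - p[j, ]
  if (is.finite(box)) d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

oracle_energy <- function(top, pos, params = NULL, f = 0.9) {
  beads <- top$beads
  box <- top$box
  cutoff <- if (is.finite(box)) box / 2 else Inf
  e_bond <- 0
  for (r in seq_len(nrow(top$bonds))) {
    b <- top$bonds[r, ]
    e_bond <- e_bond + b$kb * (oracle_dist(pos, b$i, b$j) - b$r0)^2
  }
  e_ang <- 0
  for (r in seq_len(nrow(top$angles))) {
    a <- top$angles[r, ]
    u <- pos[a$i, ] - pos[a$j, ]
    v <- pos[a$k, ] - pos[a$j, ]
    th <- acos(max(-1, min(1, sum(u * v) /
                             sqrt(sum(u * u) * sum(v * v)))))
    e_ang <- e_ang + a$ktheta * (th - a$theta0)^2
  }
  e_dih <- 0
  for (r in seq_len(nrow(top$dihedrals))) {
    d <- top$dihedrals[r, ]
    if (!d$enabled) next
    b1 <- pos[d$j, ] - pos[d$i, ]
    b2 <- pos[d$k, ] - pos[d$j, ]
    b3 <- pos[d$l, ] - pos[d$k, ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    m1 <- cr(n1, b2 / sqrt(sum(b2 * b2)))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    e_dih <- e_dih + d$k1 * (1 - cos(phi - d$phi0)) +
      d$k3 * (1 - cos(3 * (phi - d$phi0)))
  }
  # nonbonded: loop every pair, classify by exclusion/native/charge
  excl <- character(0)
  key <- function(i, j) paste(min(i, j), max(i, j))
  for (r in seq_len(nrow(top$bonds))) {
    excl <- c(excl, key(top$bonds$i[r], top$bonds$j[r]))
  }
  for (r in seq_len(nrow(top$angles))) {
    excl <- c(excl, key(top$angles$i[r], top$angles$k[r]))
  }
  natkey <- character(0)
  natmap <- list()
  for (r in seq_len(nrow(top$contacts))) {
    k <- key(top$contacts$i[r], top$contacts$j[r])
    natkey <- c(natkey, k)
    natmap[[k]] <- top$contacts[r, ]
  }
  kap <- if (!is.null(params)) {
    debye_kappa(params$I, params$epsilon_r, params$temperature)
  } else NA
  coul <- 332.0637130742 / 0.6  # e^2/(4 pi eps0) in kcal/(mol A), over epsilon
  e_nat <- e_rep <- e_dh <- e_cp <- e_cc <- 0
  n <- nrow(beads)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ki <- beads$kind[i]; kj <- beads$kind[j]
      r <- oracle_dist(pos, i, j, box)
      if (ki == "CROWDER" || kj == "CROWDER") {
        if (r < cutoff) {
          sb <- f * (beads$sigma[i] + beads$sigma[j])
          e <- (sb / r)^12
          if (ki == "CROWDER" && kj == "CROWDER") e_cc <- e_cc + e
          else e_cp <- e_cp + e
        }
        next
      }
      k <- key(i, j)
      if (k %in% excl) next
      if (k %in% natkey) {
        if (r < cutoff) {
          ct <- natmap[[k]]
          x <- ct$r0 / r
          e_nat <- e_nat + ct$depth * (5 * x^12 - 6 * x^10)
        }
      } else if (r < cutoff) {
        sb <- f * (beads$sigma[i] + beads$sigma[j])
        e_rep <- e_rep + (sb / r)^12
      }
      if (!is.null(params) && beads$charge[i] != 0 && beads$charge[j] != 0 &&
          r < params$cutoff) {
        e_dh <- e_dh + coul * beads$charge[i] * beads$charge[j] /
          (params$epsilon_r * r) * exp(-kap * r)
      }
    }
  }
  list(bond = e_bond, angle = e_ang, dihedral = e_dih,
       native_attractive = e_nat, nonnative_repulsive = e_rep,
       debye_huckel = e_dh, crowder_protein = e_cp, crowder_crowder = e_cc,
       total = e_bond + e_ang + e_dih + e_nat + e_rep + e_dh + e_cp + e_cc)
}

fd_forces <- function(top, pos, params = NULL, eps = 1e-6) {
  fd <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + eps
      pm <- pos; pm[i, c] <- pm[i, c] - eps
      fd[i, c] <- -(total_energy(top, pp, params)$total -
                      total_energy(top, pm, params)$total) / (2 * eps)
    }
  }
  fd
}

rotation_matrix <- function(ax, angle) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
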