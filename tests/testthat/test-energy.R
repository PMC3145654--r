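test_that("bond and angle terms follow their closed forms", {
  top <- make_dimer_topology(r0 = 3.8, kb = 100)
  pos <- positions(top)
  pos[2, 1] <- pos[2, 1] + 0.1
  expect_equal(bond_energy(top, pos), 100 * 0.01, tolerance = 1e-12)
  expect_equal(bond_energy(top), 0)

  # single harmonic angle: bend the end bead by exactly 0.1 rad
  top3 <- make_dimer_topology()
  top3$beads <- rbind(top3$beads, within(top3$beads[2, ], {
    index <- 3L; resno <- 3L; x <- 7.6
  }))
  top3$bonds <- top3$bonds[0, ]
  top3$angles <- data.frame(i = 1L, j = 2L, k = 3L, theta0 = pi, ktheta = 20)
  pos <- positions(top3)
  R <- rotation_matrix(c(0, 0, 1), 0.1)
  pos[3, ] <- as.numeric(R %*% (pos[3, ] - pos[2, ])) + pos[2, ]
  expect_equal(angle_energy(top3, pos), 20 * 0.1^2, tolerance = 1e-9)
  # collinear triple handled by the clamped arccos, zero at theta0
  expect_silent(e0 <- angle_energy(top3, positions(top3)))
  expect_equal(e0, 0)
})

test_that("repulsive term is epsilon at sigma-bar and falls as r^-12", {
  top <- make_dimer_topology()
  top$bonds <- top$bonds[0, ]
  pairs <- cbind(i = 1L, j = 2L)
  sbar <- 0.9 * (1.9 + 1.9)
  pos <- positions(top)
  pos[2, ] <- c(sbar, 0, 0)
  expect_equal(repulsive_energy(top, pos, pairs), 1, tolerance = 1e-12)
  pos[2, ] <- c(2 * sbar, 0, 0)
  expect_equal(repulsive_energy(top, pos, pairs), 2^-12, tolerance = 1e-12)
  # strictly decreasing on a grid
  es <- vapply(seq(2, 12, by = 0.25), function(r) {
    pos[2, ] <- c(r, 0, 0)
    repulsive_energy(top, pos, pairs)
  }, numeric(1))
  expect_true(all(diff(es) < 0))
  # coincident beads: capped, finite, with a warning
  pos[2, ] <- pos[1, ]
  expect_warning(e0 <- repulsive_energy(top, pos, pairs), "capped")
  expect_true(is.finite(e0))
})

test_that("native 12-10 well has depth -d exactly at the native distance", {
  top <- make_dimer_topology()
  top$bonds <- top$bonds[0, ]
  top$contacts <- data.frame(i = 1L, j = 2L, r0 = 5, depth = 1.7)
  pos <- positions(top)
  pos[2, ] <- c(5, 0, 0)
  expect_equal(native_energy(top, pos), -1.7, tolerance = 1e-12)
  pos[2, ] <- c(500, 0, 0)
  expect_lt(abs(native_energy(top, pos)), 1e-8)
  # brute-force 1-D scan: the minimum sits at r0
  rs <- seq(3.5, 9, by = 0.001)
  es <- vapply(rs, function(r) {
    pos[2, ] <- c(r, 0, 0)
    native_energy(top, pos)
  }, numeric(1))
  expect_equal(rs[which.min(es)], 5, tolerance = 2e-3)
  expect_equal(min(es), -1.7, tolerance = 1e-6)
})

test_that("screened electrostatics reproduce the Debye and Bjerrum lengths", {
  # closed-form screening length vs the spec-level approximations
  expect_equal(debye_length(0.1), 9.6, tolerance = 0.02)
  expect_equal(debye_length(0.5), 4.3, tolerance = 0.02)
  # exact self-consistency: kappa^-1 scales as I^(-1/2)
  expect_equal(debye_length(0.1) / debye_length(0.4), 2, tolerance = 1e-12)

  # two unit charges at the Bjerrum length interact with exactly kT
  lb <- bjerrum_length(80, 298)
  expect_equal(lb, 7.0, tolerance = 0.01)
  top <- make_dimer_topology()
  top$bonds <- top$bonds[0, ]
  top$beads$charge <- c(1, 1)
  pos <- positions(top)
  pos[2, ] <- c(lb, 0, 0)
  prm <- electrostatics_params(I = 1e-15, epsilon_r = 80, temperature = 298)
  v_eps <- debye_huckel_energy(top, pos, prm, pairs = cbind(1L, 2L))
  kT_eps <- 1.380649e-23 * 298 * 6.02214076e23 / 4184 / 0.6  # kT in epsilon
  expect_equal(v_eps / kT_eps, 1.0, tolerance = 1e-6)
})

test_that("electrostatics has the Coulomb limit, correct signs and screening", {
  top <- make_dimer_topology()
  top$bonds <- top$bonds[0, ]
  pos <- positions(top)
  pos[2, ] <- c(8, 0, 0)
  pairs <- cbind(1L, 2L)
  # opposite charges attract, like charges repel
  top$beads$charge <- c(1, -1)
  expect_lt(debye_huckel_energy(top, pos, electrostatics_params(0.1), pairs), 0)
  top$beads$charge <- c(1, 1)
  expect_gt(debye_huckel_energy(top, pos, electrostatics_params(0.1), pairs), 0)
  # Coulomb limit as I -> 0
  v_lo <- debye_huckel_energy(top, pos, electrostatics_params(1e-13), pairs)
  v_coul <- (332.06371 / (80 * 8)) / 0.6
  expect_equal(v_lo, v_coul, tolerance = 1e-6)
  # |V| monotone decreasing in ionic strength
  vs <- vapply(c(0.01, 0.05, 0.1, 0.5, 1, 2), function(I) {
    abs(debye_huckel_energy(top, pos, electrostatics_params(I), pairs))
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
  expect_error(electrostatics_params(I = -1), "ionic")
})

test_that("crowder interactions follow the excluded-volume form with 55 A spheres", {
  atoms <- make_ideal_helix(5)
  top <- coarse_grain(atoms)
  expect_equal(crowder_energy(top)$crowder_protein, 0)
  # two crowders at centre separation 110 A (touching): E = (0.9 * 110 / 110)^12
  cent <- matrix(c(100, 100, 100, 210, 100, 100), 2, 3, byrow = TRUE)
  attr(cent, "radius") <- 55
  top <- add_crowders(top, cent, box = 1140)
  pos <- positions(top)
  ce <- crowder_energy(top, pos)
  expect_equal(ce$crowder_crowder, 0.9^12, tolerance = 1e-12)
  # periodicity: translating everything by a box vector changes nothing
  pos2 <- pos + 1140
  ce2 <- crowder_energy(top, pos2)
  expect_equal(ce2$crowder_crowder, ce$crowder_crowder, tolerance = 1e-12)
  expect_equal(ce2$crowder_protein, ce$crowder_protein, tolerance = 1e-10)
})

test_that("all terms are invariant under rigid rotation and translation", {
  top <- make_random_test_system(8, seed = 3)
  prm <- electrostatics_params(I = 0.15)
  set.seed(4)
  pos <- positions(top) + matrix(stats::rnorm(3 * nrow(top$beads), sd = 0.3),
                                 ncol = 3)
  e1 <- total_energy(top, pos, prm)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  pos2 <- pos %*% t(R) + matrix(c(5, -3, 11), nrow(pos), 3, byrow = TRUE)
  e2 <- total_energy(top, pos2, prm)
  for (nm in names(unclass(e1))) {
    expect_equal(e2[[nm]], e1[[nm]], tolerance = 1e-8)
  }
})

test_that("the energy decomposition matches a naive double-loop oracle", {
  for (seed in 1:3) {
    top <- make_random_test_system(7, seed = seed, box = 60, crowders = 2)
    prm <- electrostatics_params(I = 0.1, cutoff = 30)
    set.seed(seed + 100)
    pos <- positions(top) + matrix(stats::rnorm(3 * nrow(top$beads), sd = 0.25),
                                   ncol = 3)
    got <- total_energy(top, pos, prm)
    want <- oracle_energy(top, pos, prm)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                   label = paste("term", nm, "seed", seed))
    }
    # components sum to the reported total
    terms <- unlist(unclass(got))
    expect_equal(unname(terms["total"]),
                 sum(terms[names(terms) != "total"]), tolerance = 1e-12)
  }
})

test_that("raising the ionic strength never increases the screened energy magnitude", {
  top <- make_random_test_system(8, seed = 9)
  pos <- positions(top)
  pl <- build_pair_lists(top)
  v1 <- abs(debye_huckel_energy(top, pos, electrostatics_params(0.1), pl$charged))
  v2 <- abs(debye_huckel_energy(top, pos, electrostatics_params(0.2), pl$charged))
  expect_lte(v2, v1)
})
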