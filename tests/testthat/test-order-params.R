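test_that("radius of gyration matches hand calculations", {
  expect_equal(radius_of_gyration(matrix(1, 4, 3)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1.0)
  # mass weighting: heavy bead pulls the centre
  expect_lt(radius_of_gyration(two, masses = c(9, 1)),
            radius_of_gyration(two))
  set.seed(1)
  cloud <- matrix(stats::rnorm(60), 20, 3)
  R <- rotation_matrix(c(1, 1, 0), 1.1)
  expect_equal(radius_of_gyration(cloud %*% t(R)), radius_of_gyration(cloud),
               tolerance = 1e-12)
})

test_that("asphericity is 0 for a sphere-symmetric set and 1 for a rod", {
  tet <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
                byrow = TRUE)
  expect_equal(asphericity(tet), 0, tolerance = 1e-12)
  rod <- cbind(seq(0, 10, length.out = 11), 0, 0)
  expect_equal(asphericity(rod), 1, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    d <- asphericity(matrix(stats::rnorm(45), 15, 3))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("structural overlap obeys its identities and a brute-force oracle", {
  cam <- make_synthetic_cam(holo = FALSE)
  top <- cam$top
  prot <- top$beads$kind %in% c("CA", "SC")
  ref <- positions(top)[prot, ]
  resno <- top$beads$resno[prot]
  expect_equal(overlap_chi(ref, ref, resno), 0)
  # every pair displaced beyond tolerance
  scrambled <- ref * 5
  expect_equal(overlap_chi(scrambled, ref, resno, tolerance = 2), 1)
  expect_error(overlap_chi(ref[-1, ], ref, resno), "bead counts")

  # independent double-loop evaluation on a 20-bead fixture
  small <- make_random_test_system(10, seed = 5)
  p_ref <- positions(small)
  set.seed(6)
  p <- p_ref + matrix(stats::rnorm(length(p_ref), sd = 1.2), ncol = 3)
  rn <- small$beads$resno
  tol <- 2
  hits <- 0; m <- 0
  for (i in 1:(nrow(p) - 1)) {
    for (j in (i + 1):nrow(p)) {
      if (abs(rn[i] - rn[j]) < 2) next
      m <- m + 1
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      d0 <- sqrt(sum((p_ref[i, ] - p_ref[j, ])^2))
      if (abs(d - d0) < tol) hits <- hits + 1
    }
  }
  expect_equal(overlap_chi(p, p_ref, rn, tol), 1 - hits / m,
               tolerance = 1e-12)
})

test_that("helicity separates helix, coil and mixed fixtures", {
  hel <- make_ideal_helix(18)
  ca <- as.matrix(hel[hel$elety == "CA", c("x", "y", "z")])
  expect_equal(helicity(ca), 1.0)
  ext <- make_extended_chain(18)
  ca_e <- as.matrix(ext[ext$elety == "CA", c("x", "y", "z")])
  expect_equal(helicity(ca_e), 0.0)
  # helix-loop-helix: interior loop residues break both criteria
  hlh <- make_helix_loop_helix(90, n_helix = 10, n_loop = 5)
  ca_m <- as.matrix(hlh[hlh$elety == "CA", c("x", "y", "z")])
  frac <- helicity(ca_m)
  # hand count on the same geometry
  n <- nrow(ca_m)
  cnt <- 0; denom <- 0
  for (i in 2:(n - 4)) {
    phi <- cgcam:::.dihedral(ca_m, i - 1, i, i + 1, i + 2) * 180 / pi
    d14 <- sqrt(sum((ca_m[i, ] - ca_m[i + 4, ])^2))
    denom <- denom + 1
    if (phi >= 30 && phi <= 80 && d14 < 6.5) cnt <- cnt + 1
  }
  expect_equal(frac, cnt / denom, tolerance = 1e-12)
  expect_gt(frac, 0.3); expect_lt(frac, 0.95)
})

test_that("EF-hand angles recover constructed interhelix geometry", {
  for (ang in c(90, 180)) {
    hlh <- make_helix_loop_helix(ang)
    top <- coarse_grain(hlh)
    ca <- positions(top)[top$beads$kind == "CA", ]
    ann <- helix_annotation(attr(hlh, "helix"), pairs = list(AB = c("A", "B")))
    got <- ef_hand_angle(ca, "A", "B", ann,
                         top$beads$resno[top$beads$kind == "CA"])
    expect_equal(got, ang, tolerance = 2)
  }
  # degenerate helix vector is refused
  flat <- matrix(0, 10, 3)
  expect_error(ef_hand_angle(flat, 1:5, 6:10), "zero-length")
})

test_that("contact indicators and probabilities follow their definitions", {
  cam <- make_synthetic_cam(holo = FALSE)
  top <- build_native_contacts(cam$atoms, cam$top, cutoff = 5.5)
  # nonnative candidates: pairs far apart in the reference
  defs <- contact_definitions(top, nonnative = "sidechain", min_seq_sep = 40)
  pos <- positions(top)
  q_ref <- contact_states(pos, defs)
  expect_true(all(q_ref[defs$type == "native"] == 1))
  expect_true(all(q_ref[defs$type == "nonnative"] == 0))
  expect_true(all(contact_states(pos * 10, defs) == 0))
  # double-loop oracle
  r <- sqrt(rowSums((pos[defs$i, ] - pos[defs$j, ])^2))
  manual <- ifelse(defs$type == "native", r < 1.2 * defs$r0, r < 8)
  expect_equal(q_ref, as.integer(manual))
  # two frames, formed and unformed, give probability one half
  q <- contact_q_matrix(list(pos, pos * 10), defs)
  cm <- contact_probability_matrix(q, defs)
  expect_true(all(cm$defs$probability[defs$type == "native"] == 0.5))
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1, na.rm = TRUE))
  # native contacts land in the upper triangle, nonnative in the lower
  nat <- cm$defs[cm$defs$type == "native", ][1, ]
  expect_false(is.na(cm$matrix[min(nat$resno_i, nat$resno_j),
                               max(nat$resno_i, nat$resno_j)]))
})

test_that("contact probabilities match analytic Bernoulli means", {
  set.seed(3)
  p_true <- c(0.2, 0.5, 0.9)
  q <- vapply(p_true, function(p) stats::rbinom(5000, 1, p),
              integer(5000))
  defs <- data.frame(cpi = 1:3, i = 1:3, j = 4:6, resno_i = 1:3,
                     resno_j = 4:6, class = "b", type = "native", r0 = 5)
  cm <- contact_probability_matrix(q, defs)
  expect_equal(cm$defs$probability, p_true, tolerance = 0.03)
})

test_that("contact covariance is the Pearson correlation of the indicators", {
  set.seed(4)
  a <- stats::rbinom(10000, 1, 0.5)
  b <- stats::rbinom(10000, 1, 0.5)
  q <- cbind(a, 1L - a, a, b, rep(1L, length(a)))
  cv <- contact_covariance(q)
  expect_equal(cv[1, 3], 1.0)
  expect_equal(cv[1, 2], -1.0)
  expect_lt(abs(cv[1, 4]), 0.05)          # independent streams decorrelate
  expect_true(all(is.na(cv[5, ])))        # constant contact flagged
  expect_equal(attr(cv, "constant"), 5L, ignore_attr = TRUE)
  sub <- cv[1:4, 1:4]
  expect_equal(sub, t(sub))
  expect_equal(unname(diag(sub)), rep(1, 4))
  ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)               # PSD up to estimator noise
})

test_that("free-energy surfaces and basin populations are consistent", {
  set.seed(9)
  # two-cluster synthetic ensemble with a 70/30 split
  n <- 4000
  in_m1 <- stats::runif(n) < 0.7
  chi <- ifelse(in_m1, stats::runif(n, 0.12, 0.28), stats::runif(n, 0.31, 0.39))
  delta <- ifelse(in_m1, stats::runif(n, 0.282, 0.298), stats::runif(n, 0.04, 0.14))
  basins <- cam_basins()
  p1 <- basin_population(chi, delta, basins$M1)
  p2 <- basin_population(chi, delta, basins$M2)
  expect_equal(p1, 0.7, tolerance = 0.03)
  expect_equal(p2, 0.3, tolerance = 0.03)
  expect_equal(p1 + p2, 1.0)
  expect_equal(basin_population(chi[in_m1], delta[in_m1], basins$M1), 1.0)
  expect_error(basin_population(numeric(0), numeric(0), basins$M1), "empty")

  fes <- free_energy_surface(chi, delta, kT = 1.15)
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  expect_equal(sum(fes$counts), n)
  expect_true(anyNA(fes$F))               # unvisited bins stay empty
  # boundary convention: lower edge inclusive, upper exclusive
  expect_equal(basin_population(0.1, 0.28, basins$M1), 1.0)
  expect_equal(basin_population(0.3, 0.29, basins$M1), 0.0)
})
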