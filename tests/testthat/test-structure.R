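test_that("written structures round-trip through the PDB parser", {
  h <- make_ideal_helix(3 + 2)  # minimum helix size, use first 3 residues
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, f)
  h2 <- parse_structure(f)
  expect_equal(length(unique(h2$resno)), 5)
  expect_equal(sum(h2$elety == "CA"), 5)
  expect_lt(max(abs(as.matrix(h[, c("x", "y", "z")]) -
                      as.matrix(h2[, c("x", "y", "z")]))), 1e-3)
  expect_equal(attr(h2, "helix")$start, 1L)
  expect_equal(attr(h2, "helix")$end, 5L)
})

test_that("only the first model of a multi-model file is read", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      12.800   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  atoms <- parse_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$x, c(0, 3.8))
})

test_that("alternate locations resolve to the highest occupancy copy", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  atoms <- parse_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$x[atoms$resno == 1], 5.0)
})

test_that("degenerate PDB inputs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  file.create(f)
  expect_error(parse_structure(f), "empty")
  # residue without a C-alpha
  bad <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  expect_error(parse_structure(paste(bad, collapse = "\n")), "C-alpha")
  ins <- c(
    "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C",
    "END")
  expect_error(parse_structure(paste(ins, collapse = "\n")), "insertion")
})

test_that("glycine residues carry no side-chain bead", {
  atoms <- make_extended_chain(10, sequence = "AAGAAGAAAA")
  top <- coarse_grain(atoms)
  expect_equal(nrow(top$beads), 2 * 10 - 2)
  expect_equal(sum(top$beads$kind == "SC" & top$beads$resid == "GLY"), 0)
})

test_that("coarse graining builds the two-bead topology with measured geometry", {
  atoms <- make_ideal_helix(10)
  top <- coarse_grain(atoms)
  expect_equal(nrow(top$beads), 20)
  ca_ca <- top$bonds[top$beads$kind[top$bonds$i] == "CA" &
                       top$beads$kind[top$bonds$j] == "CA", ]
  ca_sc <- top$bonds[top$beads$kind[top$bonds$j] == "SC", ]
  expect_equal(nrow(ca_ca), 9)
  expect_equal(nrow(ca_sc), 10)
  expect_true(all(top$bonds$kb == 100))
  expect_true(all(top$angles$ktheta == 20))
  # r0 reproduces the input geometry exactly
  pos <- positions(top)
  for (r in seq_len(nrow(top$bonds))) {
    d <- sqrt(sum((pos[top$bonds$i[r], ] - pos[top$bonds$j[r], ])^2))
    expect_lt(abs(d - top$bonds$r0[r]), 1e-6)
  }
  # reference conformation has zero bonded energy
  expect_equal(bond_energy(top), 0, tolerance = 1e-12)
  expect_equal(angle_energy(top), 0, tolerance = 1e-12)
  expect_equal(dihedral_energy(top), 0, tolerance = 1e-12)
})

test_that("unknown residue types without a radius entry are rejected", {
  atoms <- make_ideal_helix(5)
  atoms$resid[atoms$resno == 3] <- "XYZ"
  expect_error(coarse_grain(atoms), "radius")
})

test_that("calcium attachment reproduces the EF-hand connectivity", {
  cam <- make_synthetic_cam(holo = TRUE)
  top <- cam$top
  expect_equal(sum(top$beads$kind == "CALCIUM"), 4)
  is_ca_bond <- top$beads$kind[top$bonds$i] == "CALCIUM" |
    top$beads$kind[top$bonds$j] == "CALCIUM"
  expect_equal(sum(is_ca_bond), 15)  # 4 + 4 + 3 + 4 ligands
  is_ca_angle <- top$beads$kind[top$angles$j] == "CALCIUM"
  expect_equal(sum(is_ca_angle), choose(4, 2) * 3 + choose(3, 2))
  # crystal-geometry rest state: all calcium bonded terms vanish
  expect_equal(bond_energy(top), 0, tolerance = 1e-12)
  expect_equal(angle_energy(top), 0, tolerance = 1e-10)
})

test_that("mini EF-hand fixture gets 3 calcium bonds and 3 angle terms", {
  ef <- make_mini_efhand(90)
  top <- coarse_grain(ef$atoms)
  top <- attach_calcium(top, connectivity = ef$connectivity,
                        calcium_positions = ef$calcium)
  is_ca_bond <- top$beads$kind[top$bonds$i] == "CALCIUM" |
    top$beads$kind[top$bonds$j] == "CALCIUM"
  expect_equal(sum(is_ca_bond), 3)
  expect_equal(sum(top$beads$kind[top$angles$j] == "CALCIUM"), 3)
  expect_error(
    attach_calcium(coarse_grain(ef$atoms), connectivity = list(CA1 = 999L),
                   calcium_positions = ef$calcium),
    "999")
})

test_that("fallback formal charges give calmodulin its net charge of -24", {
  cam <- make_synthetic_cam(holo = FALSE)
  expect_equal(sum(cam$top$beads$charge), -24)
  expect_equal(sum(cam$top$beads$charge[cam$top$beads$kind == "CA"]), 0)
  # all-glycine chain is neutral
  gly <- coarse_grain(make_extended_chain(6, sequence = "GGGGGG"))
  expect_equal(sum(assign_charges(gly)$beads$charge), 0)
})

test_that("explicit charge tables round-trip and conserve total charge", {
  atoms <- make_ideal_helix(6, sequence = "ADKLEF")
  top <- coarse_grain(atoms)
  tab <- data.frame(resnum = 1:6,
                    resname = aa_three("ADKLEF"),
                    q_backbone = round(stats::runif(6, -0.3, 0.3), 3),
                    q_sidechain = round(stats::runif(6, -1, 1), 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_charge_table(tab, f)
  tab2 <- read_charge_table(f)
  expect_equal(tab2, tab)
  top <- assign_charges(top, tab2)
  expect_equal(sum(top$beads$charge),
               sum(tab$q_backbone) + sum(tab$q_sidechain))
  # table of the wrong length is rejected
  expect_error(assign_charges(top, tab[1:4, ]), "residues")
})

test_that("native contacts follow the heavy-atom cutoff definition", {
  ext <- make_extended_chain(12)
  top_e <- build_native_contacts(ext, coarse_grain(ext), cutoff = 4.5)
  expect_equal(nrow(top_e$contacts), 0)

  hel <- make_ideal_helix(12)
  top_h <- build_native_contacts(hel, coarse_grain(hel), cutoff = 6)
  expect_gt(nrow(top_h$contacts), 0)
  sep <- abs(top_h$beads$resno[top_h$contacts$i] -
               top_h$beads$resno[top_h$contacts$j])
  expect_true(all(sep %in% c(3, 4)))  # local helical geometry only
  # no duplicates, canonical ordering
  expect_true(all(top_h$contacts$i < top_h$contacts$j))
  expect_false(any(duplicated(top_h$contacts[, c("i", "j")])))
  # widening the cutoff never loses contacts
  top_w <- build_native_contacts(hel, coarse_grain(hel), cutoff = 12)
  expect_gte(nrow(top_w$contacts), nrow(top_h$contacts))
  expect_error(build_native_contacts(hel, coarse_grain(hel), cutoff = -1),
               "cutoff")
})

test_that("topologies serialize to JSON and back", {
  cam <- make_synthetic_cam(holo = TRUE)
  top <- build_native_contacts(cam$atoms, cam$top, cutoff = 5.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_topology(top, f)
  top2 <- read_topology(f)
  expect_equal(top2$beads$charge, top$beads$charge)
  expect_equal(top2$bonds$r0, top$bonds$r0)
  expect_equal(nrow(top2$contacts), nrow(top$contacts))
  expect_equal(total_energy(top2)$total, total_energy(top)$total,
               tolerance = 1e-12)
})
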