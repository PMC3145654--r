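#' Coarse-grain a structure into the two-bead side-chain C-alpha model
#'
#' Builds the side-chain C-alpha (SCM) representation: one backbone bead at
#' each C-alpha position and, for every non-glycine residue, one side-chain
#' bead at the centroid of the side-chain heavy atoms.  Bonded terms are
#' harmonic springs `k_b (r - r0)^2` between consecutive backbone beads and
#' between each backbone bead and its side-chain bead, harmonic angle terms
#' `k_theta (theta - theta0)^2` for consecutive bead triples, and a
#' 1-fold + 3-fold cosine dihedral series on the backbone.  All reference
#' values `r0`, `theta0`, `phi0` are measured from the input coordinates, so
#' the bonded energy of the input conformation is exactly zero.
#'
#' @param atoms an `atom_records` table from [parse_structure()] or a fixture
#'   generator.
#' @param radii named radius table, see [bead_radii()].
#' @param k_bond bond spring constant in units of epsilon (default 100).
#' @param k_angle angle constant in units of epsilon (default 20).
#' @param k_dihedral length-2 numeric: coefficients of the 1-fold and 3-fold
#'   cosine terms, units of epsilon.
#' @param dihedral_disable integer vector of residue numbers whose backbone
#'   dihedrals are disabled (used for re-inserted terminal residues, whose
#'   polymeric flexibility is preserved by zeroing those terms).
#' @return A `cg_topology`: list with data.frames `beads` (index, kind,
#'   resno, resid, x, y, z, sigma, mass, charge), `bonds` (i, j, r0, kb),
#'   `angles` (i, j, k, theta0, ktheta), `dihedrals` (i, j, k, l, phi0, k1,
#'   k3, enabled), `contacts` (empty until [build_native_contacts()]), and
#'   `calcium` bookkeeping.
#' @export
coarse_grain <- function(atoms, radii = bead_radii(), k_bond = 100,
                         k_angle = 20, k_dihedral = c(1.0, 0.5),
                         dihedral_disable = integer()) {
  prot <- atoms[atoms$type == "ATOM", , drop = FALSE]
  resnos <- unique(prot$resno)
  if (is.unsorted(resnos)) stop("residue numbers must be ordered")

  beads <- list()
  for (rn in resnos) {
    sub <- prot[prot$resno == rn, , drop = FALSE]
    resid <- sub$resid[1]
    ca <- sub[sub$elety == "CA", , drop = FALSE][1, ]
    if (!(resid %in% names(radii)) && resid != "GLY") {
      stop("configuration error: no radius entry for residue type ", resid)
    }
    beads[[length(beads) + 1]] <- data.frame(
      kind = "CA", resno = rn, resid = resid,
      x = ca$x, y = ca$y, z = ca$z,
      sigma = unname(radii["CA_BEAD"]), stringsAsFactors = FALSE
    )
    if (resid != "GLY") {
      sc <- .sidechain_atoms(atoms, rn)
      if (nrow(sc) == 0) {
        stop("structural error: residue ", resid, rn,
             " is not glycine but has no side-chain heavy atoms")
      }
      cen <- colMeans(sc[, c("x", "y", "z")])
      beads[[length(beads) + 1]] <- data.frame(
        kind = "SC", resno = rn, resid = resid,
        x = cen[1], y = cen[2], z = cen[3],
        sigma = unname(radii[resid]), stringsAsFactors = FALSE
      )
    }
  }
  beads <- do.call(rbind, beads)
  beads$index <- seq_len(nrow(beads))
  beads$mass <- 1
  beads$charge <- 0
  beads <- beads[, c("index", "kind", "resno", "resid", "x", "y", "z",
                     "sigma", "mass", "charge")]
  rownames(beads) <- NULL

  pos <- as.matrix(beads[, c("x", "y", "z")])
  ca_idx <- beads$index[beads$kind == "CA"]
  sc_of <- function(rn) {
    i <- beads$index[beads$kind == "SC" & beads$resno == rn]
    if (length(i)) i else NA_integer_
  }

  bonds <- list()
  for (a in seq_len(length(ca_idx) - 1)) {
    i <- ca_idx[a]; j <- ca_idx[a + 1]
    bonds[[length(bonds) + 1]] <- data.frame(i = i, j = j,
                                             r0 = .bond_length(pos, i, j),
                                             kb = k_bond)
  }
  for (rn in resnos) {
    s <- sc_of(rn)
    if (!is.na(s)) {
      i <- beads$index[beads$kind == "CA" & beads$resno == rn]
      bonds[[length(bonds) + 1]] <- data.frame(i = i, j = s,
                                               r0 = .bond_length(pos, i, s),
                                               kb = k_bond)
    }
  }
  bonds <- do.call(rbind, bonds)

  angles <- list()
  add_angle <- function(i, j, k) {
    angles[[length(angles) + 1]] <<- data.frame(
      i = i, j = j, k = k, theta0 = .bond_angle(pos, i, j, k),
      ktheta = k_angle)
  }
  n_res <- length(ca_idx)
  for (a in seq_len(n_res)) {
    rn <- resnos[a]
    s <- sc_of(rn)
    if (a >= 2 && a <= n_res - 1) add_angle(ca_idx[a - 1], ca_idx[a], ca_idx[a + 1])
    if (!is.na(s)) {
      if (a >= 2) add_angle(ca_idx[a - 1], ca_idx[a], s)
      if (a <= n_res - 1) add_angle(s, ca_idx[a], ca_idx[a + 1])
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), ktheta = numeric())

  dihedrals <- list()
  if (n_res >= 4) {
    for (a in seq_len(n_res - 3)) {
      idx <- ca_idx[a:(a + 3)]
      rset <- resnos[a:(a + 3)]
      dihedrals[[length(dihedrals) + 1]] <- data.frame(
        i = idx[1], j = idx[2], k = idx[3], l = idx[4],
        phi0 = .dihedral(pos, idx[1], idx[2], idx[3], idx[4]),
        k1 = k_dihedral[1], k3 = k_dihedral[2],
        enabled = !any(rset %in% dihedral_disable)
      )
    }
  }
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               phi0 = numeric(), k1 = numeric(), k3 = numeric(),
               enabled = logical())

  top <- list(
    beads = beads, bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = data.frame(i = integer(), j = integer(), r0 = numeric(),
                          depth = numeric()),
    calcium = list(), box = NA_real_
  )
  class(top) <- "cg_topology"
  top
}

#' @export
print.cg_topology <- function(x, ...) {
  k <- table(factor(x$beads$kind, c("CA", "SC", "CALCIUM", "CROWDER")))
  cat("<cg_topology> ", nrow(x$beads), " beads (",
      paste(names(k), k, sep = ":", collapse = " "), ")\n",
      "  bonds: ", nrow(x$bonds), "  angles: ", nrow(x$angles),
      "  dihedrals: ", nrow(x$dihedrals),
      "  native contacts: ", nrow(x$contacts), "\n", sep = "")
  invisible(x)
}

#' Attach calcium beads to the EF-hand ligand residues
#'
#' Adds one bead per calcium ion and ties it by springs (`k_b (r - r0)^2`)
#' to the side-chain beads of the listed acidic residues, plus harmonic
#' angle terms for every (ligand, calcium, ligand) triple.  Reference bond
#' lengths and angles are measured from the supplied calcium coordinates, so
#' the crystal-geometry conformation has zero calcium bonded energy.
#' Nonbonded interactions of calcium beads are strictly repulsive and the
#' beads carry no Debye-Hueckel charge.
#'
#' @param top a `cg_topology` from [coarse_grain()].
#' @param atoms optional `atom_records` containing the calcium ions as
#'   HETATM records (residue name `CA`); used when `calcium_positions` is
#'   not given.
#' @param connectivity named list: for each calcium, the residue numbers it
#'   is attached to (default [cam_calcium_sites()]).
#' @param calcium_positions optional matrix (n_ca x 3) of calcium
#'   coordinates, overriding `atoms`.
#' @param radius calcium bead radius (Angstrom).
#' @param k_bond,k_angle spring constants (epsilon units).
#' @return The augmented `cg_topology`.
#' @export
attach_calcium <- function(top, atoms = NULL,
                           connectivity = cam_calcium_sites(),
                           calcium_positions = NULL, radius = 1.7,
                           k_bond = 100, k_angle = 20) {
  if (is.null(calcium_positions)) {
    if (is.null(atoms)) stop("need either atoms or calcium_positions")
    het <- atoms[atoms$type == "HETATM" & atoms$resid %in% c("CA", "CA2"),
                 , drop = FALSE]
    if (nrow(het) < length(connectivity)) {
      stop("structure has ", nrow(het), " calcium ions but connectivity lists ",
           length(connectivity))
    }
    calcium_positions <- as.matrix(het[seq_along(connectivity),
                                       c("x", "y", "z")])
  }
  calcium_positions <- matrix(calcium_positions, ncol = 3)
  stopifnot(nrow(calcium_positions) == length(connectivity))

  beads <- top$beads
  for (m in seq_along(connectivity)) {
    ligs <- connectivity[[m]]
    sc <- vapply(ligs, function(rn) {
      i <- beads$index[beads$kind == "SC" & beads$resno == rn]
      if (!length(i)) stop("connectivity error: residue ", rn,
                           " has no side-chain bead in this topology")
      i
    }, integer(1))

    ca_bead <- data.frame(
      index = nrow(beads) + 1L, kind = "CALCIUM", resno = NA_integer_,
      resid = "CAL", x = calcium_positions[m, 1], y = calcium_positions[m, 2],
      z = calcium_positions[m, 3], sigma = radius, mass = 1, charge = 0,
      stringsAsFactors = FALSE
    )
    beads <- rbind(beads, ca_bead)
    pos <- as.matrix(beads[, c("x", "y", "z")])
    mi <- ca_bead$index

    for (s in sc) {
      top$bonds <- rbind(top$bonds, data.frame(
        i = mi, j = s, r0 = .bond_length(pos, mi, s), kb = k_bond))
    }
    if (length(sc) >= 2) {
      prs <- utils::combn(sc, 2)
      for (cidx in seq_len(ncol(prs))) {
        i <- prs[1, cidx]; j <- prs[2, cidx]
        top$angles <- rbind(top$angles, data.frame(
          i = i, j = mi, k = j, theta0 = .bond_angle(pos, i, mi, j),
          ktheta = k_angle))
      }
    }
    top$calcium[[names(connectivity)[m] %||% paste0("CA", m)]] <- sc
  }
  top$beads <- beads
  top
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Assign partial charges to the beads
#'
#' With an explicit charge table (columns `resnum`, `resname`, `q_backbone`,
#' `q_sidechain`, elementary-charge units) each backbone bead carries the
#' summed backbone charge of its residue and each side-chain bead the summed
#' side-chain charge.  In fallback mode formal charges are used: Asp/Glu
#' side chains -1, Lys/Arg side chains +1, all other beads 0; the termini
#' are neutral, matching chemically capped termini.
#'
#' @param top a `cg_topology`.
#' @param table optional charge table (data.frame as above, or a file path
#'   readable by [read_charge_table()]).
#' @return The topology with the `charge` column filled; calcium and crowder
#'   beads always carry zero charge.
#' @export
assign_charges <- function(top, table = NULL) {
  beads <- top$beads
  beads$charge <- 0
  if (is.null(table)) {
    neg <- beads$kind == "SC" & beads$resid %in% c("ASP", "GLU")
    pos <- beads$kind == "SC" & beads$resid %in% c("LYS", "ARG")
    beads$charge[neg] <- -1
    beads$charge[pos] <- 1
  } else {
    if (is.character(table)) table <- read_charge_table(table)
    res <- unique(beads$resno[beads$kind %in% c("CA", "SC")])
    if (!setequal(res, table$resnum)) {
      stop("charge table covers ", nrow(table),
           " residues but the topology has ", length(res))
    }
    for (r in seq_len(nrow(table))) {
      rn <- table$resnum[r]
      beads$charge[beads$kind == "CA" & beads$resno == rn] <- table$q_backbone[r]
      beads$charge[beads$kind == "SC" & beads$resno == rn] <- table$q_sidechain[r]
    }
  }
  beads$charge[beads$kind %in% c("CALCIUM", "CROWDER")] <- 0
  top$beads <- beads
  top
}

#' Read / write a per-residue charge table
#'
#' Tab-delimited text with columns `resnum resname q_backbone q_sidechain`
#' and `#` comment lines; charges in elementary-charge units.
#'
#' @param file path.
#' @return `read_charge_table`: a data.frame with the four columns.
#' @export
read_charge_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("resnum", "resname", "q_backbone", "q_sidechain")
  if (!all(need %in% names(tab))) {
    stop("charge table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(tab$q_backbone)) || any(!is.finite(tab$q_sidechain))) {
    stop("charge table contains non-finite charges")
  }
  tab[, need]
}

#' @rdname read_charge_table
#' @param table data.frame with the four columns.
#' @export
write_charge_table <- function(table, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# per-residue partial charges, elementary-charge units", con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Build the native-contact list from a reference structure
#'
#' A residue pair with sequence separation >= `min_seq_sep` forms a native
#' side-chain contact when the minimum distance between their side-chain
#' heavy atoms in the reference structure is below `cutoff`, and a native
#' backbone contact when their backbone heavy atoms come that close.  Each
#' contact stores the reference bead-bead distance and a well depth from the
#' chosen depth model.
#'
#' @param atoms the reference `atom_records`.
#' @param top the matching `cg_topology`.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param min_seq_sep minimum residue separation (default 3).
#' @param depth_model `"uniform"` (every well `eps` deep) or a function
#'   `(resid_i, resid_j) -> depth` implementing a residue-pair statistical
#'   potential.
#' @param eps uniform well depth (epsilon units).
#' @return The topology with its `contacts` table filled (columns `i`, `j`,
#'   `r0`, `depth`, `class` in `"b"`/`"h"` for side-chain/backbone).
#' @export
build_native_contacts <- function(atoms, top, cutoff = 4.5, min_seq_sep = 3,
                                  depth_model = "uniform", eps = 1) {
  if (cutoff <= 0) stop("parameter error: cutoff must be positive")
  beads <- top$beads
  resnos <- unique(beads$resno[beads$kind == "CA"])
  depth_fn <- if (is.function(depth_model)) depth_model else
    function(a, b) eps

  sc_atoms <- lapply(resnos, function(rn) as.matrix(
    .sidechain_atoms(atoms, rn)[, c("x", "y", "z"), drop = FALSE]))
  bb_atoms <- lapply(resnos, function(rn) as.matrix(
    .backbone_atoms(atoms, rn)[, c("x", "y", "z"), drop = FALSE]))
  names(sc_atoms) <- names(bb_atoms) <- resnos

  bead_of <- function(kind, rn) {
    i <- beads$index[beads$kind == kind & beads$resno == rn]
    if (length(i)) i else NA_integer_
  }
  min_dist <- function(A, B) {
    if (nrow(A) == 0 || nrow(B) == 0) return(Inf)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }

  pos <- positions(top)
  out <- list()
  nr <- length(resnos)
  for (a in seq_len(nr - 1)) {
    for (b in (a + 1):nr) {
      if (resnos[b] - resnos[a] < min_seq_sep) next
      ra <- as.character(resnos[a]); rb <- as.character(resnos[b])
      if (min_dist(sc_atoms[[ra]], sc_atoms[[rb]]) < cutoff) {
        i <- bead_of("SC", resnos[a]); j <- bead_of("SC", resnos[b])
        if (!is.na(i) && !is.na(j)) {
          out[[length(out) + 1]] <- data.frame(
            i = i, j = j, r0 = .bond_length(pos, i, j),
            depth = depth_fn(beads$resid[i], beads$resid[j]), class = "b")
        }
      }
      if (min_dist(bb_atoms[[ra]], bb_atoms[[rb]]) < cutoff) {
        i <- bead_of("CA", resnos[a]); j <- bead_of("CA", resnos[b])
        out[[length(out) + 1]] <- data.frame(
          i = i, j = j, r0 = .bond_length(pos, i, j),
          depth = depth_fn(beads$resid[i], beads$resid[j]), class = "h")
      }
    }
  }
  contacts <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), r0 = numeric(),
               depth = numeric(), class = character())
  # canonical ordering, no duplicates
  if (nrow(contacts)) {
    sw <- contacts$i > contacts$j
    tmp <- contacts$i[sw]; contacts$i[sw] <- contacts$j[sw]; contacts$j[sw] <- tmp
    contacts <- contacts[!duplicated(contacts[, c("i", "j")]), , drop = FALSE]
    rownames(contacts) <- NULL
  }
  top$contacts <- contacts
  top
}

#' Serialize a topology to structured text
#'
#' Writes/reads the full topology (beads, bonded terms, contacts, calcium
#' bookkeeping) as JSON for reproducibility.
#'
#' @param top a `cg_topology`.
#' @param file path.
#' @export
write_topology <- function(top, file) {
  obj <- unclass(top)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(file)
}

#' @rdname write_topology
#' @export
read_topology <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  obj$calcium <- lapply(obj$calcium, as.integer)
  obj$box <- obj$box %||% NA_real_
  if (is.null(obj$contacts) || length(obj$contacts) == 0) {
    obj$contacts <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                               depth = numeric())
  }
  class(obj) <- "cg_topology"
  obj
}
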