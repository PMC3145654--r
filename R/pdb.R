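#' Parse a protein structure in PDB format
#'
#' Reads a PDB file (or raw PDB text) into a flat atom table.  Only the first
#' model of a multi-model file is kept, alternate locations are resolved to
#' the highest-occupancy copy, and HELIX records are retained as an
#' annotation attribute.  Calcium ions stored as HETATM records are kept so
#' that the calcium-bound topology can be built from the same file.
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @return An object of class `atom_records`: a data.frame with columns
#'   `eleno`, `elety` (atom name), `resid` (residue name), `resno`, `chain`,
#'   `x`, `y`, `z`, `occ`, `type` ("ATOM"/"HETATM"), and attribute `helix`
#'   (data.frame `helix`, `start`, `end`) built from HELIX records.
#' @export
parse_structure <- function(file) {
  path <- file
  if (length(file) > 1 || any(grepl("\n", file))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(file, "\n")), path)
    on.exit(unlink(path))
  }
  if (!file.exists(path)) stop("no such PDB file: ", path)
  if (file.size(path) == 0) stop("PDB format error: empty file")

  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("PDB format error: no atom records")

  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(trimws(ins)))) {
    stop("insertion codes are not supported; renumber the structure first")
  }

  # alternate locations: keep the highest-occupancy copy of each atom
  alt <- at$alt
  if (any(!is.na(alt) & nzchar(trimws(alt)))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  atoms <- data.frame(
    eleno = at$eleno,
    elety = trimws(at$elety),
    resid = trimws(at$resid),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    type = at$type,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("PDB format error: non-finite coordinates")
  }

  prot <- atoms[atoms$type == "ATOM", , drop = FALSE]
  for (rn in unique(prot$resno)) {
    sub <- prot[prot$resno == rn, , drop = FALSE]
    if (!any(sub$elety == "CA")) {
      stop("structural error: residue ", sub$resid[1], rn,
           " has no C-alpha atom")
    }
  }

  helix <- data.frame(helix = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(pdb$helix) && length(pdb$helix$start) > 0) {
    helix <- data.frame(
      helix = LETTERS[seq_along(pdb$helix$start)],
      start = as.integer(pdb$helix$start),
      end = as.integer(pdb$helix$end),
      stringsAsFactors = FALSE
    )
  }
  attr(atoms, "helix") <- helix
  class(atoms) <- c("atom_records", "data.frame")
  atoms
}

#' Write an atom table as a PDB file
#'
#' Inverse of [parse_structure()] for the fields the coarse-grained model
#' uses.  HELIX annotations (attribute `helix`) are emitted as HELIX records.
#'
#' @param atoms an `atom_records` table.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(atoms, file) {
  stopifnot(is.data.frame(atoms))
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = file, xyz = xyz, type = atoms$type, eleno = atoms$eleno,
    elety = atoms$elety, resid = atoms$resid, resno = atoms$resno,
    chain = atoms$chain, o = atoms$occ
  )
  helix <- attr(atoms, "helix")
  if (!is.null(helix) && nrow(helix) > 0) {
    res_of <- function(rn) atoms$resid[match(rn, atoms$resno)]
    lines <- vapply(seq_len(nrow(helix)), function(i) {
      sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d %30s %5d",
              i, helix$helix[i], res_of(helix$start[i]), "A", helix$start[i],
              res_of(helix$end[i]), "A", helix$end[i], 1L, "",
              helix$end[i] - helix$start[i] + 1L)
    }, character(1))
    body <- readLines(file)
    writeLines(c(lines, body), file)
  }
  invisible(file)
}

#' @export
print.atom_records <- function(x, ...) {
  cat("<atom_records> ", nrow(x), " atoms, ",
      length(unique(x$resno[x$type == "ATOM"])), " residues\n", sep = "")
  helix <- attr(x, "helix")
  if (!is.null(helix) && nrow(helix) > 0) {
    cat("  helices:", paste0(helix$helix, "(", helix$start, "-", helix$end, ")",
                             collapse = " "), "\n")
  }
  invisible(x)
}

# side-chain heavy atoms of one residue (excludes backbone + hydrogens)
.sidechain_atoms <- function(atoms, rn) {
  sub <- atoms[atoms$type == "ATOM" & atoms$resno == rn, , drop = FALSE]
  bb <- c("N", "CA", "C", "O", "OXT")
  sub[!(sub$elety %in% bb) & !grepl("^H|^[0-9]H", sub$elety), , drop = FALSE]
}

# backbone heavy atoms of one residue
.backbone_atoms <- function(atoms, rn) {
  sub <- atoms[atoms$type == "ATOM" & atoms$resno == rn, , drop = FALSE]
  sub[sub$elety %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
}
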