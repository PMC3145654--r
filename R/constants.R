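# Physical constants (CODATA 2022) used only by the electrostatics term; the
# rest of the model lives in reduced units anchored by epsilon = 0.6 kcal/mol.
.const <- list(
  e        = 1.602176634e-19,   # elementary charge, C
  eps0     = 8.8541878188e-12,  # vacuum permittivity, F/m
  kB       = 1.380649e-23,      # Boltzmann constant, J/K
  avogadro = 6.02214076e23,     # Avogadro number, 1/mol
  cal      = 4.184,             # J per thermochemical calorie
  eps_kcal = 0.6,               # reduced energy unit epsilon, kcal/mol
  R_kcal   = 1.98720425864083e-3 # gas constant, kcal/(mol K)
)

#' Reduced energy unit
#'
#' The coarse-grained Hamiltonian is expressed in multiples of the
#' solvent-mediated interaction energy \eqn{\epsilon} = 0.6 kcal/mol.
#'
#' @return epsilon in kcal/mol.
#' @export
epsilon_kcal <- function() .const$eps_kcal

#' Vertebrate calmodulin sequence
#'
#' The 148-residue vertebrate calmodulin sequence (one-letter codes, starting
#' at Ala1).  38 residues are Asp/Glu and 14 are Lys/Arg, so the formal-charge
#' fallback assignment gives a net charge of -24 e.
#'
#' @return A length-one character string of 148 one-letter residue codes.
#' @export
cam_sequence <- function() {
  paste0(
    "ADQLTEEQIAEFKEAFSLFDKDGDGTITTKELGTVMRSLGQNPTEAELQDMINEVDADGNGTIDFPEFLTMM",
    "ARKMKDTDSEEEIREAFRVFDKDGNGYISAAELRHVMTNLGEKLTDEEVDEMIREADIDGDGQVNYEEFVQMMTAK"
  )
}

#' Calcium-ligand connectivity of the four EF-hands
#'
#' Residue numbers of the acidic side chains that each calcium bead is tied to
#' by springs in the calcium-bound model: 4 + 4 + 3 + 4 = 15 attachments.
#'
#' @return Named list of integer vectors, one per calcium bead.
#' @export
cam_calcium_sites <- function() {
  list(
    CA1 = c(20L, 22L, 24L, 31L),
    CA2 = c(56L, 58L, 64L, 67L),
    CA3 = c(93L, 95L, 104L),
    CA4 = c(129L, 131L, 133L, 140L)
  )
}

#' Default helix ranges and EF-hand pairing for calmodulin
#'
#' Approximate residue ranges of the eight helices A-H, ordered from the
#' N-terminus.  These are fallback defaults: when a structure carries HELIX
#' records, [helix_annotation()] built from those records should be preferred.
#'
#' @return A data.frame with columns `helix`, `start`, `end`.
#' @seealso [ef_hand_pairs()]
#' @export
cam_helix_ranges <- function() {
  data.frame(
    helix = c("A", "B", "C", "D", "E", "F", "G", "H"),
    start = c(6L, 29L, 45L, 65L, 82L, 102L, 118L, 138L),
    end   = c(19L, 38L, 55L, 75L, 92L, 111L, 128L, 146L),
    stringsAsFactors = FALSE
  )
}

#' EF-hand helix pairing
#'
#' @return Named list mapping EF-hand name to its two helices.
#' @export
ef_hand_pairs <- function() {
  list(AB = c("A", "B"), CD = c("C", "D"), EF = c("E", "F"), GH = c("G", "H"))
}

# van der Waals radii (Angstrom) used for the repulsive bead sizes.
# Backbone (CA) beads share one radius; side-chain radii scale with residue
# volume.  Overridable through the `radii` argument of coarse_grain().
.aa_sc_radii <- c(
  ALA = 2.52, ARG = 3.28, ASN = 2.84, ASP = 2.79, CYS = 2.74,
  GLN = 3.01, GLU = 2.96, GLY = 2.25, HIS = 3.04, ILE = 3.09,
  LEU = 3.09, LYS = 3.18, MET = 3.09, PHE = 3.18, PRO = 2.78,
  SER = 2.59, THR = 2.81, TRP = 3.39, TYR = 3.23, VAL = 2.93
)

#' Bead radius table
#'
#' Side-chain van der Waals radii per residue type plus the shared backbone
#' radius and the calcium/crowder radii.  All values in Angstrom.
#'
#' @param backbone radius of the backbone (C-alpha) bead.
#' @param calcium radius of a calcium bead.
#' @param crowder radius of a crowder sphere (Ficoll 70 is modelled as a
#'   55 Angstrom hard sphere).
#' @return Named numeric vector; names are three-letter residue codes plus
#'   `"CA_BEAD"`, `"CALCIUM"`, `"CROWDER"`.
#' @export
bead_radii <- function(backbone = 1.9, calcium = 1.7, crowder = 55) {
  c(.aa_sc_radii, CA_BEAD = backbone, CALCIUM = calcium, CROWDER = crowder)
}

.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Convert one-letter to three-letter residue codes
#' @param x character vector of one-letter codes, or a single string.
#' @return character vector of three-letter codes.
#' @export
aa_three <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  out <- .aa3[toupper(x)]
  if (anyNA(out)) stop("unknown one-letter residue code: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}
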