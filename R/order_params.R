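#' Radius of gyration
#'
#' Mass-weighted radius of gyration of a configuration.
#'
#' @param pos n x 3 coordinate matrix (Angstrom).
#' @param masses per-bead masses (default: equal).
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(pos, masses = rep(1, nrow(pos))) {
  stopifnot(nrow(pos) >= 1)
  w <- masses / sum(masses)
  com <- colSums(pos * w)
  d <- sweep(pos, 2, com)
  sqrt(sum(w * rowSums(d * d)))
}

#' Asphericity of a configuration
#'
#' Shape parameter from the gyration-tensor eigenvalues
#' \eqn{\lambda_1,\lambda_2,\lambda_3}:
#' \eqn{\Delta = \frac{3}{2}\sum_i(\lambda_i-\bar\lambda)^2 / (\sum_i \lambda_i)^2}.
#' 0 for a sphere, 1 for a rod.
#'
#' @inheritParams radius_of_gyration
#' @return Delta in `[0, 1]`.
#' @export
asphericity <- function(pos, masses = rep(1, nrow(pos))) {
  stopifnot(nrow(pos) >= 3)
  w <- masses / sum(masses)
  com <- colSums(pos * w)
  d <- sweep(pos, 2, com)
  S <- crossprod(d * sqrt(w))          # mass-weighted gyration tensor
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(lam)
  if (tr == 0) return(0)
  1.5 * sum((lam - mean(lam))^2) / tr^2
}

#' Structural overlap with a reference
#'
#' The overlap function compares all bead-pair distances (residue separation
#' of at least `min_res_sep`) with the reference structure:
#' \eqn{\chi = 1 - M^{-1}\sum \Theta(\mathrm{tol} - |r_{ij} - r_{ij}^{ref}|)}.
#' 0 means every pair distance is reference-like, 1 means none is.
#'
#' @param pos frame coordinates (n x 3).
#' @param ref reference coordinates (n x 3, same beads in the same order).
#' @param resno residue number of each bead (for the separation filter).
#' @param tolerance distance tolerance in Angstrom (default 2).
#' @param min_res_sep minimum residue separation of included pairs.
#' @return chi in `[0, 1]`.
#' @export
overlap_chi <- function(pos, ref, resno, tolerance = 2, min_res_sep = 2) {
  if (nrow(pos) != nrow(ref)) {
    stop("frame and reference have different bead counts")
  }
  pr <- all_pairs(seq_len(nrow(pos)))
  sep <- abs(resno[pr[, 1]] - resno[pr[, 2]])
  pr <- pr[sep >= min_res_sep, , drop = FALSE]
  if (!nrow(pr)) stop("no pairs at the requested residue separation")
  r <- .pair_dist(pos, pr[, 1], pr[, 2])
  r0 <- .pair_dist(ref, pr[, 1], pr[, 2])
  1 - mean(abs(r - r0) < tolerance)
}

#' Helical fraction of a backbone trace
#'
#' Residue `i` is assigned helical when the virtual dihedral over C-alpha
#' beads `(i-1, i, i+1, i+2)` falls inside the helical window and the
#' C-alpha(i) to C-alpha(i+4) distance is below `d14_max`.  The returned
#' fraction is over the residues for which both criteria are defined
#' (chain ends are excluded from the denominator).
#'
#' @param ca C-alpha coordinates in chain order (n x 3).
#' @param dihedral_window helical window for the virtual dihedral, degrees.
#' @param d14_max maximum C-alpha(i)-C-alpha(i+4) distance, Angstrom.
#' @return fraction in `[0, 1]`.
#' @export
helicity <- function(ca, dihedral_window = c(30, 80), d14_max = 6.5) {
  n <- nrow(ca)
  if (n < 5) stop("need at least 5 residues")
  idx <- 2:(n - 4)
  if (length(idx) < 1) stop("chain too short for the helicity estimator")
  hel <- vapply(idx, function(i) {
    phi <- .dihedral(ca, i - 1, i, i + 1, i + 2) * 180 / pi
    d14 <- .vnorm(ca[i, ] - ca[i + 4, ])
    phi >= dihedral_window[1] && phi <= dihedral_window[2] && d14 < d14_max
  }, logical(1))
  mean(hel)
}

#' Helix annotation
#'
#' Residue ranges of named helices (A-H for calmodulin, ordered from the
#' N-terminus) plus the EF-hand pairing used by [ef_hand_angle()].
#'
#' @param ranges data.frame with columns `helix`, `start`, `end` (residue
#'   numbers), e.g. [cam_helix_ranges()] or the `helix` attribute of a
#'   parsed structure.
#' @param pairs named list of helix pairs (default [ef_hand_pairs()]).
#' @return a `helix_annotation` object.
#' @export
helix_annotation <- function(ranges = cam_helix_ranges(),
                             pairs = ef_hand_pairs()) {
  stopifnot(all(c("helix", "start", "end") %in% names(ranges)))
  ranges <- ranges[order(ranges$start), , drop = FALSE]
  if (any(ranges$end < ranges$start)) stop("helix end before start")
  if (any(utils::head(ranges$end, -1) >= utils::tail(ranges$start, -1))) {
    stop("helix ranges overlap")
  }
  structure(list(ranges = ranges, pairs = pairs), class = "helix_annotation")
}

#' Interhelical EF-hand angle
#'
#' Each helix is represented by the vector from the average position of its
#' first four residues to the average position of its last four residues;
#' the EF-hand angle Theta_ij is the arccosine of the inner product of the
#' two unit vectors, in degrees.
#'
#' @param ca C-alpha coordinates indexed by residue (row r = residue r), or
#'   an n x 3 matrix together with `resno` giving each row's residue number.
#' @param helix_i,helix_j integer ranges of the two helices (residue
#'   numbers), or helix names when `annotation` is given.
#' @param annotation optional [helix_annotation()] used to resolve names.
#' @param resno optional residue numbers of the rows of `ca`.
#' @return angle in degrees, in `[0, 180]`.
#' @export
ef_hand_angle <- function(ca, helix_i, helix_j, annotation = NULL,
                          resno = seq_len(nrow(ca))) {
  resolve <- function(h) {
    if (is.character(h)) {
      if (is.null(annotation)) stop("helix names need an annotation")
      r <- annotation$ranges[annotation$ranges$helix == h, ]
      if (!nrow(r)) stop("unknown helix: ", h)
      h <- r$start:r$end
    }
    h
  }
  axis_vec <- function(res) {
    if (length(res) < 4) stop("helix must have at least 4 residues")
    rows <- match(res, resno)
    if (anyNA(rows)) stop("helix residues missing from the frame")
    v <- colMeans(ca[utils::tail(rows, 4), , drop = FALSE]) -
      colMeans(ca[utils::head(rows, 4), , drop = FALSE])
    nv <- .vnorm(v)
    if (nv < 1e-12) stop("zero-length helix vector")
    v / nv
  }
  vi <- axis_vec(resolve(helix_i))
  vj <- axis_vec(resolve(helix_j))
  acos(pmin(1, pmax(-1, sum(vi * vj)))) * 180 / pi
}

#' Per-frame order parameters of an ensemble
#'
#' Computes R_g, overlap chi, asphericity Delta, helicity, and the four
#' EF-hand angles for every frame, returning one tidy row per frame.
#'
#' @param frames list of n x 3 coordinate matrices (all beads), or a
#'   `replica_ensemble` with stored positions.
#' @param top the `cg_topology` the frames belong to.
#' @param ref reference coordinates for chi (default: topology coordinates).
#' @param annotation a [helix_annotation()]; `NULL` skips helicity/angles.
#' @param tolerance chi tolerance (Angstrom).
#' @return data.frame with columns `frame`, `rg`, `chi`, `delta`,
#'   `helicity`, and `theta_AB` ... one per EF-hand pair.
#' @export
order_parameters <- function(frames, top, ref = positions(top),
                             annotation = NULL, tolerance = 2) {
  meta <- NULL
  if (inherits(frames, "replica_ensemble")) {
    meta <- frames$frames
    frames <- frames$positions
  }
  beads <- top$beads
  prot <- beads$kind %in% c("CA", "SC")
  ca_rows <- which(beads$kind == "CA")
  ca_resno <- beads$resno[ca_rows]
  refp <- ref[prot, , drop = FALSE]
  out <- lapply(seq_along(frames), function(f) {
    p <- frames[[f]]
    pp <- p[prot, , drop = FALSE]
    row <- data.frame(
      frame = f,
      rg = radius_of_gyration(pp, beads$mass[prot]),
      chi = overlap_chi(pp, refp, beads$resno[prot], tolerance),
      delta = asphericity(pp, beads$mass[prot])
    )
    if (!is.null(annotation)) {
      ca <- p[ca_rows, , drop = FALSE]
      row$helicity <- helicity(ca)
      for (nm in names(annotation$pairs)) {
        pr <- annotation$pairs[[nm]]
        row[[paste0("theta_", nm)]] <-
          ef_hand_angle(ca, pr[1], pr[2], annotation, ca_resno)
      }
    }
    row
  })
  out <- do.call(rbind, out)
  if (!is.null(meta)) out <- cbind(meta, out[, -1, drop = FALSE])
  out
}
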