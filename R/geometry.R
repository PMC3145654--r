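# Small vector-geometry helpers shared by topology building, energies and
# order parameters.  Positions are n x 3 matrices in Angstrom.

.vnorm <- function(v) sqrt(sum(v * v))

.bond_length <- function(p, i, j) .vnorm(p[i, ] - p[j, ])

# angle at j for triple (i, j, k), radians, clamped arccos
.bond_angle <- function(p, i, j, k) {
  u <- p[i, ] - p[j, ]
  v <- p[k, ] - p[j, ]
  cs <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(pmin(1, pmax(-1, cs)))
}

# signed dihedral for quadruple (i, j, k, l), radians in (-pi, pi]
.dihedral <- function(p, i, j, k, l) {
  b1 <- p[j, ] - p[i, ]
  b2 <- p[k, ] - p[j, ]
  b3 <- p[l, ] - p[k, ]
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / .vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# minimum-image displacement matrix rows; box = NA disables periodicity
.min_image <- function(d, box) {
  if (is.null(box) || length(box) == 0 || is.na(box)) return(d)
  d - box * round(d / box)
}

# pairwise distances for an index pair table (matrix with columns i, j)
.pair_dist <- function(p, ii, jj, box = NA) {
  d <- p[ii, , drop = FALSE] - p[jj, , drop = FALSE]
  d <- .min_image(d, box)
  sqrt(rowSums(d * d))
}

# positions matrix of a topology
#' Bead coordinates of a topology
#' @param top a `cg_topology`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
positions <- function(top) {
  as.matrix(top$beads[, c("x", "y", "z")])
}
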