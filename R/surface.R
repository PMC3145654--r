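#' Rectangular basin in the (chi, Delta) plane
#'
#' @param name basin label (e.g. "M1").
#' @param chi length-2 numeric: chi interval.
#' @param delta length-2 numeric: Delta interval.
#' @return a `basin_definition`.
#' @export
basin_definition <- function(name, chi, delta) {
  stopifnot(length(chi) == 2, length(delta) == 2,
            all(chi >= 0 & chi <= 1), all(delta >= 0 & delta <= 1))
  structure(list(name = name, chi = sort(chi), delta = sort(delta)),
            class = "basin_definition")
}

#' The three calmodulin basins
#'
#' M1: the extended, dumbbell-like apo state (0.1 < chi < 0.3,
#' 0.28 < Delta < 0.3).  M2: the compact, spherical apo state
#' (0.3 < chi < 0.4, 0.03 < Delta < 0.15).  M3: the compact
#' calcium-saturated state (0.38 < chi < 0.45, 0.01 < Delta < 0.1).
#'
#' @return named list of [basin_definition()]s.
#' @export
cam_basins <- function() {
  list(
    M1 = basin_definition("M1", c(0.10, 0.30), c(0.28, 0.30)),
    M2 = basin_definition("M2", c(0.30, 0.40), c(0.03, 0.15)),
    M3 = basin_definition("M3", c(0.38, 0.45), c(0.01, 0.10))
  )
}

#' Two-dimensional free-energy surface over (chi, Delta)
#'
#' Bins the per-frame order parameters (optionally with reweighting
#' weights), converts occupied-bin probabilities to free energies
#' \eqn{F = -k_B T \ln P} and shifts the minimum to zero.  Empty bins stay
#' NA rather than being zero-filled.
#'
#' @param chi,delta per-frame order parameters.
#' @param kT temperature in reduced units (epsilon).
#' @param weights per-frame weights (default uniform), e.g. from
#'   [wham_weights()].
#' @param bins number of bins per axis (default 50 over `[0, 1]`).
#' @param limits common axis limits.
#' @return A `free_energy_surface`: list with `F` (bins x bins matrix, chi
#'   rows), `counts`, bin `chi_mid`/`delta_mid`, `kT`.
#' @export
free_energy_surface <- function(chi, delta, kT, weights = NULL, bins = 50,
                                limits = c(0, 1)) {
  stopifnot(length(chi) == length(delta))
  if (is.null(weights)) weights <- rep(1, length(chi))
  weights <- weights / sum(weights)
  edges <- seq(limits[1], limits[2], length.out = bins + 1)
  bx <- findInterval(pmin(pmax(chi, limits[1]), limits[2]), edges,
                     rightmost.closed = TRUE)
  by <- findInterval(pmin(pmax(delta, limits[1]), limits[2]), edges,
                     rightmost.closed = TRUE)
  P <- matrix(0, bins, bins)
  Cn <- matrix(0L, bins, bins)
  for (s in seq_along(chi)) {
    P[bx[s], by[s]] <- P[bx[s], by[s]] + weights[s]
    Cn[bx[s], by[s]] <- Cn[bx[s], by[s]] + 1L
  }
  F <- -kT * log(P)
  F[!is.finite(F)] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  structure(list(F = F, counts = Cn, chi_mid = mids, delta_mid = mids,
                 kT = kT), class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("<free_energy_surface> ", length(x$chi_mid), "x", length(x$delta_mid),
      " bins at kT = ", x$kT, "; occupied bins: ", sum(!is.na(x$F)), "\n",
      sep = "")
  invisible(x)
}

#' Probability mass inside a basin
#'
#' Lower bounds inclusive, upper bounds exclusive.
#'
#' @param chi,delta per-frame order parameters.
#' @param basin a [basin_definition()].
#' @param weights optional per-frame weights.
#' @return probability in `[0, 1]`.
#' @export
basin_population <- function(chi, delta, basin, weights = NULL) {
  if (!length(chi)) stop("empty ensemble")
  if (is.null(weights)) weights <- rep(1, length(chi))
  weights <- weights / sum(weights)
  inside <- chi >= basin$chi[1] & chi < basin$chi[2] &
    delta >= basin$delta[1] & delta < basin$delta[2]
  sum(weights[inside])
}

#' Write a free-energy surface as gridded text
#'
#' One row per occupied grid cell (`chi delta F count`), preceded by `#`
#' header metadata.
#'
#' @param surface a `free_energy_surface`.
#' @param file path.
#' @export
write_surface <- function(surface, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# free energy surface, kT = %g (epsilon units)", surface$kT),
    sprintf("# %d x %d bins; F = -kT ln P, minimum shifted to 0",
            length(surface$chi_mid), length(surface$delta_mid)),
    "chi\tdelta\tF\tcount"), con)
  for (a in seq_along(surface$chi_mid)) {
    for (b in seq_along(surface$delta_mid)) {
      if (!is.na(surface$F[a, b])) {
        writeLines(sprintf("%g\t%g\t%g\t%d", surface$chi_mid[a],
                           surface$delta_mid[b], surface$F[a, b],
                           surface$counts[a, b]), con)
      }
    }
  }
  invisible(file)
}
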