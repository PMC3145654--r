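#' Reference CD basis spectra
#'
#' Loads the packaged basis spectra: mean residue ellipticity of pure
#' alpha-helix, beta-strand and random-coil states on a common wavelength
#' grid.  The shipped table is a smooth synthetic stand-in shaped after the
#' classic poly-amino-acid reference spectra (see the file header); supply
#' your own table with the same columns to use a measured basis.
#'
#' @param file path to a basis CSV with columns `wavelength`, `helix`,
#'   `beta`, `coil` (defaults to the packaged synthetic basis).
#' @return data.frame with those four columns.
#' @export
cd_basis <- function(file = system.file("extdata", "cd_basis_synthetic.csv",
                                        package = "cgcam")) {
  b <- utils::read.csv(file, comment.char = "#")
  need <- c("wavelength", "helix", "beta", "coil")
  if (!all(need %in% names(b))) {
    stop("basis table must have columns: ", paste(need, collapse = ", "))
  }
  b[, need]
}

#' Synthesize a CD spectrum from secondary-structure content
#'
#' Linear combination of the reference basis spectra:
#' \eqn{\theta(\lambda) = f_H B_H(\lambda) + f_\beta B_\beta(\lambda)
#' + (1 - f_H - f_\beta) B_C(\lambda)}, giving the mean residue ellipticity
#' expected for an ensemble with the stated average helix and strand
#' fractions.  Tertiary contributions (e.g. helix reorientation) are not
#' representable in this approximation.
#'
#' @param f_helix,f_beta secondary-structure fractions, each >= 0 with
#'   `f_helix + f_beta <= 1`.
#' @param basis a [cd_basis()] table.
#' @return data.frame `wavelength` (nm), `theta` (deg cm^2/dmol).
#' @export
synthesize_cd_spectrum <- function(f_helix, f_beta = 0, basis = cd_basis()) {
  if (f_helix < 0 || f_beta < 0 || f_helix + f_beta > 1) {
    stop("fractions must be non-negative and sum to at most 1")
  }
  theta <- f_helix * basis$helix + f_beta * basis$beta +
    (1 - f_helix - f_beta) * basis$coil
  data.frame(wavelength = basis$wavelength, theta = theta)
}
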