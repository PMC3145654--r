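#' Contact-pair index table
#'
#' Enumerates the contacts tracked by the ensemble statistics: the native
#' contacts of the topology plus, optionally, candidate nonnative pairs.
#' Mirrors the contact-pair-index (CPI) convention: `class` is `"b"` for
#' side-chain bead pairs and `"h"` for backbone bead pairs.
#'
#' @param top a `cg_topology` with native contacts built.
#' @param nonnative `"none"`, or a 2-column matrix of bead index pairs to
#'   track as nonnative contacts, or `"sidechain"` to track every
#'   side-chain pair with residue separation >= `min_seq_sep` that is not a
#'   native contact.
#' @param min_seq_sep residue separation for generated nonnative pairs.
#' @return data.frame `cpi`, `i`, `j`, `resno_i`, `resno_j`, `class`,
#'   `type` ("native"/"nonnative"), `r0` (NA for nonnative).
#' @export
contact_definitions <- function(top, nonnative = "none", min_seq_sep = 3) {
  ct <- top$contacts
  beads <- top$beads
  defs <- data.frame(
    i = ct$i, j = ct$j,
    class = if ("class" %in% names(ct)) ct$class else
      ifelse(beads$kind[ct$i] == "SC" & beads$kind[ct$j] == "SC", "b", "h"),
    type = rep("native", nrow(ct)), r0 = ct$r0,
    stringsAsFactors = FALSE
  )
  nn <- NULL
  if (is.matrix(nonnative)) {
    nn <- nonnative
  } else if (identical(nonnative, "sidechain")) {
    sc <- beads$index[beads$kind == "SC"]
    pp <- all_pairs(sc)
    sep <- abs(beads$resno[pp[, 1]] - beads$resno[pp[, 2]])
    pp <- pp[sep >= min_seq_sep, , drop = FALSE]
    nat <- pair_key(defs$i, defs$j)
    pp <- pp[!(pair_key(pp[, 1], pp[, 2]) %in% nat), , drop = FALSE]
    nn <- pp
  }
  if (!is.null(nn) && nrow(nn)) {
    defs <- rbind(defs, data.frame(
      i = nn[, 1], j = nn[, 2],
      class = ifelse(beads$kind[nn[, 1]] == "SC" &
                       beads$kind[nn[, 2]] == "SC", "b", "h"),
      type = "nonnative", r0 = NA_real_, stringsAsFactors = FALSE))
  }
  defs$resno_i <- beads$resno[defs$i]
  defs$resno_j <- beads$resno[defs$j]
  defs$cpi <- seq_len(nrow(defs))
  defs[, c("cpi", "i", "j", "resno_i", "resno_j", "class", "type", "r0")]
}

#' Per-frame contact formation indicators
#'
#' A native contact is formed when the pair distance is below
#' `native_factor` times its native distance; a nonnative contact when the
#' distance is below the absolute `nonnative_cutoff`.
#'
#' @param pos frame coordinates.
#' @param defs a [contact_definitions()] table.
#' @param native_factor multiple of the native distance (default 1.2).
#' @param nonnative_cutoff absolute cutoff for nonnative pairs, Angstrom.
#' @param box periodic box edge or NA.
#' @return integer 0/1 vector, one entry per contact (CPI order).
#' @export
contact_states <- function(pos, defs, native_factor = 1.2,
                           nonnative_cutoff = 8, box = NA) {
  r <- .pair_dist(pos, defs$i, defs$j, box)
  thr <- ifelse(defs$type == "native", native_factor * defs$r0,
                nonnative_cutoff)
  as.integer(r < thr)
}

#' Contact indicators for every frame
#'
#' @param frames list of coordinate matrices.
#' @inheritParams contact_states
#' @return frames x contacts integer matrix.
#' @export
contact_q_matrix <- function(frames, defs, native_factor = 1.2,
                             nonnative_cutoff = 8, box = NA) {
  out <- vapply(frames, contact_states, integer(nrow(defs)), defs = defs,
                native_factor = native_factor,
                nonnative_cutoff = nonnative_cutoff, box = box)
  if (is.null(dim(out))) matrix(out, ncol = nrow(defs)) else t(out)
}

#' Contact probability matrices
#'
#' Mean formation probability of each contact over the ensemble, arranged
#' residue-by-residue with native contacts in the upper triangle and
#' nonnative contacts in the lower triangle.
#'
#' @param q frames x contacts indicator matrix from [contact_q_matrix()]
#'   (optionally weighted through `weights`).
#' @param defs the matching [contact_definitions()] table.
#' @param weights optional per-frame weights (e.g. WHAM weights).
#' @return A `contact_matrices` object: list with `defs` (plus a
#'   `probability` column), and `matrix` (n_res x n_res, native upper /
#'   nonnative lower, NA where no contact is tracked).
#' @export
contact_probability_matrix <- function(q, defs, weights = NULL) {
  stopifnot(ncol(q) == nrow(defs))
  if (is.null(weights)) weights <- rep(1 / nrow(q), nrow(q))
  weights <- weights / sum(weights)
  p <- as.numeric(crossprod(q, weights))
  defs$probability <- p
  rmax <- max(defs$resno_i, defs$resno_j)
  M <- matrix(NA_real_, rmax, rmax)
  for (r in seq_len(nrow(defs))) {
    lo <- min(defs$resno_i[r], defs$resno_j[r])
    hi <- max(defs$resno_i[r], defs$resno_j[r])
    if (defs$type[r] == "native") M[lo, hi] <- p[r] else M[hi, lo] <- p[r]
  }
  structure(list(defs = defs, matrix = M), class = "contact_matrices")
}

#' Covariance matrix of contact formation
#'
#' Pearson-normalised covariance of the per-frame contact indicators:
#' \eqn{cov_{ij} = \frac{\langle q_i q_j\rangle - \langle q_i\rangle\langle q_j\rangle}
#' {\sigma_i \sigma_j}}, in `[-1, 1]`.  Contacts with zero variance
#' (always or never formed) have undefined correlations; their entries are
#' NA and they are listed in the `constant` attribute.
#'
#' @param q frames x contacts indicator matrix (>= 2 frames).
#' @return contacts x contacts matrix with unit diagonal for non-constant
#'   contacts; attribute `constant` gives the flagged column indices.
#' @export
contact_covariance <- function(q) {
  if (nrow(q) < 2) stop("need at least 2 frames")
  v <- apply(q, 2, stats::var)
  const <- which(v == 0)
  cv <- suppressWarnings(stats::cor(q))
  cv[const, ] <- NA_real_
  cv[, const] <- NA_real_
  attr(cv, "constant") <- const
  cv
}

#' Write a contact-pair index table as delimited text
#'
#' @param defs a [contact_definitions()] table (optionally with
#'   probabilities).
#' @param file path.
#' @export
write_cpi_table <- function(defs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# contact pair index table: class b = side-chain, h = backbone",
             con)
  utils::write.table(defs, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
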