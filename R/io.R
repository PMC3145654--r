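#' Write a trajectory as multi-frame XYZ
#'
#' One block per frame: atom count, a comment line `step=... T=... E=...`,
#' then one `BEAD x y z` line per bead.
#'
#' @param frames list of n x 3 coordinate matrices, or a `replica_ensemble`
#'   with stored positions.
#' @param file output path.
#' @param meta optional data.frame with columns `step`, `temperature`,
#'   `energy` (taken from the ensemble when available).
#' @export
write_trajectory <- function(frames, file, meta = NULL) {
  if (inherits(frames, "replica_ensemble")) {
    meta <- frames$frames
    frames <- frames$positions
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    p <- frames[[f]]
    cm <- if (!is.null(meta) && f <= nrow(meta)) {
      sprintf("step=%d T=%g E=%g", meta$step[f], meta$temperature[f],
              meta$energy[f])
    } else sprintf("frame=%d", f)
    writeLines(c(as.character(nrow(p)), cm), con)
    writeLines(sprintf("BEAD %.6f %.6f %.6f", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(file)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param file path written by [write_trajectory()].
#' @return list with `frames` (coordinate matrices) and `meta` (data.frame
#'   parsed from the comment lines, where present).
#' @export
read_trajectory <- function(file) {
  lines <- readLines(file)
  frames <- list()
  meta <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    xyz <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(v) {
      as.numeric(v[2:4])
    }))
    frames[[length(frames) + 1]] <- xyz
    kv <- regmatches(cm, gregexpr("[A-Za-z]+=[-0-9.eE+]+", cm))[[1]]
    row <- list()
    for (p in kv) {
      parts <- strsplit(p, "=")[[1]]
      row[[tolower(parts[1])]] <- as.numeric(parts[2])
    }
    meta[[length(meta) + 1]] <- as.data.frame(row)
    i <- i + 2 + n
  }
  meta <- tryCatch(do.call(rbind, meta), error = function(e) NULL)
  list(frames = frames, meta = meta)
}

#' Write per-frame energy or order-parameter tables
#'
#' Delimited text, one row per frame, `#` metadata header.
#'
#' @param df data.frame (e.g. from [order_parameters()] or a stack of
#'   [total_energy()] breakdowns).
#' @param file path.
#' @param comment optional header lines (without the `#`).
#' @export
write_frame_table <- function(df, file, comment = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Stack energy breakdowns into a per-frame table
#'
#' @param breakdowns list of `energy_breakdown` objects.
#' @return data.frame, one row per frame, one column per term.
#' @export
energy_report <- function(breakdowns) {
  do.call(rbind, lapply(breakdowns, function(b) as.data.frame(unclass(b))))
}
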