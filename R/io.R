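# Readers and writers for the package's plain-text interchange formats:
# torsion-series TSV, DSSP code tables, PDB structures (via bio3d) and
# matrix/record exports.

#' Write a torsion table as TSV
#'
#' Header `snapshot<TAB>t1...t{2N-2}`, angles printed with 6 decimal
#' places; [read_torsion_tsv()] round-trips the file bit-identically.
#'
#' @param torsions Torsion table (tibble with `snapshot` + angle columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_torsion_tsv <- function(torsions, path) {
  stopifnot(is.data.frame(torsions), "snapshot" %in% names(torsions))
  cols <- setdiff(names(torsions), "snapshot")
  lines <- c(
    paste(c("snapshot", cols), collapse = "\t"),
    do.call(paste, c(
      list(format(torsions$snapshot, trim = TRUE, scientific = FALSE)),
      lapply(cols, function(cn) sprintf("%.6f", torsions[[cn]])),
      sep = "\t"
    ))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a torsion table from TSV
#'
#' @param path TSV written by [write_torsion_tsv()] (or any table with a
#'   `snapshot` column and angle columns in degrees).
#' @return A tibble.
#' @export
read_torsion_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read DSSP code tables
#'
#' Each file is whitespace-separated with two columns: residue number and
#' single-letter DSSP code. Multiple files (one per input structure) feed
#' the majority vote of [map_secondary_structure()].
#'
#' @param paths Character vector of file paths.
#' @return A list of tibbles with columns `residue`, `code`.
#' @export
read_dssp_codes <- function(paths) {
  lapply(paths, function(p) {
    tb <- utils::read.table(p, header = FALSE, col.names = c("residue", "code"),
                            colClasses = c("integer", "character"))
    as_tibble(tb)
  })
}

#' Write DSSP-style code table
#'
#' @param dssp Tibble with columns `residue`, `code`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dssp_codes <- function(dssp, path) {
  writeLines(sprintf("%d %s", dssp$residue, dssp$code), path)
  invisible(path)
}

#' Read backbone coordinates from a PDB file
#'
#' Parses ATOM records with bio3d, keeps the N/CA/C backbone atoms of the
#' requested model and returns a structure frame. Alternate locations
#' beyond the first occurrence are dropped.
#'
#' @param path PDB file path.
#' @param model Model number (default 1).
#' @return A structure frame tibble (`residue`, `atom`, `x`, `y`, `z`).
#' @export
read_structure <- function(path, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety %in% c("N", "CA", "C")
  at <- at[keep, ]
  if (dim(pdb$xyz)[1] >= model && model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  fr <- tibble(residue = at$resno, atom = at$elety, x = at$x, y = at$y, z = at$z)
  fr <- fr[!duplicated(fr[c("residue", "atom")]), ]
  as_structure_frame(fr)
}

#' Write a structure frame as a minimal PDB file
#'
#' @param frame Structure frame tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path) {
  frame <- as_structure_frame(frame)
  n <- nrow(frame)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(frame[, c("x", "y", "z")]))),
    resno = frame$residue,
    resid = rep("ALA", n),
    elety = frame$atom,
    chain = rep("A", n)
  )
  invisible(path)
}

#' Write a 2D distribution or difference grid as a TSV matrix
#'
#' 60 rows by 60 columns (row = x-bin), for figure reproduction.
#'
#' @param grid A `btp_dist2d` or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  p <- if (inherits(grid, "btp_dist2d")) grid$p else grid
  utils::write.table(format(p, digits = 6, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
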