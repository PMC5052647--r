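# Backbone geometry: dihedral angles from coordinates, the 2N-2 torsion
# index, torsion positions/distances and secondary-structure typing.

#' Dihedral angle of four points
#'
#' Standard IUPAC backbone torsion: looking from `p2` towards `p3`, a
#' clockwise rotation of the far bond relative to the near bond is positive.
#' Computed as atan2 of the triple product `(n1 x n2) . b2_hat` against
#' `n1 . n2`, with `n1`, `n2` the plane normals.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    abort("undefined dihedral: collinear or coincident points.")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  wrap_angle(rad2deg(atan2(y, x)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the 2N-2 backbone torsion index
#'
#' For a chain of N residues the phi of residue 1 and the psi of residue N
#' are undefined, leaving 2N-2 torsions indexed 1..2N-2 from the N- to the
#' C-terminus in the order psi(1), phi(2), psi(2), ..., phi(N). Correlation
#' matrices and all per-pair outputs are keyed by this index.
#'
#' @param n_residues Number of residues, >= 2.
#' @return A tibble with columns `index`, `residue`, `kind` ("phi"/"psi").
#' @export
#' @examples
#' build_torsion_index(3)
build_torsion_index <- function(n_residues) {
  if (n_residues < 2) abort("`n_residues` must be >= 2: no backbone torsion exists.")
  res <- rep(seq_len(n_residues), each = 2)
  kind <- rep(c("phi", "psi"), n_residues)
  keep <- !(res == 1 & kind == "phi") & !(res == n_residues & kind == "psi")
  tibble(
    index = seq_len(2L * n_residues - 2L),
    residue = res[keep],
    kind = kind[keep]
  )
}

# A structure frame is a tibble(residue, atom, x, y, z) restricted to the
# backbone atoms N, CA, C. `as_structure_frame` validates.
as_structure_frame <- function(frame) {
  need <- c("residue", "atom", "x", "y", "z")
  if (!all(need %in% names(frame))) {
    abort("a structure frame needs columns residue, atom, x, y, z.")
  }
  if (!all(is.finite(frame$x) & is.finite(frame$y) & is.finite(frame$z))) {
    abort("non-finite coordinates in structure frame.")
  }
  frame
}

frame_atom <- function(frame, residue, atom) {
  hit <- which(frame$residue == residue & frame$atom == atom)
  if (length(hit) == 0L) {
    abort(sprintf("missing backbone atom %s of residue %d.", atom, residue))
  }
  c(frame$x[hit[1]], frame$y[hit[1]], frame$z[hit[1]])
}

#' Extract phi/psi torsion series from structure frames
#'
#' phi(i) is the dihedral C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). One series per entry of the torsion index.
#'
#' @param frames A list of structure frames (tibbles with columns
#'   `residue`, `atom`, `x`, `y`, `z`; atoms N/CA/C per residue).
#' @param index_map Torsion index from [build_torsion_index()]; defaults to
#'   the map implied by the residues of the first frame.
#' @return A torsion table: tibble with `snapshot` and one column `t<k>` per
#'   torsion index, angles in degrees.
#' @export
extract_torsion_series <- function(frames, index_map = NULL) {
  if (!is.list(frames) || length(frames) == 0L) abort("`frames` must be a non-empty list.")
  frames <- lapply(frames, as_structure_frame)
  if (is.null(index_map)) {
    index_map <- build_torsion_index(length(unique(frames[[1]]$residue)))
  }
  vals <- vapply(seq_along(frames), function(fi) {
    fr <- frames[[fi]]
    vapply(seq_len(nrow(index_map)), function(k) {
      res <- index_map$residue[k]
      tryCatch(
        if (index_map$kind[k] == "phi") {
          dihedral_angle(
            frame_atom(fr, res - 1L, "C"), frame_atom(fr, res, "N"),
            frame_atom(fr, res, "CA"), frame_atom(fr, res, "C")
          )
        } else {
          dihedral_angle(
            frame_atom(fr, res, "N"), frame_atom(fr, res, "CA"),
            frame_atom(fr, res, "C"), frame_atom(fr, res + 1L, "N")
          )
        },
        error = function(e) {
          abort(sprintf("frame %d, torsion %d (%s of residue %d): %s",
                        fi, index_map$index[k], index_map$kind[k], res,
                        conditionMessage(e)))
        }
      )
    }, numeric(1))
  }, numeric(nrow(index_map)))
  vals <- matrix(vals, nrow = nrow(index_map))
  out <- as_tibble(setNames(
    as.data.frame(t(vals)),
    paste0("t", index_map$index)
  ))
  dplyr::bind_cols(tibble(snapshot = seq_along(frames)), out)
}

#' Position of a torsion: midpoint of its central bond
#'
#' phi rotates about N-CA, psi about CA-C; the arithmetic midpoint of the
#' central bond serves as the torsion's spatial position for inter-torsion
#' distances.
#'
#' @param frame A structure frame.
#' @param residue Residue number.
#' @param kind "phi" or "psi".
#' @return Length-3 coordinate vector (Angstrom).
#' @export
torsion_position <- function(frame, residue, kind = c("phi", "psi")) {
  kind <- match.arg(kind)
  frame <- as_structure_frame(frame)
  if (kind == "phi") {
    (frame_atom(frame, residue, "N") + frame_atom(frame, residue, "CA")) / 2
  } else {
    (frame_atom(frame, residue, "CA") + frame_atom(frame, residue, "C")) / 2
  }
}

#' Euclidean distance between two torsion positions
#'
#' @param frame Reference structure frame (by default the structure used to
#'   start a simulation).
#' @param index_map Torsion index map.
#' @param i,j Torsion indices.
#' @return Distance in Angstrom. The 8 Angstrom cutoff used downstream
#'   classifies a pair as spatially local when its distance is <= 8.
#' @export
inter_torsion_distance <- function(frame, index_map, i, j) {
  if (i == j) {
    warn("self-pair distance requested; returning 0.")
    return(0)
  }
  ei <- index_map[index_map$index == i, ]
  ej <- index_map[index_map$index == j, ]
  if (nrow(ei) == 0L || nrow(ej) == 0L) abort("torsion index not in map.")
  pi_ <- torsion_position(frame, ei$residue, ei$kind)
  pj <- torsion_position(frame, ej$residue, ej$kind)
  sqrt(sum((pi_ - pj)^2))
}

#' All pairwise torsion distances of a reference frame
#'
#' @inheritParams inter_torsion_distance
#' @return Tibble with columns `i`, `j` (i < j) and `distance`.
#' @export
torsion_distances <- function(frame, index_map) {
  pos <- t(vapply(
    seq_len(nrow(index_map)),
    function(k) torsion_position(frame, index_map$residue[k], index_map$kind[k]),
    numeric(3)
  ))
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble(
    i = index_map$index[idx[, 1]],
    j = index_map$index[idx[, 2]],
    distance = d[idx]
  )
}

#' Map DSSP codes to alpha/beta/loop classes
#'
#' DSSP's seven states are collapsed to three: H -> "alpha", E -> "beta",
#' everything else (B, G, I, T, S, blank/coil "-" or "C") -> "L". When codes
#' from several structures are supplied the per-residue class is decided by
#' majority vote of the mapped classes; ties break conservatively toward
#' "L". Residues with missing codes are treated as loop with a warning.
#'
#' @param dssp One tibble, or a list of tibbles, with columns `residue` and
#'   `code`(single DSSP letters).
#' @param residues Optional integer vector of residues the assignment must
#'   cover (defaults to the union observed).
#' @return Tibble with columns `residue`, `ss` in {"alpha","beta","L"}.
#' @export
#' @examples
#' map_secondary_structure(tibble::tibble(residue = 1:4,
#'                                        code = c("H", "H", "T", "E")))
map_secondary_structure <- function(dssp, residues = NULL) {
  if (is.data.frame(dssp)) dssp <- list(dssp)
  valid <- c("H", "B", "E", "G", "I", "T", "S", "-", "C", " ", "")
  mapped <- lapply(dssp, function(tb) {
    bad <- setdiff(unique(tb$code), valid)
    if (length(bad)) abort(paste0("unknown DSSP code(s): ", paste(bad, collapse = ", ")))
    tibble(
      residue = tb$residue,
      class = ifelse(tb$code == "H", "alpha", ifelse(tb$code == "E", "beta", "L"))
    )
  })
  votes <- bind_rows(mapped)
  if (is.null(residues)) residues <- sort(unique(votes$residue))
  missing <- setdiff(residues, votes$residue)
  if (length(missing)) {
    warn(sprintf("no DSSP code for residue(s) %s; treated as L.",
                 paste(missing, collapse = ", ")))
  }
  tab <- votes |>
    dplyr::count(.data$residue, .data$class) |>
    group_by(.data$residue) |>
    summarise(ss = {
      top <- .data$class[.data$n == max(.data$n)]
      if (length(top) > 1L) "L" else top  # tie -> loop
    }, .groups = "drop")
  tibble(residue = residues) |>
    left_join(tab, by = "residue") |>
    mutate(ss = ifelse(is.na(.data$ss), "L", .data$ss))
}

#' Secondary-structure type of a torsion pair
#'
#' Helix and strand are pooled as "ab" (alpha/beta); the three symmetric
#' pair types are "ab-ab", "ab-L" and "L-L".
#'
#' @param ss_i,ss_j Classes in {"alpha","beta","L"} (vectorised).
#' @return Character vector of pair types.
#' @export
#' @examples
#' pair_type("alpha", "beta")  # "ab-ab"
#' pair_type("beta", "L")      # "ab-L"
pair_type <- function(ss_i, ss_j) {
  ok <- c("alpha", "beta", "L")
  if (!all(ss_i %in% ok) || !all(ss_j %in% ok)) abort("invalid secondary-structure class.")
  a <- ifelse(ss_i == "L", "L", "ab")
  b <- ifelse(ss_j == "L", "L", "ab")
  ifelse(a == "L" & b == "L", "L-L",
         ifelse(a == "ab" & b == "ab", "ab-ab", "ab-L"))
}
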