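# End-to-end orchestration: per-pair correlation records, classification
# tables, stratification, convergence/permutation diagnostics and the
# deterministic report bundle.

#' Analysis configuration
#'
#' Collects every analysis parameter in one validated object: 60 bins over
#' the circle, the 0.02-nat nonlinearity threshold, the 8-Angstrom
#' local/long-range cutoff, the 0.2 convergence threshold over 3 trajectory
#' thirds, 20 trajectory subsets.
#'
#' @param n_bins Histogram bins per axis (default 60).
#' @param contour `"default_calibrated"` or a `btp_contour` (e.g. from
#'   [fit_contour()]).
#' @param nonlinearity_threshold Excess-MI threshold (nats, default 0.02).
#' @param distance_cutoff Local/long-range split (Angstrom, default 8,
#'   inclusive on the local side).
#' @param n_subsets Trajectory subsets for [subset_analysis()] (default 20).
#' @param convergence_splits,convergence_threshold Convergence-check
#'   parameters (defaults 3 and 0.2).
#' @param permutation_rounds Rounds of the permutation null per analyzed
#'   pair (default 5; 0 disables).
#' @param thin_stride,thin_n Optional snapshot thinning applied before
#'   analysis.
#' @param exclude_adjacent Drop pairs of sequence-adjacent torsion indices
#'   from the classification counts (default FALSE; per-pair values are
#'   never affected).
#' @param peak_threshold Collective-bin probability for a marginal peak
#'   (default 0.1).
#' @param merge_radius Joint-peak merge radius in bins (default 3).
#' @param seed Seed controlling all stochastic diagnostics.
#' @return A `btp_config` list.
#' @export
analysis_config <- function(n_bins = 60L, contour = "default_calibrated",
                            nonlinearity_threshold = 0.02,
                            distance_cutoff = 8, n_subsets = 20L,
                            convergence_splits = 3L, convergence_threshold = 0.2,
                            permutation_rounds = 5L,
                            thin_stride = NULL, thin_n = NULL,
                            exclude_adjacent = FALSE,
                            peak_threshold = 0.1, merge_radius = 3L,
                            seed = 1L) {
  stopifnot(n_bins >= 2, nonlinearity_threshold > 0, distance_cutoff > 0,
            convergence_threshold > 0, n_subsets >= 1, convergence_splits >= 2,
            peak_threshold > 0)
  if (identical(contour, "default_calibrated")) contour <- contour_default()
  stopifnot(inherits(contour, "btp_contour"))
  structure(
    list(n_bins = as.integer(n_bins), contour = contour,
         nonlinearity_threshold = nonlinearity_threshold,
         distance_cutoff = distance_cutoff, n_subsets = as.integer(n_subsets),
         convergence_splits = as.integer(convergence_splits),
         convergence_threshold = convergence_threshold,
         permutation_rounds = as.integer(permutation_rounds),
         thin_stride = thin_stride, thin_n = thin_n,
         exclude_adjacent = exclude_adjacent,
         peak_threshold = peak_threshold, merge_radius = as.integer(merge_radius),
         seed = as.integer(seed)),
    class = "btp_config"
  )
}

#' Per-pair correlation records for a torsion table
#'
#' For every unordered torsion pair (i < j): circular correlation r with
#' instability/degeneracy flags, entropies and mutual information, the
#' contour value MPMI(r), the excess MI - MPMI(r), the linear/nonlinear
#' label and the DSP/SMP/DMP transition class from the marginal peak
#' counts; plus pair type and inter-torsion distance when secondary
#' structure and a reference frame are available.
#'
#' @param torsions Torsion table (tibble with `snapshot` column) or matrix.
#' @param structure Optional reference structure frame for distances.
#' @param ss Optional secondary-structure assignment (tibble `residue`,
#'   `ss`) or DSSP code list for [map_secondary_structure()].
#' @param index_map Torsion index map; inferred from the column count when
#'   absent.
#' @param config A `btp_config`.
#' @return A `btp_pairs` tibble, one row per pair.
#' @export
analyze_pairs <- function(torsions, structure = NULL, ss = NULL,
                          index_map = NULL, config = analysis_config()) {
  mat <- torsion_matrix(torsions)
  nt <- ncol(mat)
  if (is.null(index_map)) index_map <- build_torsion_index((nt + 2L) %/% 2L)
  if (nrow(index_map) != nt) {
    abort("torsion table and index map disagree on the number of torsions.")
  }
  nb <- config$n_bins
  per <- purrr::map(seq_len(nt), function(k) {
    d1 <- histogram_1d(mat[, k], nb)
    pk <- count_peaks_1d(d1, config$peak_threshold)
    list(dist = d1, n_peaks = pk$n_peaks,
         mean = circular_mean(mat[, k]))
  })
  ss_tbl <- if (!is.null(ss)) {
    if (is.data.frame(ss) && "ss" %in% names(ss)) ss else map_secondary_structure(ss)
  }
  dist_tbl <- if (!is.null(structure)) torsion_distances(structure, index_map)
  pairs <- which(upper.tri(diag(nt)), arr.ind = TRUE)
  recs <- purrr::map(seq_len(nrow(pairs)), function(pi_) {
    i <- pairs[pi_, 1]; j <- pairs[pi_, 2]
    cc <- circular_correlation(mat[, i], mat[, j])
    d2 <- joint_histogram(mat[, i], mat[, j], nb)
    s_x <- entropy(d2$px); s_y <- entropy(d2$py); s_xy <- entropy(d2)
    mi <- s_x + s_y - s_xy
    tibble(
      i = index_map$index[i], j = index_map$index[j],
      m = nrow(mat), r = cc$r,
      unstable = cc$unstable, degenerate = cc$degenerate,
      s_x = s_x, s_y = s_y, s_xy = s_xy, mi = mi,
      n_peaks_x = per[[i]]$n_peaks, n_peaks_y = per[[j]]$n_peaks
    )
  }) |> list_rbind()
  recs <- recs |>
    mutate(
      mpmi = mpmi_contour(.data$r, config$contour),
      excess = .data$mi - .data$mpmi,
      linearity = classify_linearity(.data$mi, .data$r, config$contour,
                                     config$nonlinearity_threshold),
      transition_class = classify_transition_status(.data$n_peaks_x, .data$n_peaks_y),
      adjacent = abs(.data$j - .data$i) == 1L
    )
  if (!is.null(ss_tbl)) {
    res_ss <- ss_tbl$ss[match(index_map$residue, ss_tbl$residue)]
    recs$pair_type <- pair_type(
      res_ss[match(recs$i, index_map$index)],
      res_ss[match(recs$j, index_map$index)]
    )
  } else {
    recs$pair_type <- NA_character_
  }
  if (!is.null(dist_tbl)) {
    recs <- recs |> left_join(dist_tbl, by = c("i", "j"))
  } else {
    recs$distance <- NA_real_
  }
  class(recs) <- c("btp_pairs", class(recs))
  attr(recs, "config") <- config
  recs
}

#' @export
glance.btp_pairs <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_nonlinear = sum(x$linearity == "nonlinear"),
    fraction_nonlinear = mean(x$linearity == "nonlinear"),
    max_mi = max(x$mi),
    n_unstable = sum(x$unstable)
  )
}

#' Classification summary (linear/nonlinear by DSP/SMP/DMP)
#'
#' Counts and percentages of pairs in the six cells of transition class by
#' linearity; the analogue of a per-protein classification table.
#'
#' @param records A `btp_pairs` table.
#' @param exclude_adjacent Drop sequence-adjacent pairs from the counts.
#' @return Tibble with `transition_class`, `linearity`, `n`, `percent`.
#' @export
classification_table <- function(records, exclude_adjacent = FALSE) {
  if (exclude_adjacent) records <- records |> filter(!.data$adjacent)
  tidyr::expand_grid(
    transition_class = c("DSP", "SMP", "DMP"),
    linearity = c("linear", "nonlinear")
  ) |>
    left_join(
      records |> dplyr::count(.data$transition_class, .data$linearity),
      by = c("transition_class", "linearity")
    ) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           percent = round(100 * .data$n / max(1L, sum(.data$n)), 1))
}

#' Stratify pairs by distance and secondary-structure type
#'
#' Splits pairs into local (distance <= cutoff, inclusive) versus
#' long-range, crossed with the three pair types, and reports the count and
#' fraction of nonlinear pairs per stratum — the relative ratio of pairs
#' with significant long-range nonlinear correlations.
#'
#' @param records A `btp_pairs` table with distances.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return Tibble with `locality`, `pair_type`, `n`, `n_nonlinear`,
#'   `fraction_nonlinear`.
#' @export
stratify_pairs <- function(records, cutoff = 8) {
  if (all(is.na(records$distance))) {
    warn("no distances available; stratification skipped.")
    return(tibble(locality = character(0), pair_type = character(0),
                  n = integer(0), n_nonlinear = integer(0),
                  fraction_nonlinear = numeric(0)))
  }
  records |>
    filter(!is.na(.data$distance)) |>
    mutate(locality = ifelse(.data$distance <= cutoff, "local", "long_range")) |>
    group_by(.data$locality, .data$pair_type) |>
    summarise(
      n = n(),
      n_nonlinear = sum(.data$linearity == "nonlinear"),
      fraction_nonlinear = mean(.data$linearity == "nonlinear"),
      .groups = "drop"
    )
}

#' MI and MPMI correlation matrices
#'
#' Square symmetric matrices over the torsion index: observed MI, and the
#' contour value MPMI(r) per pair (the two triangles of a combined
#' correlation-matrix figure).
#'
#' @param records A `btp_pairs` table.
#' @return List with matrices `mi` and `mpmi` (dimnames = torsion indices).
#' @export
correlation_matrices <- function(records) {
  idx <- sort(unique(c(records$i, records$j)))
  n <- length(idx)
  mi <- mpmi <- matrix(0, n, n, dimnames = list(idx, idx))
  ii <- match(records$i, idx); jj <- match(records$j, idx)
  mi[cbind(ii, jj)] <- mi[cbind(jj, ii)] <- records$mi
  mpmi[cbind(ii, jj)] <- mpmi[cbind(jj, ii)] <- records$mpmi
  list(mi = mi, mpmi = mpmi)
}

#' Run the full torsional-pair correlation pipeline
#'
#' From a torsion table (plus optional structure and secondary-structure
#' input) to the full report: per-pair records, MI/MPMI matrices, the
#' classification table, distance/SS strata, the convergence report,
#' permutation-null maxima and (optionally) trajectory-subset analyses of
#' selected pairs. Deterministic given input + config seed.
#'
#' @inheritParams analyze_pairs
#' @param subset_pairs Optional 2-column matrix/tibble of torsion index
#'   pairs to run [subset_analysis()] on; `NULL` analyzes the most
#'   nonlinear pair when any pair is nonlinear.
#' @param output_dir Optional directory; when given, the bundle is written
#'   as TSV/JSON via [write_report()].
#' @return A `btp_report` list: `pairs`, `matrices`, `classification`,
#'   `strata`, `convergence`, `permutation`, `subsets`, `config`.
#' @export
run_pipeline <- function(torsions, structure = NULL, ss = NULL,
                         index_map = NULL, config = analysis_config(),
                         subset_pairs = NULL, output_dir = NULL) {
  if (!is.null(config$thin_stride) || !is.null(config$thin_n)) {
    torsions <- thin_snapshots(torsions, stride = config$thin_stride,
                               n = config$thin_n)
  }
  mat <- torsion_matrix(torsions)
  nt <- ncol(mat)
  if (is.null(index_map)) index_map <- build_torsion_index((nt + 2L) %/% 2L)
  recs <- analyze_pairs(mat, structure, ss, index_map, config)
  mats <- correlation_matrices(recs)
  cls <- classification_table(recs, config$exclude_adjacent)
  strata <- if (!all(is.na(recs$distance))) stratify_pairs(recs, config$distance_cutoff)
  conv <- convergence_check(mat, config$convergence_splits,
                            config$convergence_threshold, config$n_bins)
  perm <- NULL
  if (config$permutation_rounds > 0L) {
    pairs <- which(upper.tri(diag(nt)), arr.ind = TRUE)
    perm_rows <- purrr::map(seq_len(nrow(pairs)), function(pi_) {
      pn <- permutation_null(mat[, pairs[pi_, 1]], mat[, pairs[pi_, 2]],
                             n_rounds = config$permutation_rounds,
                             seed = config$seed + pi_, n_bins = config$n_bins)
      g <- glance(pn)
      tibble(i = index_map$index[pairs[pi_, 1]], j = index_map$index[pairs[pi_, 2]],
             max_abs_r = g$max_abs_r, max_mi = g$max_mi)
    }) |> list_rbind()
    perm <- tibble(
      n_rounds = config$permutation_rounds,
      max_abs_r = max(perm_rows$max_abs_r),
      max_mi = max(perm_rows$max_mi)
    )
  }
  if (is.null(subset_pairs)) {
    nl <- recs |> filter(.data$linearity == "nonlinear") |> arrange(-.data$excess)
    if (nrow(nl) > 0) subset_pairs <- nl[1, c("i", "j")]
  }
  subsets <- NULL
  if (!is.null(subset_pairs) && nrow(subset_pairs) > 0) {
    subset_pairs <- as.data.frame(subset_pairs)
    subsets <- purrr::map(seq_len(nrow(subset_pairs)), function(k) {
      ci <- match(subset_pairs[k, 1], index_map$index)
      cj <- match(subset_pairs[k, 2], index_map$index)
      sa <- subset_analysis(mat[, ci], mat[, cj],
                            n_subsets = min(config$n_subsets, nrow(mat)),
                            n_bins = config$n_bins)
      sa |> mutate(i = index_map$index[ci], j = index_map$index[cj],
                   .before = 1)
    }) |> list_rbind()
  }
  report <- structure(
    list(pairs = recs, matrices = mats, classification = cls, strata = strata,
         convergence = conv, permutation = perm, subsets = subsets,
         config = config),
    class = "btp_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.btp_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<btp_report> %d pairs: %d nonlinear (%.1f%%), max MI = %.4f nats\n",
    "  convergence: %.1f%% of torsions not converged\n"),
    g$n_pairs, g$n_nonlinear, 100 * g$fraction_nonlinear, g$max_mi,
    100 * g$fraction_not_converged))
  invisible(x)
}

#' @export
glance.btp_report <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$pairs),
    glance(x$convergence)[, c("fraction_not_converged", "n_not_converged")]
  )
}

#' @export
tidy.btp_report <- function(x, ...) x$pairs

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write a report bundle to disk
#'
#' TSV tables (6 significant digits; percentages with 1 decimal) plus a
#' JSON echo of the configuration. Re-running the pipeline with the same
#' inputs and seed reproduces the bundle byte-identically.
#'
#' @param report A `btp_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(tb, name) {
    tb <- dplyr::mutate(as_tibble(tb), across(dplyr::where(is.numeric), fmt6))
    utils::write.table(tb, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$pairs, "pairs.tsv")
  wt(report$classification, "classification.tsv")
  wt(report$convergence, "convergence.tsv")
  wt(report$pairs[, c("i", "j", "r", "mi", "pair_type", "distance")], "scatter.tsv")
  if (!is.null(report$strata)) wt(report$strata, "strata.tsv")
  if (!is.null(report$permutation)) wt(report$permutation, "permutation.tsv")
  if (!is.null(report$subsets)) wt(report$subsets, "subsets.tsv")
  write_grid_tsv(report$matrices$mi, file.path(dir, "mi_matrix.tsv"))
  write_grid_tsv(report$matrices$mpmi, file.path(dir, "mpmi_matrix.tsv"))
  cfg <- report$config
  cfg$contour <- list(a = cfg$contour$a, b = cfg$contour$b,
                      provenance = cfg$contour$provenance)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
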