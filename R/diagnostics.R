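# Convergence (K-L divergence across trajectory thirds), permutation nulls
# for spurious-correlation control, trajectory-subset analysis and snapshot
# thinning.

#' Kullback-Leibler divergence between two binned angle distributions
#'
#' \eqn{KL(p\|q) = \sum_n p_n \ln(p_n/q_n)}. K-L is asymmetric; both
#' directions are used (and maximised) by [convergence_check()]. Empty
#' reference cells are regularized by adding `epsilon` to every q cell and
#' renormalizing, keeping the divergence finite without distorting
#' converged cases; the default `epsilon = 1/(10 * M_q)` is one tenth of a
#' single count.
#'
#' @param p,q `btp_dist1d` objects on the same binning.
#' @param epsilon Regularization added to q cells; `NULL` (default) uses
#'   `1/(10 * q$m)`, 0 disables it.
#' @return Divergence in nats, >= 0 after regularization.
#' @export
#' @examples
#' p <- histogram_1d(c(rep(-90, 5), rep(90, 5)), n_bins = 2)
#' kl_divergence(p, p)  # 0
kl_divergence <- function(p, q, epsilon = NULL) {
  stopifnot(inherits(p, "btp_dist1d"), inherits(q, "btp_dist1d"))
  if (p$n_bins != q$n_bins) abort("distributions must share the same binning.")
  if (is.null(epsilon)) epsilon <- 1 / (10 * q$m)
  qq <- q$p
  if (epsilon > 0) qq <- (qq + epsilon) / (1 + q$n_bins * epsilon)
  pos <- p$p > 0
  sum(p$p[pos] * log(p$p[pos] / qq[pos]))
}

# contiguous split of 1..m into k near-equal blocks (sizes differ by <= 1)
split_blocks <- function(m, k) {
  sizes <- rep(m %/% k, k)
  extra <- m %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  purrr::map2(c(1L, head(ends, -1) + 1L), ends, seq)
}

#' Convergence check of torsion distributions across trajectory thirds
#'
#' Partitions the trajectory into `n_splits` contiguous equal subsets and,
#' per torsion, computes the K-L divergence between each pair of subset
#' distributions (both directions; the per-pair value is the maximum of the
#' two, a conservative symmetrization). A torsion is satisfactorily
#' converged when the largest pairwise divergence is below `threshold`. The
#' same 60-bin discretization is used as in the MI calculation.
#'
#' @param torsions Torsion table: tibble with a `snapshot` column and one
#'   angle column per torsion (degrees), or a plain numeric matrix.
#' @param n_splits Number of contiguous subsets (default 3).
#' @param threshold Convergence threshold on the max divergence (default
#'   0.2, strict "smaller than").
#' @param n_bins Histogram bins (default 60).
#' @return A `btp_convergence` tibble: one row per torsion with the pairwise
#'   divergences, `kl_max` and `converged`. `glance()` gives the fraction
#'   not converged.
#' @export
convergence_check <- function(torsions, n_splits = 3L, threshold = 0.2,
                              n_bins = 60L) {
  mat <- torsion_matrix(torsions)
  m <- nrow(mat)
  if (m < n_splits) abort("fewer snapshots than subsets.")
  blocks <- split_blocks(m, n_splits)
  pairs <- utils::combn(n_splits, 2)
  out <- purrr::map(colnames(mat), function(tn) {
    dists <- lapply(blocks, function(ix) histogram_1d(mat[ix, tn], n_bins))
    kl <- vapply(seq_len(ncol(pairs)), function(pi_) {
      a <- dists[[pairs[1, pi_]]]
      b <- dists[[pairs[2, pi_]]]
      max(kl_divergence(a, b), kl_divergence(b, a))
    }, numeric(1))
    tb <- tibble(torsion = tn, kl_max = max(kl),
                 converged = max(kl) < threshold)
    for (pi_ in seq_len(ncol(pairs))) {
      tb[[sprintf("kl_%d_%d", pairs[1, pi_], pairs[2, pi_])]] <- kl[pi_]
    }
    tb
  }) |> list_rbind()
  out <- out[, c("torsion", grep("^kl_\\d", names(out), value = TRUE),
                 "kl_max", "converged")]
  class(out) <- c("btp_convergence", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' @export
glance.btp_convergence <- function(x, ...) {
  tibble(
    n_torsions = nrow(x),
    n_not_converged = sum(!x$converged),
    fraction_not_converged = mean(!x$converged),
    threshold = attr(x, "threshold")
  )
}

#' Permutation null for spurious correlation from limited sampling
#'
#' Destroys the pairing between two torsion series: in every round, x and y
#' values are taken from independently drawn random snapshots (uniform over
#' 1..M, with replacement), and r and MI recomputed. Whatever correlation
#' survives reflects lack of statistics, not coupling; the maxima over
#' rounds bound the spurious-correlation level of the data set.
#'
#' @param x,y Angle series in degrees, equal length >= 2.
#' @param n_rounds Number of permutation rounds.
#' @param seed Integer seed; the result is reproducible given (data, seed).
#' @param n_bins Histogram bins for MI.
#' @return A `btp_permutation` tibble with one row per round (`round`, `r`,
#'   `mi`); `glance()` gives `max_abs_r` and `max_mi`.
#' @export
permutation_null <- function(x, y, n_rounds = 10L, seed = 1L, n_bins = 60L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  m <- length(x)
  if (m < 2L) abort("need at least two snapshots.")
  out <- withr::with_seed(seed, {
    purrr::map(seq_len(n_rounds), function(rd) {
      xi <- x[sample.int(m, m, replace = TRUE)]
      yi <- y[sample.int(m, m, replace = TRUE)]
      tibble(round = rd,
             r = circular_correlation(xi, yi)$r,
             mi = mutual_information(xi, yi, n_bins))
    }) |> list_rbind()
  })
  class(out) <- c("btp_permutation", class(out))
  out
}

#' @export
glance.btp_permutation <- function(x, ...) {
  tibble(n_rounds = nrow(x), max_abs_r = max(abs(x$r)), max_mi = max(x$mi))
}

#' Trajectory-subset analysis of a torsion pair
#'
#' Splits the snapshots of a pair into `n_subsets` contiguous equal blocks
#' and recomputes MI, r and the joint-peak count per block. Torsional state
#' transitions occur on long time scales, so subsets of a nonlinear pair
#' typically scatter widely around the full-set values — many subsets catch
#' no transition and look linear.
#'
#' @param x,y Angle series in degrees, equal length.
#' @param n_subsets Number of contiguous blocks (default 20).
#' @param n_bins Histogram bins.
#' @return A `btp_subsets` tibble with one row per subset (`subset`, `m`,
#'   `r`, `unstable`, `mi`, `n_joint_peaks`); the full-set values are
#'   attached as attribute `reference` and reported by `glance()`.
#' @export
subset_analysis <- function(x, y, n_subsets = 20L, n_bins = 60L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  m <- length(x)
  if (n_subsets > m) abort("more subsets than snapshots.")
  blocks <- split_blocks(m, n_subsets)
  out <- purrr::map(seq_len(n_subsets), function(s) {
    ix <- blocks[[s]]
    cc <- circular_correlation(x[ix], y[ix])
    tibble(
      subset = s, m = length(ix), r = cc$r, unstable = cc$unstable,
      mi = mutual_information(x[ix], y[ix], n_bins),
      n_joint_peaks = count_joint_peaks(joint_histogram(x[ix], y[ix], n_bins))$n_peaks
    )
  }) |> list_rbind()
  cc_full <- circular_correlation(x, y)
  class(out) <- c("btp_subsets", class(out))
  attr(out, "reference") <- tibble(
    m = m, r = cc_full$r, mi = mutual_information(x, y, n_bins)
  )
  out
}

#' @export
glance.btp_subsets <- function(x, ...) {
  ref <- attr(x, "reference")
  tibble(
    n_subsets = nrow(x), full_r = ref$r, full_mi = ref$mi,
    subset_mi_min = min(x$mi), subset_mi_max = max(x$mi)
  )
}

#' Thin a torsion table in time
#'
#' Either keep every `stride`-th snapshot (starting from the first), or
#' keep `n` evenly spaced snapshots including the first. Thinning trades
#' fast local motion for long-time-scale structure: strongly thinned series
#' emphasize torsional state transitions.
#'
#' @param torsions Torsion table (tibble with `snapshot` column) or matrix.
#' @param stride Keep snapshots 1, 1+stride, 1+2*stride, ...
#' @param n Keep `n` evenly spaced snapshots (`round(seq(1, M, length.out
#'   = n))`); mutually exclusive with `stride`.
#' @return The thinned table, same type as the input.
#' @export
#' @examples
#' tb <- tibble::tibble(snapshot = 1:100, t1 = runif(100, -180, 180))
#' nrow(thin_snapshots(tb, stride = 10))
thin_snapshots <- function(torsions, stride = NULL, n = NULL) {
  m <- if (is.matrix(torsions)) nrow(torsions) else nrow(torsions)
  if (!is.null(stride) && !is.null(n)) abort("give either `stride` or `n`, not both.")
  if (!is.null(stride)) {
    if (stride < 1) abort("`stride` must be >= 1.")
    keep <- seq(1L, m, by = stride)
  } else if (!is.null(n)) {
    if (n > m) abort("`n` exceeds the number of snapshots.")
    keep <- unique(round(seq(1L, m, length.out = n)))
  } else {
    abort("give `stride` or `n`.")
  }
  if (is.matrix(torsions)) torsions[keep, , drop = FALSE] else torsions[keep, ]
}

# accept either a torsion tibble (with snapshot column) or a bare matrix;
# return the angle matrix with torsion names
torsion_matrix <- function(torsions) {
  if (is.matrix(torsions)) {
    if (is.null(colnames(torsions))) {
      colnames(torsions) <- paste0("t", seq_len(ncol(torsions)))
    }
    return(torsions)
  }
  if (!is.data.frame(torsions)) abort("expected a torsion table or matrix.")
  cols <- setdiff(names(torsions), "snapshot")
  as.matrix(torsions[, cols])
}
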