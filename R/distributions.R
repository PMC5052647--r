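# Angle histograms, torsional-state peak counting and distribution
# differences. Bins are 6 degrees wide by default (60 bins over the circle);
# bin k covers [-180 + 6k, -180 + 6(k+1)) with the last bin closed at +180.

bin_index <- function(x, n_bins) {
  w <- 360 / n_bins
  k <- floor((wrap_angle(x) + 180) / w)
  k[k >= n_bins] <- n_bins - 1L  # +180 falls in the last bin
  as.integer(k)
}

#' Marginal angle distribution (normalized histogram)
#'
#' @param x Angle series in degrees.
#' @param n_bins Number of equal bins over the circle (default 60).
#' @return A `btp_dist1d`: list with `p` (probabilities per bin, 0-based bin
#'   k covers `[-180 + k*360/n_bins, ...)`), `n_bins` and `m` (sample count).
#' @export
#' @examples
#' d <- histogram_1d(c(-179, -179, 10))
#' sum(d$p)
histogram_1d <- function(x, n_bins = 60L) {
  if (length(x) == 0L) abort("empty angle series.")
  k <- bin_index(x, n_bins)
  counts <- tabulate(k + 1L, nbins = n_bins)
  structure(
    list(p = counts / length(x), n_bins = as.integer(n_bins), m = length(x)),
    class = "btp_dist1d"
  )
}

#' @export
print.btp_dist1d <- function(x, ...) {
  cat(sprintf("<btp_dist1d> %d bins, M = %d, entropy = %.4f nats\n",
              x$n_bins, x$m, entropy(x)))
  invisible(x)
}

#' @export
tidy.btp_dist1d <- function(x, ...) {
  w <- 360 / x$n_bins
  tibble(
    bin = seq_len(x$n_bins) - 1L,
    lower = -180 + (seq_len(x$n_bins) - 1L) * w,
    upper = -180 + seq_len(x$n_bins) * w,
    p = x$p
  )
}

#' Construct distribution objects from probabilities
#'
#' For workflows where binned probabilities already exist (e.g. constructed
#' reference distributions); [histogram_1d()] / [joint_histogram()] are the
#' usual entry points.
#'
#' @param p Probability vector (`as_dist1d`) or matrix (`as_dist2d`,
#'   rows = x-bin); must be non-negative and sum to 1 within 1e-9.
#' @param m Sample count behind the probabilities (`NA` for analytic
#'   distributions).
#' @return A `btp_dist1d` / `btp_dist2d`.
#' @export
as_dist1d <- function(p, m = NA_integer_) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`p` must be non-negative and sum to 1.")
  }
  structure(list(p = as.vector(p), n_bins = length(p), m = m),
            class = "btp_dist1d")
}

#' @rdname as_dist1d
#' @export
as_dist2d <- function(p, m = NA_integer_) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`p` must be a square non-negative matrix summing to 1.")
  }
  structure(list(p = p, px = rowSums(p), py = colSums(p),
                 n_bins = nrow(p), m = m),
            class = "btp_dist2d")
}

#' Count peaks of a marginal torsion distribution
#'
#' Implements the collective-bin rule used to detect torsional states:
#' cyclic neighbour differences \eqn{\delta_n = p(n) - p(n-1)} (with
#' \eqn{\delta_0 = p(0) - p(59)}) are scanned; a bin i with \eqn{\delta_i <
#' 0} whose next non-zero difference (cyclically) is positive is a boundary
#' bin; bins between consecutive boundaries merge into collective bins, and
#' a collective bin with probability strictly greater than `peak_threshold`
#' counts as a distribution peak. A distribution with no boundaries (e.g.
#' uniform, or a single basin) is one collective bin.
#'
#' @param dist A `btp_dist1d`.
#' @param peak_threshold Minimum collective-bin probability for a peak
#'   (default 0.1, exclusive).
#' @return A `btp_peaks` object: list with `dim = 1`, `boundaries` (0-based
#'   boundary bins), `collective` (tibble: first/last bin, probability,
#'   is_peak) and `n_peaks`.
#' @export
count_peaks_1d <- function(dist, peak_threshold = 0.1) {
  stopifnot(inherits(dist, "btp_dist1d"))
  p <- dist$p
  nb <- dist$n_bins
  delta <- p - p[c(nb, seq_len(nb - 1L))]  # delta[n+1] = p(n) - p(n-1), cyclic
  nz <- which(delta != 0)
  boundaries <- integer(0)
  if (length(nz) >= 2L) {
    for (ii in seq_along(nz)) {
      i <- nz[ii]
      j <- nz[if (ii == length(nz)) 1L else ii + 1L]
      if (delta[i] < 0 && delta[j] > 0) boundaries <- c(boundaries, i - 1L)
    }
  }
  if (length(boundaries) == 0L) {
    collective <- tibble(
      first_bin = 0L, last_bin = nb - 1L, probability = sum(p),
      is_peak = sum(p) > peak_threshold
    )
  } else {
    b <- sort(boundaries)
    k <- length(b)
    collective <- purrr::map(seq_len(k), function(s) {
      lo <- b[s]
      hi <- if (s == k) b[1] else b[s + 1L]
      len <- (hi - lo) %% nb
      if (len == 0L) len <- nb  # single boundary: whole circle
      bins <- (lo + seq_len(len)) %% nb
      tibble(first_bin = bins[1], last_bin = bins[len],
             probability = sum(p[bins + 1L]))
    }) |> list_rbind() |>
      mutate(is_peak = .data$probability > peak_threshold)
  }
  structure(
    list(dim = 1L, boundaries = sort(boundaries), collective = collective,
         n_peaks = sum(collective$is_peak)),
    class = "btp_peaks"
  )
}

#' @export
print.btp_peaks <- function(x, ...) {
  cat(sprintf("<btp_peaks> %dD, %d peak(s)%s\n", x$dim, x$n_peaks,
              if (isTRUE(x$plateau)) " [degenerate plateau]" else ""))
  invisible(x)
}

#' @export
tidy.btp_peaks <- function(x, ...) {
  if (x$dim == 1L) x$collective else x$groups
}

#' Joint angle distribution of a torsion pair
#'
#' Discretizes the 2-torus into `n_bins x n_bins` cells with the same bin
#' edges as [histogram_1d()] on each axis; marginals of the stored joint are
#' the per-series histograms.
#'
#' @param x,y Angle series in degrees, equal length.
#' @param n_bins Bins per axis (default 60, i.e. 3600 cells).
#' @return A `btp_dist2d`: list with `p` (matrix, rows = x-bin), `px`, `py`,
#'   `n_bins`, `m`.
#' @export
joint_histogram <- function(x, y, n_bins = 60L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) == 0L) abort("empty angle series.")
  kx <- bin_index(x, n_bins)
  ky <- bin_index(y, n_bins)
  counts <- tabulate(kx * n_bins + ky + 1L, nbins = n_bins * n_bins)
  p <- matrix(counts / length(x), nrow = n_bins, byrow = TRUE)
  structure(
    list(p = p, px = rowSums(p), py = colSums(p),
         n_bins = as.integer(n_bins), m = length(x)),
    class = "btp_dist2d"
  )
}

#' @export
print.btp_dist2d <- function(x, ...) {
  cat(sprintf("<btp_dist2d> %dx%d bins, M = %d, MI = %.4f nats\n",
              x$n_bins, x$n_bins, x$m,
              entropy(x$px) + entropy(x$py) - entropy(x)))
  invisible(x)
}

#' @export
tidy.btp_dist2d <- function(x, ...) {
  nb <- x$n_bins
  tibble(
    bin_x = rep(seq_len(nb) - 1L, each = nb),
    bin_y = rep(seq_len(nb) - 1L, nb),
    p = as.vector(t(x$p))
  )
}

# strict local maxima on the torus: cell greater than all 8 toroidal
# neighbours
toroidal_maxima <- function(p) {
  n <- nrow(p)
  up <- function(m) m[c(n, seq_len(n - 1L)), , drop = FALSE]
  dn <- function(m) m[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  lf <- function(m) m[, c(n, seq_len(n - 1L)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(n - 1L) + 1L, 1L), drop = FALSE]
  ok <- p > up(p) & p > dn(p) & p > lf(p) & p > rt(p) &
    p > up(lf(p)) & p > up(rt(p)) & p > dn(lf(p)) & p > dn(rt(p))
  which(ok, arr.ind = TRUE)
}

cyclic_diff <- function(a, b, n) pmin(abs(a - b), n - abs(a - b))

# union-find over tentative maxima; merge when cyclic index difference on
# BOTH dimensions <= radius, closed transitively
merge_maxima <- function(maxima, n_bins, merge_radius) {
  k <- nrow(maxima)
  if (k == 0L) return(integer(0))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (a in seq_len(k)) for (b in seq_len(k)) if (a < b) {
    if (cyclic_diff(maxima[a, 1], maxima[b, 1], n_bins) <= merge_radius &&
        cyclic_diff(maxima[a, 2], maxima[b, 2], n_bins) <= merge_radius) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

#' Count peaks of a joint torsion-pair distribution
#'
#' A cell is a tentative peak when its probability strictly exceeds all 8
#' toroidal neighbours. Two tentative peaks whose cyclic index differences
#' on both dimensions are at most `merge_radius` (default 3, i.e. within 24
#' degrees at 6-degree bins) are merged into one joint distribution peak;
#' merging is closed transitively. If no cell strictly exceeds its
#' neighbours (an exact plateau, e.g. a uniform joint) the count is 0 with
#' the `plateau` flag set.
#'
#' @param dist A `btp_dist2d` (or a bare probability matrix, e.g. a clipped
#'   distribution difference).
#' @param merge_radius Maximum per-dimension cyclic index difference for
#'   merging (default 3, inclusive).
#' @return A `btp_peaks` with `dim = 2`, `maxima` (0-based tibble of
#'   tentative peaks with group ids), `groups` (one row per merged peak with
#'   its centroid), `n_peaks` and `plateau`.
#' @export
count_joint_peaks <- function(dist, merge_radius = 3L) {
  p <- if (inherits(dist, "btp_dist2d")) dist$p else dist
  nb <- nrow(p)
  mx <- toroidal_maxima(p)
  if (nrow(mx) == 0L) {
    return(structure(
      list(dim = 2L,
           maxima = tibble(bin_x = integer(0), bin_y = integer(0), group = integer(0)),
           groups = tibble(group = integer(0), center_x = numeric(0),
                           center_y = numeric(0), n_members = integer(0)),
           n_peaks = 0L, plateau = TRUE),
      class = "btp_peaks"
    ))
  }
  grp <- merge_maxima(mx, nb, merge_radius)
  maxima <- tibble(bin_x = mx[, 1] - 1L, bin_y = mx[, 2] - 1L, group = grp)
  groups <- maxima |>
    group_by(.data$group) |>
    summarise(
      center_x = cyclic_centroid(.data$bin_x, nb),
      center_y = cyclic_centroid(.data$bin_y, nb),
      n_members = n(), .groups = "drop"
    )
  structure(
    list(dim = 2L, maxima = maxima, groups = groups,
         n_peaks = nrow(groups), plateau = FALSE),
    class = "btp_peaks"
  )
}

# circular mean of bin indices on a cycle of length n, mapped back to [0, n)
cyclic_centroid <- function(bins, n) {
  th <- bins * 2 * pi / n
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m * n / (2 * pi)) %% n
}

#' Distribution difference of a torsion pair
#'
#' \eqn{\Delta p(m,n) = p(m,n) - p_x(m) p_y(n)}: zero everywhere iff the
#' binned joint factorizes. Sums to 0 by the marginal identity.
#'
#' @param dist A `btp_dist2d`.
#' @return Numeric matrix (rows = x-bin).
#' @export
distribution_difference <- function(dist) {
  stopifnot(inherits(dist, "btp_dist2d"))
  dist$p - outer(dist$px, dist$py)
}

#' Heterogeneity of linear correlation from distribution-difference peaks
#'
#' A pair's linear correlation is homogeneous when (i) the
#' positively-signed peaks of \eqn{\Delta p} fall approximately on one
#' straight line and (ii) the anisotropic local structure within each peak
#' is described by the same line; it is heterogeneous (different linear
#' relationships in different parts of the joint) when either condition
#' fails. Positive peaks are detected with the 2D peak rule applied to
#' \eqn{\max(\Delta p, 0)}, keeping only maxima above a counting-noise
#' floor; peak centers are unwrapped around their circular mean and a
#' total-least-squares line fitted (RMS perpendicular residual in bins
#' against `tolerance`); additionally each peak's \eqn{\Delta p}-weighted
#' principal direction — when clearly anisotropic — is compared with the
#' line's direction (misalignment against `angle_tolerance`). With a single
#' peak the peak's own principal direction serves as the line, so a bent
#' ("L"- or "X"-shaped) single peak region with conflicting local slopes is
#' still detected through the residual of its member cells.
#'
#' @param dp Distribution-difference matrix from
#'   [distribution_difference()].
#' @param m Sample count behind the histogram (sets the counting-noise
#'   scale).
#' @param joint Optional joint probability matrix (or `btp_dist2d`)
#'   underlying `dp`. When given, a peak cell is countable only when its
#'   \eqn{\Delta p} exceeds `significance` standard deviations of that
#'   cell's binomial counting noise, \eqn{z\sqrt{p/M}} — so peaks of
#'   independent pairs (pure noise) are rejected while genuine but weak
#'   excess probability is kept.
#' @param noise_floor Scalar floor on \eqn{\Delta p} used when `joint` is
#'   absent (default `2 / sqrt(m)`); overrides the significance rule when
#'   supplied.
#' @param significance z-score for the cell-wise noise test (default 5).
#' @param tolerance RMS residual (bins) below which a peak set counts as
#'   collinear (default 1.5, sub-peak-width).
#' @param angle_tolerance Maximum misalignment (degrees) between a peak's
#'   principal direction and the fitted line (default 25).
#' @param anisotropy_min Eigenvalue ratio above which a peak's direction is
#'   considered meaningful (default 4).
#' @param merge_radius Passed to the 2D peak rule.
#' @return List with `verdict` ("independent", "homogeneous" or
#'   "heterogeneous"), `peaks` (tibble of positive-peak centers, 0-based
#'   bins, with per-peak directions in degrees where defined), `residual`
#'   (RMS perpendicular distance of the centers, bins; 0 when < 2 peaks),
#'   `max_misalignment` (degrees) and `n_segments` (1, or the minimal
#'   number of lines <= 3 covering the peaks within tolerance).
#' @export
heterogeneity_score <- function(dp, m, joint = NULL, noise_floor = NULL,
                                tolerance = 1.5, significance = 5,
                                angle_tolerance = 25, anisotropy_min = 4,
                                merge_radius = 3L) {
  if (inherits(joint, "btp_dist2d")) joint <- joint$p
  nb <- nrow(dp)
  pos <- pmax(dp, 0)
  pk <- count_joint_peaks(pos, merge_radius = merge_radius)
  if (pk$n_peaks > 0L) {
    # keep merged groups whose best member rises above counting noise
    vals <- pk$maxima |>
      mutate(val = dp[cbind(.data$bin_x + 1L, .data$bin_y + 1L)],
             thr = if (!is.null(joint) && is.null(noise_floor)) {
               significance *
                 sqrt(joint[cbind(.data$bin_x + 1L, .data$bin_y + 1L)] / m) + 2 / m
             } else if (!is.null(noise_floor)) noise_floor else 2 / sqrt(m))
    keep <- vals |>
      group_by(.data$group) |>
      summarise(ok = any(.data$val > .data$thr), .groups = "drop") |>
      filter(.data$ok)
    groups <- pk$groups |> filter(.data$group %in% keep$group)
  } else {
    groups <- tibble(center_x = numeric(0), center_y = numeric(0))
  }
  if (nrow(groups) == 0L) {
    return(list(verdict = "independent",
                peaks = tibble(center_x = numeric(0), center_y = numeric(0)),
                residual = NA_real_, max_misalignment = NA_real_,
                n_segments = 0L))
  }
  dirs <- vapply(seq_len(nrow(groups)), function(g) {
    peak_direction(dp, groups$center_x[g], groups$center_y[g], nb,
                   radius = 2L * merge_radius,
                   anisotropy_min = anisotropy_min)
  }, numeric(1))
  groups$direction <- dirs
  pts <- unwrap_points(groups$center_x, groups$center_y, nb)
  if (nrow(groups) >= 2L) {
    res1 <- tls_residual(pts)
    line_dir <- tls_direction(pts)
  } else {
    res1 <- 0
    line_dir <- dirs[1]  # single peak: its own principal direction
  }
  mis <- if (is.na(line_dir)) NA_real_ else {
    suppressWarnings(max(line_angle_diff(dirs[!is.na(dirs)], line_dir)))
  }
  if (!is.finite(mis)) mis <- NA_real_
  heterogeneous <- res1 > tolerance ||
    (!is.na(mis) && mis > angle_tolerance)
  if (!heterogeneous) {
    return(list(verdict = "homogeneous", peaks = groups,
                residual = res1, max_misalignment = mis, n_segments = 1L))
  }
  nseg <- if (res1 > tolerance) min_segments(pts, tolerance) else 2L
  list(verdict = "heterogeneous", peaks = groups,
       residual = res1, max_misalignment = mis, n_segments = nseg)
}

# delta-p-weighted principal direction (degrees, mod 180) of the positive
# cells within a toroidal Chebyshev radius of a peak center; NA when the
# local cloud is too small or not clearly anisotropic. Cells below a tenth
# of the local maximum are background and excluded.
peak_direction <- function(dp, cx, cy, nb, radius, anisotropy_min) {
  ix <- which(dp > 0, arr.ind = TRUE)
  if (nrow(ix) == 0L) return(NA_real_)
  dx <- (ix[, 1] - 1 - cx + nb / 2) %% nb - nb / 2
  dy <- (ix[, 2] - 1 - cy + nb / 2) %% nb - nb / 2
  sel <- abs(dx) <= radius & abs(dy) <= radius
  if (!any(sel)) return(NA_real_)
  local_max <- max(dp[ix[sel, , drop = FALSE]])
  sel <- sel & dp[ix] > local_max / 10
  if (sum(sel) < 5L) return(NA_real_)
  w <- dp[ix[sel, , drop = FALSE]]
  pts <- cbind(dx[sel], dy[sel])
  mu <- colSums(pts * w) / sum(w)
  ctr <- sweep(pts, 2, mu)
  cov <- crossprod(ctr * sqrt(w / sum(w)), ctr * sqrt(w / sum(w)))
  e <- eigen(cov, symmetric = TRUE)
  if (e$values[2] <= 0 || e$values[1] / e$values[2] < anisotropy_min) {
    return(NA_real_)
  }
  (rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1]))) %% 180
}

tls_direction <- function(pts) {
  ctr <- scale(pts, scale = FALSE)
  e <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  (rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1]))) %% 180
}

# acute angle between undirected lines, degrees
line_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# center bin coordinates on their circular mean and unwrap to the nearest
# representative, so a peak set straddling the +/-180 seam is contiguous
unwrap_points <- function(bx, by, n) {
  cx <- cyclic_centroid(bx, n)
  cy <- cyclic_centroid(by, n)
  ux <- (bx - cx + n / 2) %% n - n / 2
  uy <- (by - cy + n / 2) %% n - n / 2
  cbind(ux, uy)
}

# RMS perpendicular residual of the total-least-squares line through points
tls_residual <- function(pts) {
  ctr <- scale(pts, scale = FALSE)
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$values
  sqrt(max(0, min(ev)))
}

# minimal number of lines (1..3) covering the points within tolerance;
# exhaustive over bipartitions (peak sets are small)
min_segments <- function(pts, tolerance) {
  k <- nrow(pts)
  fits <- function(idx) length(idx) < 3L || tls_residual(pts[idx, , drop = FALSE]) <= tolerance
  if (fits(seq_len(k))) return(1L)
  if (k <= 12L) {
    for (mask in seq_len(2^(k - 1) - 1)) {
      a <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
      b <- setdiff(seq_len(k), a)
      if (length(a) && length(b) && fits(a) && fits(b)) return(2L)
    }
  }
  3L
}
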