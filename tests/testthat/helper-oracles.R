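# Independent oracles and small constructors used across the suite.

# --- dihedral oracle: project the outer points onto the plane
# perpendicular to the central bond and measure the signed angle between
# the projections (det/dot form, coded independently of the package)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  bh <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * bh) * bh   # near-side reference
  v <- (p4 - p3) - sum((p4 - p3) * bh) * bh   # far-side arm
  det3 <- function(a, b, c) {
    a[1] * (b[2] * c[3] - b[3] * c[2]) -
      a[2] * (b[1] * c[3] - b[3] * c[1]) +
      a[3] * (b[1] * c[2] - b[2] * c[1])
  }
  # cis (arms on the same side) gives u parallel v -> 0; sign follows the
  # IUPAC clockwise-positive convention viewed from p2 towards p3
  ang <- as.numeric(atan2(det3(u, v, bh), sum(u * v))) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# --- naive brute-force MI: per-snapshot double loop over joint counts
naive_mi <- function(x, y, n_bins = 60L) {
  w <- 360 / n_bins
  wrap <- function(a) {
    v <- a %% 360
    v[v > 180] <- v[v > 180] - 360
    v[v == -180] <- 180
    v
  }
  bin <- function(a) {
    k <- floor((wrap(a) + 180) / w)
    k[k >= n_bins] <- n_bins - 1
    k + 1
  }
  cmat <- matrix(0L, n_bins, n_bins)
  bx <- bin(x); by <- bin(y)
  for (s in seq_along(x)) {
    cmat[bx[s], by[s]] <- cmat[bx[s], by[s]] + 1L
  }
  m <- length(x)
  p <- cmat / m
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- as.vector(q); q <- q[q > 0]; -sum(q * log(q)) }
  ent(px) + ent(py) - ent(p)
}

# --- analytic MI of a discrete joint table (nats)
oracle_state_mi <- function(tab) {
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (a in seq_len(nrow(tab))) for (b in seq_len(ncol(tab))) {
    if (tab[a, b] > 0) s <- s + tab[a, b] * log(tab[a, b] / (px[a] * py[b]))
  }
  s
}

# --- constructed 1D distribution: triangular bumps at given bins/masses
bump_dist <- function(centers, masses, half_width = 4L, n_bins = 60L) {
  p <- numeric(n_bins)
  for (k in seq_along(centers)) {
    offs <- -half_width:half_width
    wts <- (half_width + 1 - abs(offs))
    wts <- wts / sum(wts) * masses[k]
    bins <- ((centers[k] + offs) %% n_bins) + 1
    p[bins] <- p[bins] + wts
  }
  as_dist1d(p / sum(p))
}

# --- constructed 2D grid with smooth circular Gaussian bumps (matrix only)
bump_grid <- function(centers, masses, sigma = 2, n_bins = 60L) {
  g <- matrix(0, n_bins, n_bins)
  ax <- seq_len(n_bins) - 1
  for (k in seq_len(nrow(centers))) {
    dx <- pmin(abs(ax - centers[k, 1]), n_bins - abs(ax - centers[k, 1]))
    dy <- pmin(abs(ax - centers[k, 2]), n_bins - abs(ax - centers[k, 2]))
    b <- exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
    g <- g + masses[k] * b / sum(b)
  }
  g / sum(g)
}

# --- rotate a 1D distribution's bins cyclically by k
rotate_dist <- function(d, k) {
  n <- d$n_bins
  as_dist1d(d$p[((seq_len(n) - 1 - k) %% n) + 1], d$m)
}

# shift a matrix toroidally by (kx, ky)
shift_grid <- function(g, kx, ky) {
  n <- nrow(g)
  g[((seq_len(n) - 1 - kx) %% n) + 1, ((seq_len(n) - 1 - ky) %% n) + 1]
}
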