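test_that("1D histograms use 6-degree bins with the stated boundary convention", {
  d <- histogram_1d(rep(-179, 5))
  expect_s3_class(d, "btp_dist1d")
  expect_equal(d$p[1], 1)
  expect_equal(sum(d$p), 1)
  # one angle per bin -> uniform
  centers <- seq(-177, 177, by = 6)
  expect_equal(histogram_1d(centers)$p, rep(1 / 60, 60))
  # +180 falls in the last bin; -180 is the same angle
  expect_equal(histogram_1d(c(180))$p[60], 1)
  expect_equal(histogram_1d(c(-180))$p[60], 1)
  expect_error(histogram_1d(numeric(0)), "empty")
})

test_that("1D peak counting follows the cyclic collective-bin rule", {
  # uniform: no nonzero differences, one collective bin, one peak
  expect_equal(count_peaks_1d(as_dist1d(rep(1 / 60, 60)))$n_peaks, 1)
  # two separated bumps with masses 0.6/0.4: two boundaries, two peaks
  p <- numeric(60)
  p[1:10] <- 0.06
  p[31:40] <- 0.04
  pk <- count_peaks_1d(as_dist1d(p))
  expect_equal(length(pk$boundaries), 2)
  expect_equal(pk$n_peaks, 2)
  expect_equal(sort(pk$collective$probability), c(0.4, 0.6))
  # sub-threshold bump is excluded: 0.92 + 0.08 -> one peak
  p2 <- numeric(60)
  p2[1:10] <- 0.092
  p2[31:40] <- 0.008
  expect_equal(count_peaks_1d(as_dist1d(p2))$n_peaks, 1)
  # a collective bin of exactly the threshold is not a peak (strict >)
  p3 <- numeric(60)
  p3[1:10] <- 0.09
  p3[31:40] <- 0.01
  pk3 <- count_peaks_1d(as_dist1d(p3), peak_threshold = 0.1)
  expect_equal(pk3$n_peaks, 1)
})

test_that("collective-bin probabilities sum to one and rotation leaves counts unchanged", {
  set.seed(42)
  for (k in 1:10) {
    d <- histogram_1d(rvonmises(500, mu = runif(1, -180, 180), kappa = 2))
    pk <- count_peaks_1d(d)
    expect_equal(sum(pk$collective$probability), 1)
    for (rot in c(1, 7, 30, 59)) {
      expect_equal(count_peaks_1d(rotate_dist(d, rot))$n_peaks, pk$n_peaks)
    }
  }
})

test_that("well-separated von Mises mixtures yield their designed peak count", {
  # kappa = 20, modes >= 60 degrees apart, weights clear of the 0.1 rule
  set.seed(7)
  for (s in 1:20) {
    w <- sample(1:3, 1)
    modes <- (sample(0:5, w) * 60 - 150)
    wts <- runif(w, 0.5, 1)
    wts <- wts / sum(wts)
    wts <- 0.15 + wts * (1 - 0.15 * w)  # every weight > 0.15
    mdl <- state_model(modes, 20, wts, dwell = 1)
    xy <- sample_pair(pair_spec(mdl, mdl, coupling = "independent", m = 1e5),
                      seed = s)
    expect_equal(count_peaks_1d(histogram_1d(xy$x))$n_peaks, w)
  }
})

test_that("joint histograms are consistent with their marginals", {
  x <- rep(10, 5); y <- rep(-30, 5)
  d <- joint_histogram(x, y)
  expect_equal(sum(d$p > 0), 1)
  expect_equal(sum(d$p), 1)
  # four hand-listed pairs occupy four known cells at 0.25
  xs <- c(-179, -179, 1, 179)
  ys <- c(-179, 1, 1, -100)
  d4 <- joint_histogram(xs, ys)
  expect_equal(d4$p[1, 1], 0.25)
  expect_equal(d4$p[1, 31], 0.25)
  expect_equal(d4$p[31, 31], 0.25)
  expect_equal(d4$p[60, 14], 0.25)
  # marginal consistency on random data
  set.seed(5)
  x <- runif(500, -180, 180); y <- runif(500, -180, 180)
  d <- joint_histogram(x, y)
  expect_equal(d$px, histogram_1d(x)$p)
  expect_equal(d$py, histogram_1d(y)$p)
  expect_error(joint_histogram(1:3, 1:2), "equal length")
})

test_that("joint peak counting merges nearby maxima and flags plateaus", {
  # product of two single bumps: one joint peak
  g1 <- bump_grid(matrix(c(20, 20), 1), 1)
  expect_equal(count_joint_peaks(g1)$n_peaks, 1)
  # maxima at (10,10) and (12,12): both index differences <= 3 -> merged
  g2 <- matrix(0, 60, 60)
  g2[11, 11] <- 0.6
  g2[13, 13] <- 0.4
  pk2 <- count_joint_peaks(g2)
  expect_equal(nrow(pk2$maxima), 2)
  expect_equal(pk2$n_peaks, 1)
  # distance 4 on one dimension: not merged
  g2b <- matrix(0, 60, 60)
  g2b[11, 11] <- 0.6
  g2b[15, 13] <- 0.4
  expect_equal(count_joint_peaks(g2b)$n_peaks, 2)
  # far-apart maxima stay separate
  g3 <- bump_grid(rbind(c(10, 10), c(40, 40)), c(0.5, 0.5))
  expect_equal(count_joint_peaks(g3)$n_peaks, 2)
  # transitive closure: chain a-b-c with a-c farther than the radius
  g4 <- matrix(0, 60, 60)
  g4[11, 11] <- 0.5
  g4[14, 14] <- 0.3
  g4[17, 17] <- 0.2
  expect_equal(count_joint_peaks(g4)$n_peaks, 1)
  # exact plateau: flagged, zero peaks
  pku <- count_joint_peaks(matrix(1 / 3600, 60, 60))
  expect_true(pku$plateau)
  expect_equal(pku$n_peaks, 0)
})

test_that("joint peak counts are invariant under toroidal translation", {
  set.seed(9)
  g <- bump_grid(rbind(c(5, 50), c(30, 10), c(45, 45)), c(0.4, 0.35, 0.25))
  n0 <- count_joint_peaks(g)$n_peaks
  expect_equal(n0, 3)
  for (k in 1:5) {
    kx <- sample(0:59, 1); ky <- sample(0:59, 1)
    expect_equal(count_joint_peaks(shift_grid(g, kx, ky))$n_peaks, n0)
  }
})

test_that("distribution differences vanish for products and sum to zero", {
  # independent product input
  px <- numeric(60); px[10:14] <- 0.2
  py <- numeric(60); py[40:47] <- 0.125
  d <- as_dist2d(outer(px, py))
  expect_equal(max(abs(distribution_difference(d))), 0, tolerance = 1e-12)
  # perfectly coupled diagonal: closed form 1/60 - 1/3600 on the diagonal
  dg <- as_dist2d(diag(rep(1 / 60, 60)))
  dp <- distribution_difference(dg)
  expect_equal(diag(dp), rep(1 / 60 - 1 / 3600, 60))
  # random input sums to zero
  set.seed(13)
  x <- runif(2000, -180, 180); y <- x + rnorm(2000, 0, 20)
  dpr <- distribution_difference(joint_histogram(x, wrap_angle(y)))
  expect_equal(sum(dpr), 0, tolerance = 1e-12)
})

test_that("heterogeneity verdicts follow collinearity of constructed peaks", {
  m <- 1e5
  # two positive peaks define a line: homogeneous, residual 0
  g2 <- bump_grid(rbind(c(10, 10), c(30, 30)), c(0.5, 0.5)) - 1 / 3600
  h2 <- heterogeneity_score(g2, m)
  expect_equal(h2$verdict, "homogeneous")
  expect_equal(h2$residual, 0, tolerance = 1e-9)
  # three collinear peaks: homogeneous
  g3 <- bump_grid(rbind(c(10, 10), c(25, 25), c(40, 40)), rep(1 / 3, 3)) - 1 / 3600
  h3 <- heterogeneity_score(g3, m)
  expect_equal(h3$verdict, "homogeneous")
  expect_lt(h3$residual, 0.5)
  # right-angle "L": one line cannot fit, two can
  gl <- bump_grid(rbind(c(10, 10), c(30, 10), c(30, 30)), rep(1 / 3, 3)) - 1 / 3600
  hl <- heterogeneity_score(gl, m)
  expect_equal(hl$verdict, "heterogeneous")
  expect_gt(hl$residual, 1.5)
  expect_equal(hl$n_segments, 2)
  # no positive peak above the floor: independent
  flat <- matrix(1e-6, 60, 60) - 1e-6
  expect_equal(heterogeneity_score(flat, m)$verdict, "independent")
})

test_that("sampled pair archetypes score as designed", {
  score <- function(xy) {
    d2 <- joint_histogram(xy$x, xy$y)
    heterogeneity_score(distribution_difference(d2), length(xy$x), joint = d2)
  }
  # X-shape (opposite within-state slopes, shared y basin): heterogeneous
  het <- score(sample_heterogeneous_pair(c(-60, 60), c(0, 0), c(0.8, -0.8),
                                         m = 1e5, seed = 3))
  expect_equal(het$verdict, "heterogeneous")
  # same-signed rho with collinear centers: homogeneous
  hom <- score(sample_heterogeneous_pair(c(-60, 60), c(-60, 60), c(0.8, 0.8),
                                         m = 1e5, seed = 3))
  expect_equal(hom$verdict, "homogeneous")
  # independent single-state pair: no significant peak
  ind <- score(sample_pair(pair_spec(state_model(-60, 8), state_model(-45, 8),
                                     coupling = "independent", m = 1e5), seed = 3))
  expect_equal(ind$verdict, "independent")
})
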