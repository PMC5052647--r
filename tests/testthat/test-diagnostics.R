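test_that("K-L divergence matches hand evaluation and is asymmetric", {
  two_bin <- function(w) as_dist1d(c(w, 1 - w))
  p <- two_bin(0.5); q <- two_bin(0.25)
  # 0.5 ln 2 + 0.5 ln(2/3)
  expect_equal(kl_divergence(p, q, epsilon = 0), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(p, q, epsilon = 0), 0.1438410, tolerance = 1e-6)
  expect_equal(kl_divergence(q, p, epsilon = 0), 0.25 * log(0.5) + 0.75 * log(1.5))
  expect_equal(kl_divergence(q, p, epsilon = 0), 0.1308120, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(kl_divergence(p, q, epsilon = 0),
                                kl_divergence(q, p, epsilon = 0))))
  # self-divergence is exactly 0, with and without regularization
  set.seed(2)
  d <- histogram_1d(rvonmises(500, 30, 4))
  expect_equal(kl_divergence(d, d, epsilon = 0), 0)
  expect_lt(kl_divergence(d, d), 0.02)
  # regularization keeps zero-reference cells finite
  expect_true(is.finite(kl_divergence(as_dist1d(c(0.5, 0.5)),
                                      as_dist1d(c(1, 0), m = 100L))))
  expect_error(kl_divergence(histogram_1d(1:10, 60), histogram_1d(1:10, 30)),
               "binning")
})

test_that("convergence check flags a planted state switch but not stationarity", {
  m <- 3e4
  set.seed(6)
  stationary <- rvonmises(m, -60, 10)
  switch_at_2_3 <- c(rvonmises(2 * m / 3, -60, 10), rvonmises(m / 3, 120, 10))
  tb <- tibble::tibble(snapshot = 1:m, t1 = stationary, t2 = switch_at_2_3)
  cv <- convergence_check(tb)
  expect_s3_class(cv, "btp_convergence")
  expect_true(cv$converged[cv$torsion == "t1"])
  expect_lt(cv$kl_max[cv$torsion == "t1"], 0.2)
  expect_false(cv$converged[cv$torsion == "t2"])
  expect_gt(cv$kl_max[cv$torsion == "t2"], 0.2)
  expect_equal(glance(cv)$fraction_not_converged, 0.5)
  # identical repeated subsets: zero divergence, converged
  rep3 <- tibble::tibble(snapshot = 1:300, t1 = rep(rvonmises(100, 0, 5), 3))
  expect_true(all(convergence_check(rep3)$kl_max < 0.05))
  expect_error(convergence_check(tb[1:2, ]), "fewer snapshots")
})

test_that("convergence verdicts are invariant to subset relabeling", {
  # K-L pairs cover all subset pairs, so permuting block contents that
  # coincide with block boundaries leaves kl_max unchanged
  set.seed(61)
  m <- 9000
  x <- c(rvonmises(3000, -60, 8), rvonmises(3000, 60, 8), rvonmises(3000, 180, 8))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  kl <- sapply(perms, function(pm) {
    blocks <- split(x, rep(1:3, each = 3000))
    convergence_check(matrix(unlist(blocks[pm]), ncol = 1))$kl_max
  })
  expect_equal(max(kl) - min(kl), 0, tolerance = 1e-12)
})

test_that("permutation annihilates correlation and is seed-reproducible", {
  set.seed(14)
  x <- wrap_angle(rnorm(5000, 0, 40))
  y <- wrap_angle(x + rnorm(5000, 0, 15))  # strongly coupled
  full_mi <- mutual_information(x, y)
  pn1 <- permutation_null(x, y, n_rounds = 5, seed = 77)
  pn2 <- permutation_null(x, y, n_rounds = 5, seed = 77)
  expect_identical(pn1, pn2)
  g <- glance(pn1)
  expect_lt(g$max_mi, full_mi / 4)
  # perfectly coupled pair drops from S_x to near zero
  pnc <- permutation_null(x, x, n_rounds = 5, seed = 5)
  expect_lt(glance(pnc)$max_mi, 0.1 * entropy(histogram_1d(x)))
  expect_lt(glance(pnc)$max_abs_r, 0.1)
})

test_that("permuted MI sits at the independent-pair plug-in bias level", {
  set.seed(15)
  m <- 1e4
  x <- rvonmises(m, -60, 6)
  y <- wrap_angle(x + rnorm(m, 0, 20))
  pn <- permutation_null(x, y, n_rounds = 10, seed = 31)
  # oracle: repeated truly-independent resamplings computed outside the
  # package (base-R sampling + table counts)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  oracle <- replicate(50, {
    xi <- x[sample.int(m, m, replace = TRUE)]
    yi <- y[sample.int(m, m, replace = TRUE)]
    bx <- findInterval(xi, seq(-180, 180, by = 6), left.open = TRUE)
    by <- findInterval(yi, seq(-180, 180, by = 6), left.open = TRUE)
    tab <- table(factor(bx, 1:60), factor(by, 1:60)) / m
    ent(rowSums(tab)) + ent(colSums(tab)) - ent(as.vector(tab))
  })
  expect_lt(max(abs(pn$mi - mean(oracle))), 3 * sd(oracle) + 1e-4)
})

test_that("subset analysis partitions snapshots and matches the full set when trivial", {
  set.seed(16)
  x <- rvonmises(4000, 10, 5)
  y <- wrap_angle(x + rnorm(4000, 0, 30))
  sa1 <- subset_analysis(x, y, n_subsets = 1)
  ref <- attr(sa1, "reference")
  expect_equal(sa1$mi, ref$mi)
  expect_equal(sa1$r, ref$r)
  sa <- subset_analysis(x, y, n_subsets = 20)
  expect_equal(sum(sa$m), 4000)
  expect_true(all(abs(sa$m - 200) <= 1))
  # i.i.d. pair: block shuffling permutes the multiset of subset results
  ord <- sample(20)
  xs <- as.vector(matrix(x, ncol = 20)[, ord])
  ys <- as.vector(matrix(y, ncol = 20)[, ord])
  sa_shuf <- subset_analysis(xs, ys, n_subsets = 20)
  expect_equal(sort(sa_shuf$mi), sort(sa$mi))
  expect_equal(sort(sa_shuf$r), sort(sa$r))
  expect_error(subset_analysis(x, y, n_subsets = 5000), "more subsets")
})

test_that("slow two-state pairs look linear in most subsets but not the full set", {
  # ~5 expected transitions in the whole trajectory: most subsets see one
  # state only (single joint peak, low MI), the full set sees the coupling
  sp <- pair_spec(
    state_model(c(-60, 60), 50, c(0.5, 0.5), dwell = 4000),
    state_model(c(-60, 60), 50, c(0.5, 0.5), dwell = 4000),
    coupling = "state_coupled",
    joint_states = matrix(c(0.5, 0, 0, 0.5), 2, 2), m = 2e4, dwell = 4000
  )
  xy <- sample_pair(sp, seed = 8)
  sa <- subset_analysis(xy$x, xy$y, n_subsets = 20)
  ref <- attr(sa, "reference")
  expect_gt(ref$mi, 0.4)  # full set: strong state-level MI (ln 2 minus noise)
  expect_gte(sum(sa$n_joint_peaks == 1), 10)
  expect_gte(sum(sa$mi < ref$mi / 2), 10)
})

test_that("snapshot thinning keeps the stated indices", {
  tb <- tibble::tibble(snapshot = 1:100, t1 = seq(-99, 99, by = 2))
  expect_identical(thin_snapshots(tb, stride = 1), tb)
  th <- thin_snapshots(tb, stride = 10)
  expect_equal(th$snapshot, seq(1, 100, by = 10))
  tu <- thin_snapshots(tb, n = 10)
  expect_equal(tu$snapshot, c(1, 12, 23, 34, 45, 56, 67, 78, 89, 100))
  expect_equal(nrow(thin_snapshots(matrix(0, 1e5, 1), stride = 10)), 1e4)
  expect_error(thin_snapshots(tb, n = 101), "exceeds")
  expect_error(thin_snapshots(tb, stride = 2, n = 5), "not both")
})
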