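test_that("von Mises quantiles and samples have the right location and spread", {
  u <- seq(0.001, 0.999, length.out = 999)
  q <- qvonmises(u, mu = 30, kappa = 10)
  # monotone in u (as centered deviations from the mean direction)
  expect_true(all(diff((q - 30 + 180) %% 360) >= 0))
  expect_equal(qvonmises(0.5, mu = 30, kappa = 10), 30, tolerance = 1e-3)
  set.seed(1)
  x <- rvonmises(5e4, -45, 8)
  cm <- circular_mean(x)
  expect_equal(cm$mean, -45, tolerance = 1)
  # resultant length matches the von Mises A(kappa) = I1/I0 ratio
  a_kappa <- besselI(8, 1, expon.scaled = TRUE) / besselI(8, 0, expon.scaled = TRUE)
  expect_equal(cm$r_length, a_kappa, tolerance = 0.01)
  expect_error(state_model(c(0, 10, 20, 30)), "1 to 3")
  expect_error(state_model(0, kappa = -1), "kappa")
})

test_that("identical spec and seed give bit-identical series", {
  sp <- pair_spec(
    state_model(c(-60, 60), 12, c(0.6, 0.4)),
    state_model(c(-45, 120), 9, c(0.3, 0.7)),
    coupling = "copula", rho = 0.4, m = 2000
  )
  a <- sample_pair(sp, seed = 123)
  b <- sample_pair(sp, seed = 123)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$states_x, b$states_x)
  c <- sample_pair(sp, seed = 124)
  expect_false(identical(a$x, c$x))
})

test_that("state occupancy matches the stationary weights", {
  w <- c(0.2, 0.5, 0.3)
  sp <- pair_spec(
    state_model(c(-150, -30, 90), 15, w, dwell = 1),  # i.i.d. states
    state_model(0, 5),
    coupling = "independent", m = 1e5
  )
  xy <- sample_pair(sp, seed = 2)
  occ <- tabulate(xy$states_x, 3) / 1e5
  for (k in 1:3) {
    expect_lt(abs(occ[k] - w[k]), 3 * sqrt(w[k] * (1 - w[k]) / 1e5))
  }
})

test_that("empirical circular correlation increases with the copula rho", {
  rhos <- c(-0.8, -0.4, 0, 0.4, 0.8)
  med <- sapply(rhos, function(rho) {
    rs <- sapply(1:20, function(s) {
      sp <- pair_spec(state_model(-60, 8), state_model(60, 8),
                      coupling = "copula", rho = rho, m = 2e4)
      xy <- sample_pair(sp, seed = s)
      circular_correlation(xy$x, xy$y)$r
    })
    median(rs)
  })
  expect_true(all(diff(med) > 0))
  expect_equal(med[3], 0, tolerance = 0.05)
})

test_that("uncoupled single-state pairs show only sampling-level correlation", {
  sp <- pair_spec(state_model(-60, 8), state_model(60, 8),
                  coupling = "copula", rho = 0, m = 5e4)
  xy <- sample_pair(sp, seed = 11)
  expect_lt(abs(circular_correlation(xy$x, xy$y)$r), 0.05)
  expect_lt(mutual_information(xy$x, xy$y), 0.04)
})

test_that("separated coupled states reproduce the analytic state-level MI", {
  tab <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  expect_equal(oracle_state_mi(tab), 0.8 * log(1.6) + 0.2 * log(0.4))
  sp <- pair_spec(
    state_model(c(-60, 60), 20, c(0.5, 0.5), dwell = 20),
    state_model(c(-60, 60), 20, c(0.5, 0.5), dwell = 20),
    coupling = "state_coupled", joint_states = tab, m = 2e5, dwell = 20
  )
  xy <- sample_pair(sp, seed = 77)
  expect_equal(xy$truth$state_mi, oracle_state_mi(tab))
  expect_equal(mutual_information(xy$x, xy$y), oracle_state_mi(tab),
               tolerance = 0.02)
  expect_equal(xy$truth$expected_class, "DMP")
  # invalid joint table (marginals do not match weights)
  expect_error(
    pair_spec(state_model(c(-60, 60), 20, c(0.7, 0.3)),
              state_model(c(-60, 60), 20),
              coupling = "state_coupled",
              joint_states = matrix(0.25, 2, 2)),
    "marginals"
  )
})

test_that("heterogeneous pairs are nonlinear; matched-slope controls are not flagged", {
  xy <- sample_heterogeneous_pair(c(-60, 60), c(0, 0), rho = c(0.8, -0.8),
                                  m = 1e5, seed = 21)
  cc <- circular_correlation(xy$x, xy$y)
  mi <- mutual_information(xy$x, xy$y)
  expect_equal(classify_linearity(mi, cc$r), "nonlinear")
  expect_true(xy$truth$heterogeneous)
  expect_equal(xy$truth$expected_linearity, "nonlinear")
  same <- sample_heterogeneous_pair(c(-60, 60), c(-60, 60), rho = c(0.8, 0.8),
                                    m = 1e5, seed = 21)
  expect_false(same$truth$heterogeneous)
  expect_error(sample_heterogeneous_pair(c(-60, 60), c(0, 0), rho = 0.8),
               "one rho per state")
})

test_that("an L-shaped single collective state is DSP yet nonlinear", {
  # two elliptical components in immediate contact: the 1D collective-bin
  # rule sees one peak per torsion, but conflicting local slopes push MI
  # above the contour (single-peak nonlinear case)
  xy <- sample_heterogeneous_pair(c(-66, -54), c(-51, -39), rho = c(0.85, -0.85),
                                  kappa = 30, dwell = 50, m = 2e5, seed = 31)
  px <- count_peaks_1d(histogram_1d(xy$x))
  py <- count_peaks_1d(histogram_1d(xy$y))
  expect_equal(classify_transition_status(px$n_peaks, py$n_peaks), "DSP")
  cc <- circular_correlation(xy$x, xy$y)
  mi <- mutual_information(xy$x, xy$y)
  expect_equal(classify_linearity(mi, cc$r), "nonlinear")
})

test_that("synthetic proteins assemble consistent tables, labels and geometry", {
  cp <- tibble::tibble(i = c(2, 8), j = c(11, 17),
                       type = c("copula", "heterogeneous"), rho = c(0.5, 0.8))
  pr <- sample_protein(10, m = 5000, seed = 42, couplings = cp)
  expect_equal(nrow(pr$index_map), 18)
  expect_equal(ncol(pr$torsions), 19)  # snapshot + 18
  expect_equal(nrow(pr$torsions), 5000)
  expect_equal(nrow(pr$ss), 10)
  expect_true(all(pr$dssp$code %in% c("H", "E", "T")))
  expect_equal(nrow(pr$structure), 30)
  expect_equal(pr$truth$couplings$expected_linearity, c("linear", "nonlinear"))
  # determinism
  pr2 <- sample_protein(10, m = 5000, seed = 42, couplings = cp)
  expect_identical(pr$torsions, pr2$torsions)
  # alpha/beta torsions have single-peak distributions (planted couplings
  # override the secondary-structure state models, so exclude them)
  ab_idx <- setdiff(pr$index_map$index[pr$ss$ss[pr$index_map$residue] != "L"],
                    c(cp$i, cp$j))
  for (k in ab_idx) {
    expect_equal(count_peaks_1d(histogram_1d(pr$torsions[[paste0("t", k)]]))$n_peaks, 1)
  }
  expect_error(sample_protein(10, couplings = tibble::tibble(i = 1, j = 99,
                                                             type = "copula")),
               "outside")
  expect_error(sample_protein(1), "n_residues")
})

test_that("secondary-structure torsions are single-peaked across seeds", {
  for (s in 1:10) {
    pr <- sample_protein(6, m = 5000, seed = s)
    helix <- pr$index_map$index[pr$ss$ss[pr$index_map$residue] == "alpha"]
    for (k in helix) {
      expect_equal(
        count_peaks_1d(histogram_1d(pr$torsions[[paste0("t", k)]]))$n_peaks, 1
      )
    }
  }
})
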