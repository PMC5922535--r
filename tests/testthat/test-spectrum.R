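test_that("line eigenfrequencies match the closed-form cosine band", {
  for (case in list(c(2, 1), c(5, 1), c(16, 0.5), c(64, 1), c(200, 1.7))) {
    n <- case[1]; s <- case[2]
    sp <- eigenmodes(line_connectivity(n, s))
    expect_equal(sp$omega, line_spectrum_oracle(n, s), tolerance = 1e-10)
  }
  # N = 2 collapses to a single mode at omega = s
  expect_equal(eigenmodes(line_connectivity(2))$omega, 1)
})

test_that("the quoted panel eigenfrequencies appear at ranks 2, 4, 6", {
  sp <- eigenmodes(line_connectivity(64, 1))
  expect_equal(round(sp$omega[c(2, 4, 6)], 2), c(1.99, 1.96, 1.92))
})

test_that("spectrum scales covariantly with the coupling strength", {
  base <- eigenmodes(line_connectivity(12, 1))
  scaled <- eigenmodes(line_connectivity(12, 3.5))
  expect_equal(scaled$omega, 3.5 * base$omega, tolerance = 1e-12)
  sig <- 2.5   # same covariance through a custom matrix
  A <- as.matrix(random_skew(9, seed = 7))
  expect_equal(eigenmodes(custom_connectivity(sig * A))$omega,
               sig * eigenmodes(custom_connectivity(A))$omega,
               tolerance = 1e-10)
})

test_that("eigenmodes satisfy residual, normalization and phase conventions", {
  conn <- line_connectivity(17, 1)
  A <- as.matrix(conn)
  sp <- eigenmodes(conn)
  expect_equal(length(sp$omega), 9)          # ceiling(N/2), conjugates dropped
  expect_true(all(diff(sp$omega) <= 0))
  for (k in seq_along(sp$omega)) {
    v <- sp$vectors[, k]
    expect_lt(sqrt(sum(Mod(A %*% v - 1i * sp$omega[k] * v)^2)), 1e-9)
    expect_equal(sum(Mod(v)^2), 1, tolerance = 1e-12)
    lead <- v[which.max(Mod(v))]
    expect_gt(Re(lead), 0)
    expect_lt(abs(Im(lead)), 1e-10)
  }
})

test_that("odd-sized skew networks carry an exact DC eigenmode", {
  for (n in c(3, 9, 33)) {
    A <- as.matrix(line_connectivity(n))
    expect_lt(min(Mod(eigen(A, only.values = TRUE)$values)), 1e-12)
    sp <- eigenmodes(line_connectivity(n))
    expect_equal(min(sp$omega), 0)
    dc <- sp$vectors[, length(sp$omega)]
    expect_identical(max(abs(Im(dc))), 0)    # DC eigenvector kept real
  }
})

test_that("line eigenvector moduli are symmetric about the chain midpoint", {
  sp <- eigenmodes(line_connectivity(24))
  for (k in seq_along(sp$omega)) {
    m <- Mod(sp$vectors[, k])
    expect_lt(max(abs(m - rev(m))), 1e-8)
  }
})

test_that("ring modes have uniform moduli; long range breaks uniformity", {
  for (n in c(4, 8, 9, 12, 32, 33))
    expect_lt(max_modulus_spread(eigenmodes(ring_connectivity(n, 1))), 1e-8)
  with_lr <- eigenmodes(ring_connectivity(32, 1, list(c(2, 1))))
  expect_gt(max_modulus_spread(with_lr), 0.01)
})

test_that("spatial frequency recovers envelope periodicity", {
  n <- 64
  expect_identical(spatial_frequency(rep(1 + 0i, n)), 0)
  v <- sin(3 * pi * (0:(n - 1)) / (n + 1))
  expect_lt(abs(spatial_frequency(v) - 3 / (2 * (n + 1))), 1 / (2 * n))
  expect_identical(spatial_frequency(v), spatial_frequency(Conj(v + 0i)))
  sp <- eigenmodes(line_connectivity(n))
  for (k in c(1, 4, 9))   # line mode k maps to k / (2 (N+1))
    expect_lt(abs(sp$spatial_frequency[k] - k / (2 * (n + 1))), 1 / (2 * n))
})

test_that("dispersion fit recovers an exact ellipse and orders pairs", {
  k <- seq(0.02, 0.4, length.out = 9)
  modes <- data.frame(spatial_frequency = k, omega = sqrt(1 - 4 * k^2))
  fit <- dispersion_fit(modes)
  expect_equal(fit$ellipse_constant, 2, tolerance = 1e-9)
  expect_equal(fit$scale, 1, tolerance = 1e-9)
  expect_equal(fit$goodness, 1, tolerance = 1e-9)
  expect_true(!is.unsorted(fit$pairs$spatial_frequency))
})

test_that("dispersion fit refuses degenerate inputs", {
  few <- data.frame(spatial_frequency = c(0.1, 0.2, 0.3, 0.4), omega = 1:4)
  expect_error(dispersion_fit(few), class = "critnet_fit_undetermined")
  same <- data.frame(spatial_frequency = rep(0.1, 6), omega = 1:6)
  expect_error(dispersion_fit(same), class = "critnet_fit_undetermined")
})

test_that("line dispersion is monotone with bounded goodness", {
  sp <- eigenmodes(line_connectivity(64))
  fit <- dispersion_fit(sp)
  expect_true(fit$goodness >= 0 && fit$goodness <= 1)
  expect_true(all(diff(fit$pairs$omega) < 0))   # omega strictly falls with k
})

test_that("mode extrema locate zeros and antinodes of the envelope", {
  sp <- eigenmodes(line_connectivity(64))
  md <- get_mode(sp, omega = 1.92)
  ex <- mode_extrema(md)
  expect_true(all(c(-1L, 64L) %in% ex$zeros))   # Dirichlet boundary zeros
  m <- Mod(md$eigenvector)
  expect_true(all(m[ex$antinodes + 1] > 0.75 * max(m)))
  inner <- setdiff(ex$zeros, c(-1L, 64L))
  expect_true(all(m[inner + 1] < 0.25 * max(m)))
})

test_that("get_mode selects by rank or nearest eigenfrequency", {
  sp <- eigenmodes(line_connectivity(64))
  expect_equal(get_mode(sp, rank = 6)$omega, get_mode(sp, omega = 1.92)$omega)
  expect_error(get_mode(sp, rank = 6, omega = 1.92),
               class = "critnet_invalid_argument")
  expect_error(get_mode(sp, rank = 99), class = "critnet_invalid_argument")
})
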