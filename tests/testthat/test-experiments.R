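test_that("a single-neuron network responds independently of input length", {
  c1 <- line_connectivity(1)
  md <- get_mode(eigenmodes(c1), rank = 1)
  ex <- length_response_experiment(c1, md, center = 0, strengths = c(0.5, 2),
                                   max_half_length = 4, verify = FALSE)
  for (cv in ex$curves) {
    expect_equal(diff(range(cv$responses)), 0)
    expect_equal(cv$input_lengths, rep(1L, 5))
  }
})

test_that("mirror-symmetric centres produce identical curves on the line", {
  conn <- line_connectivity(16)
  md <- get_mode(eigenmodes(conn), rank = 3)
  expect_lt(max(abs(Mod(md$eigenvector) - rev(Mod(md$eigenvector)))), 1e-8)
  a <- length_response_experiment(conn, md, center = 5, strengths = 1,
                                  max_half_length = 5, verify = FALSE)
  b <- length_response_experiment(conn, md, center = 10, strengths = 1,
                                  max_half_length = 5, verify = FALSE)
  expect_lt(max(abs(a$curves[[1]]$responses - b$curves[[1]]$responses)), 1e-8)
})

test_that("response grows with strength at every fixed input length", {
  conn <- line_connectivity(16)
  md <- get_mode(eigenmodes(conn), rank = 2)
  ex <- length_response_experiment(conn, md, center = 8,
                                   strengths = 2^(-4:2), verify = FALSE)
  resp <- vapply(ex$curves, function(cv) cv$responses,
                 numeric(length(ex$curves[[1]]$responses)))
  for (li in seq_len(nrow(resp)))
    expect_true(all(diff(resp[li, ]) >= -1e-10))
})

test_that("experiment grids are converged and stability-verified", {
  conn <- line_connectivity(16)
  md <- get_mode(eigenmodes(conn), rank = 2)
  ex <- length_response_experiment(conn, md, center = 8, strengths = c(0.25, 4))
  for (cv in ex$curves) {
    expect_true(all(cv$converged))
    expect_true(all(cv$stable))
  }
  df <- as.data.frame(ex)
  expect_true(all(c("omega", "strength", "half_length", "input_length",
                    "response_modulus", "iterations", "converged", "stable")
                  %in% names(df)))
})

test_that("rotating the input around a ring rotates the response with it", {
  rc <- ring_connectivity(12, 1, list(c(2, 0.5)))
  md <- get_mode(eigenmodes(rc), rank = 2)
  f <- forcing_pattern(md, 0, 2, 1)
  base <- newton_solve(rc, md$omega, f)
  m <- 2   # whole pattern (eigenvector included) shifted by m neurons
  shifted <- f$vector[((0:11 - m) %% 12) + 1]
  rot <- newton_solve(rc, md$omega, shifted)
  expect_lt(max(abs(Mod(rot$amplitude) -
                    Mod(base$amplitude)[((0:11 - m) %% 12) + 1])), 1e-8)
})

test_that("uniform ring modes suppress equally at every centre", {
  rc <- ring_connectivity(12, 1)
  md <- get_mode(eigenmodes(rc), rank = 2)
  sm <- suppression_vs_position(rc, md, centers = c(0, 3, 7), strength = 2,
                                max_half_length = 6, verify = FALSE)
  si <- sm$table$suppression_index
  expect_lt(max(si) - min(si), 1e-6)
})

test_that("long-range couplings create orientation-space surround suppression", {
  orx <- orientation_ring_experiment(32, 1, long_range = list(c(2, 1)),
                                     mode_rank = 2, strengths = 2^(-4:2),
                                     max_half_length = 16, verify = FALSE)
  expect_gt(max(orx$suppression$with_long_range), 0.05)
  expect_true(all(orx$suppression$with_long_range >=
                  orx$suppression$without_long_range - 1e-9))
})

test_that("suppression tracks proximity to eigenvector zeros (small network)", {
  conn <- line_connectivity(32)
  sp <- eigenmodes(conn)
  md <- get_mode(sp, rank = 3)
  ex <- mode_extrema(md)
  zero_c <- setdiff(ex$zeros, c(-1L, 32L))[1]
  anti_c <- ex$antinodes[which.min(abs(ex$antinodes - 16))]
  sm <- suppression_vs_position(conn, md, centers = sort(c(zero_c, anti_c)),
                                strength = 4, verify = FALSE)
  tab <- sm$table
  expect_gt(tab$suppression_index[tab$center == zero_c],
            tab$suppression_index[tab$center == anti_c])
  expect_lt(tab$suppression_index[tab$center == anti_c], 0.05)
})

test_that("decay scaling on the single oscillator gives the exact 2/3 law", {
  c1 <- line_connectivity(1)
  md <- get_mode(eigenmodes(c1), rank = 1)
  ds <- suppressWarnings(
    decay_scaling_experiment(c1, md, center = 0, strengths = 2^(-6:3),
                             half_length = 0))
  for (pl in ds$power_laws)
    expect_equal(pl$slope, 2 / 3, tolerance = 0.02 * 2 / 3)
})

test_that("presets are self-consistent and runnable at reduced scale", {
  p <- preset_config("decay_scan")
  expect_equal(2 * p$half_length + 1, 29)
  expect_equal(p$n_neurons, 32L)
  expect_equal(range(p$strengths), c(2^-10, 2^2))
  p3 <- preset_config("length_response")
  expect_equal(p3$n_neurons, 64L)
  expect_equal(p3$center, 32L)
  sp <- eigenmodes(line_connectivity(p3$n_neurons))
  expect_equal(round(sp$omega[c(2, 4, 6)], 2), c(1.99, 1.96, 1.92))
})
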