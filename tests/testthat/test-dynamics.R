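test_that("unforced single-oscillator decay follows the separable closed form", {
  c1 <- line_connectivity(1)
  tr <- integrate_rotating_frame(c1, 0, 0 + 0i, initial_state = 1 + 0i,
                                 max_time = 10, n_samples = 500)
  expect_lt(max(abs(tr$moduli[, 1] - 1 / sqrt(1 + 2 * tr$times))), 1e-7)
})

test_that("unforced energy is non-increasing for every topology", {
  cases <- list(line_connectivity(6), ring_connectivity(8, 1),
                ring_connectivity(9, 1, list(c(3, 0.5))),
                random_skew(7, seed = 11))
  set.seed(5)
  for (conn in cases) {
    n <- conn$n_neurons
    y0 <- complex(real = rnorm(n), imaginary = rnorm(n))
    tr <- integrate_rotating_frame(conn, 0.3, complex(n), initial_state = y0,
                                   max_time = 15, n_samples = 300)
    E <- rowSums(tr$moduli^2)
    expect_true(all(diff(E) <= 1e-8 * E[1]))
  }
})

test_that("transients from rest land on the Newton limit cycle", {
  conn <- line_connectivity(8)
  md <- get_mode(eigenmodes(conn), rank = 2)
  f <- forcing_pattern(md, 4, 2, 0.5)
  st <- newton_solve(conn, md$omega, f)
  tr <- integrate_rotating_frame(conn, md$omega, f, max_time = 400,
                                 steady_state = st, floor = 1e-8,
                                 n_samples = 2000)
  expect_lt(max(Mod(tr$final_state - st$amplitude)), 1e-6)
})

test_that("lab-frame integration reproduces rotating-frame moduli", {
  conn <- line_connectivity(4)
  md <- get_mode(eigenmodes(conn), rank = 1)
  f <- forcing_pattern(md, 1, 1, 0.5)
  a <- integrate_rotating_frame(conn, md$omega, f, max_time = 5, n_samples = 200)
  b <- integrate_rotating_frame(conn, md$omega, f, max_time = 5, n_samples = 200,
                                frame = "lab")
  expect_lt(max(abs(a$moduli - b$moduli)), 1e-6)
})

test_that("decay fitter recovers synthetic exponentials", {
  times <- seq(0, 5, length.out = 400)
  one <- synthetic_trace(-3, 1, times)
  fit <- fit_decay_segments(one, steady_state = 1, tail_margin = Inf,
                            floor = 1e-7)
  expect_equal(fit$n_segments, 1L)
  expect_equal(fit$segments$slope, -3, tolerance = 0.01)

  times2 <- seq(0, 14, length.out = 600)
  two <- synthetic_trace(c(-5, -0.5), c(1, 0.01), times2)
  fit2 <- fit_decay_segments(two, steady_state = 1, tail_margin = Inf,
                             floor = 1e-6)
  expect_equal(fit2$n_segments, 2L)
  fast <- fit2$segments[fit2$segments$label == "fast", ]
  slow <- fit2$segments[fit2$segments$label == "slow", ]
  expect_equal(fast$slope, -5, tolerance = 0.05)
  expect_equal(slow$slope, -0.5, tolerance = 0.05)
  # changepoint sits where the slow term overtakes the fast one
  cross <- log(0.01) / (-5 + 0.5)
  expect_gt(fit2$changepoint, fast$t_start)
  expect_lt(abs(fit2$changepoint - cross), 2)
})

test_that("noisy two-exponential traces are still recovered within 5%", {
  times <- seq(0, 14, length.out = 500)
  tr <- synthetic_trace(c(-5, -0.5), c(1, 0.01), times, noise = 0.01, seed = 42)
  fit <- fit_decay_segments(tr, steady_state = 1, tail_margin = Inf,
                            floor = 1e-6)
  expect_equal(fit$n_segments, 2L)
  expect_equal(fit$segments$slope[fit$segments$label == "fast"], -5,
               tolerance = 0.05)
  expect_equal(fit$segments$slope[fit$segments$label == "slow"], -0.5,
               tolerance = 0.05)
})

test_that("synthetic traces are seed-deterministic and validated", {
  times <- seq(0, 2, length.out = 50)
  a <- synthetic_trace(-2, 1, times, noise = 0.05, seed = 7)
  b <- synthetic_trace(-2, 1, times, noise = 0.05, seed = 7)
  expect_identical(a$moduli, b$moduli)
  c <- synthetic_trace(-2, 1, times, noise = 0.05, seed = 8)
  expect_false(identical(a$moduli, c$moduli))
  expect_error(synthetic_trace(2, 1, times), class = "critnet_invalid_argument")
  # piecewise form is continuous across its breakpoint
  pw <- synthetic_trace(c(-4, -1), 1, times, breakpoints = 1)
  r <- pw$moduli[, 1] - 1
  expect_true(all(abs(diff(log(r))) < 0.4))
})

test_that("single-oscillator transient from rest decays at -3 B^(2/3)", {
  c1 <- line_connectivity(1)
  B <- 4
  st <- newton_solve(c1, 0, B + 0i)
  tr <- integrate_rotating_frame(c1, 0, B + 0i, max_time = 50,
                                 steady_state = st, n_samples = 2000)
  fit <- fit_decay_segments(tr, st, neuron = 0)
  late <- fit$segments[nrow(fit$segments), ]
  expect_equal(late$slope, -3 * B^(2 / 3), tolerance = 0.1)
})

test_that("perturbed oscillators relax at both linearized rates in ratio 3", {
  # the linearization at the forced fixed point has rates 3 B^(2/3)
  # (amplitude direction) and B^(2/3) (phase direction); both appear in the
  # state-space distance |y(t) - Z|, fast first, in exact ratio 3
  c1 <- line_connectivity(1)
  for (B in c(2^-6, 2^-3, 1, 2^3)) {
    sig <- B^(2 / 3)
    st <- newton_solve(c1, 0, B + 0i)
    y0 <- st$amplitude + (1e-2 + 1e-4i) * Mod(st$amplitude)
    tr <- integrate_rotating_frame(c1, 0, B + 0i, initial_state = y0,
                                   max_time = 14 / sig, n_samples = 3000,
                                   keep_states = TRUE)
    d <- Mod(tr$states[, 1] - st$amplitude)
    # d(t) mixes the modes in quadrature, not additively, so the peeling
    # refinement's additive model is switched off here
    fit <- fit_decay_segments(distance_trace(tr$times, d), steady_state = 0,
                              floor = 1e-8 * Mod(st$amplitude),
                              min_segment_points = 30, peel = FALSE)
    expect_equal(fit$n_segments, 2L)
    fast <- fit$segments$slope[fit$segments$label == "fast"]
    slow <- fit$segments$slope[fit$segments$label == "slow"]
    expect_lt(fit$segments$t_start[fit$segments$label == "fast"],
              fit$segments$t_start[fit$segments$label == "slow"])
    expect_equal(fast, -3 * sig, tolerance = 0.1)
    expect_equal(slow, -sig, tolerance = 0.1)
  }
})

test_that("fitting demands an approach to the limit cycle and enough points", {
  times <- seq(0, 0.2, length.out = 30)
  far <- synthetic_trace(-0.1, 1, times)     # never near the floor
  expect_error(fit_decay_segments(far, steady_state = 1, floor = 1e-10),
               class = "critnet_fit_undetermined")
  short <- synthetic_trace(-3, 1, seq(0, 5, length.out = 8))
  expect_error(fit_decay_segments(short, steady_state = 1,
                                  min_segment_points = 10),
               class = "critnet_fit_undetermined")
})
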