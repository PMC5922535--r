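test_that("forcing pattern windows, clips and scales the eigenvector", {
  sp <- eigenmodes(line_connectivity(8))
  md <- get_mode(sp, rank = 1)
  f0 <- forcing_pattern(md, 3, 0, 2)          # window of one
  expect_equal(sum(f0$vector != 0), 1)
  expect_equal(f0$vector[4], 2 * md$eigenvector[4])
  full <- forcing_pattern(md, 4, 10, 1.5)     # fully clipped window
  expect_equal(full$vector, 1.5 * md$eigenvector)
  expect_equal(full$input_length, 8)
  zero <- forcing_pattern(md, 4, 2, 0)
  expect_true(all(zero$vector == 0))
  part <- forcing_pattern(md, 1, 3, 1)        # clipped at the left edge
  expect_equal(part$input_length, 5)
  expect_lte(sum(part$vector != 0), 2 * 3 + 1)
  expect_error(forcing_pattern(md, 8, 1, 1), class = "critnet_invalid_argument")
})

test_that("harmonic-balance residual matches hand values and closed forms", {
  c1 <- line_connectivity(1)
  expect_equal(hb_residual(2 + 0i, c1, 0, 8 + 0i), 0 + 0i)  # 8 - 2^3
  conn <- line_connectivity(6)
  f <- complex(real = 1:6, imaginary = 6:1) / 10
  expect_equal(hb_residual(complex(6), conn, 0.7, f), f)    # Z = 0 -> F
  # ring resonant closed form: Z = (N B)^(1/3) v has zero residual
  rc <- ring_connectivity(8, 1)
  md <- get_mode(eigenmodes(rc), rank = 1)
  B <- 0.7
  f8 <- forcing_pattern(md, 0, 4, B)
  Z <- (8 * B)^(1 / 3) * md$eigenvector
  expect_lt(max(Mod(hb_residual(Z, rc, md$omega, f8))), 1e-10)
  expect_error(hb_residual(complex(3), conn, 0, f),
               class = "critnet_invalid_argument")
})

test_that("realified Jacobian matches hand differentiation and finite differences", {
  c1 <- line_connectivity(1)
  u <- 1.3
  expect_equal(hb_jacobian(u + 0i, c1, 0),
               matrix(c(-3 * u^2, 0, 0, -u^2), 2))
  conn <- random_skew(5, seed = 1)
  set.seed(2)
  z <- complex(real = rnorm(5), imaginary = rnorm(5))
  f <- complex(real = rnorm(5), imaginary = rnorm(5))
  J <- hb_jacobian(z, conn, 0.7)
  expect_lt(max(abs(J - fd_jacobian(z, conn, 0.7, f))), 1e-6)
})

test_that("Jacobian is singular at the origin at an eigenfrequency", {
  conn <- line_connectivity(8)
  sp <- eigenmodes(conn)
  J0 <- hb_jacobian(complex(8), conn, sp$omega[1])
  expect_lt(min(svd(J0)$d), 1e-8)
})

test_that("Newton solver finds the resonant cubic-root response", {
  c1 <- line_connectivity(1)
  st <- newton_solve(c1, 0, 8 + 0i, initial_guess = 1 + 0i)
  expect_true(st$converged)
  expect_equal(st$amplitude, 2 + 0i, tolerance = 1e-10)
  for (B in c(0.001, 1, 1000)) {
    st <- newton_solve(c1, 0, B + 0i)
    expect_true(st$converged)
    expect_equal(Mod(st$amplitude), B^(1 / 3), tolerance = 1e-10)
  }
})

test_that("ring at resonance reaches the uniform closed-form amplitude", {
  rc <- ring_connectivity(8, 1)
  md <- get_mode(eigenmodes(rc), rank = 1)
  B <- 0.3
  f <- forcing_pattern(md, 0, 4, B)
  st <- newton_solve(rc, md$omega, f)
  expect_true(st$converged)
  expect_lt(max(abs(Mod(st$amplitude) - (8 * B)^(1 / 3) * Mod(md$eigenvector))),
            1e-8)
})

test_that("solutions are gauge covariant and scaling covariant", {
  conn <- line_connectivity(8)
  md <- get_mode(eigenmodes(conn), rank = 2)
  f <- forcing_pattern(md, 4, 2, 0.5)
  base <- newton_solve(conn, md$omega, f)
  phi <- pi / 3     # global input phase rotates the response identically
  rot <- newton_solve(conn, md$omega, f$vector * exp(1i * phi))
  expect_lt(max(Mod(rot$amplitude - base$amplitude * exp(1i * phi))), 1e-9)
  expect_equal(Mod(rot$amplitude), Mod(base$amplitude), tolerance = 1e-10)
  sig <- 4          # (A, omega, F) -> (sA, s w, s^1.5 F) maps Z -> sqrt(s) Z
  sc <- newton_solve(custom_connectivity(sig * as.matrix(conn)),
                     sig * md$omega, sig^1.5 * f$vector)
  expect_lt(max(Mod(sc$amplitude - sqrt(sig) * base$amplitude)), 1e-8)
})

test_that("DC forcing of an odd network is solved on the real subsystem", {
  conn <- line_connectivity(9)
  sp <- eigenmodes(conn)
  dc <- get_mode(sp, omega = 0)
  expect_equal(dc$omega, 0)
  f <- forcing_pattern(dc, 4, 3, 0.5)
  st <- newton_solve(conn, 0, f)
  expect_true(st$converged)
  expect_identical(max(abs(Im(st$amplitude))), 0)
  expect_lt(resid_norm <- st$residual_norm, 1e-10)
})

test_that("a singular Jacobian raises a typed error carrying the iterate", {
  conn <- line_connectivity(8)
  sp <- eigenmodes(conn)
  err <- tryCatch(
    newton_solve(conn, sp$omega[1], complex(real = rep(1e-6, 8)),
                 initial_guess = complex(8)),
    critnet_singular_jacobian = function(e) e)
  expect_s3_class(err, "critnet_singular_jacobian")
  expect_length(err$iterate, 8)
  st <- newton_solve(conn, sp$omega[1], complex(real = rep(1e-6, 8)),
                     initial_guess = complex(8), regularize = TRUE)
  expect_true(st$converged)   # regularized retry escapes the singular origin
})

test_that("continuation sweep warm-starts and reproduces the cubic law", {
  c1 <- line_connectivity(1)
  md <- get_mode(eigenmodes(c1), rank = 1)
  Bs <- 2^(-4:4)
  sw <- continuation_sweep(c1, md, 0, Bs, 0)
  expect_true(all(sw$converged))
  resp <- vapply(seq_along(Bs), function(i) Mod(sw$states[[i, 1]]$amplitude), 0)
  expect_equal(resp, Bs^(1 / 3), tolerance = 1e-9)

  conn <- line_connectivity(16)
  md <- get_mode(eigenmodes(conn), rank = 2)
  sw <- continuation_sweep(conn, md, 8, 2^(-4:2), 0:8)
  expect_true(all(sw$converged))
  cold <- vapply(2^(-4:2), function(B) stats::median(vapply(0:8, function(l)
    newton_solve(conn, md$omega,
                 forcing_pattern(md, 8, l, B))$iterations, 0L)), 0)
  expect_lte(stats::median(sw$iterations), stats::median(cold))
})

test_that("sweep input grids must be sorted and nonempty", {
  conn <- line_connectivity(4)
  md <- get_mode(eigenmodes(conn), rank = 1)
  expect_error(continuation_sweep(conn, md, 2, c(2, 1), 0:1),
               class = "critnet_invalid_argument")
  expect_error(continuation_sweep(conn, md, 2, numeric(0), 0:1),
               class = "critnet_invalid_argument")
})
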