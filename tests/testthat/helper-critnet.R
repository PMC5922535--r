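# shared oracles and fixtures, all generated in code

# closed-form eigenfrequencies of the alternating-sign open chain: the sign
# pattern is removable by a diagonal similarity, leaving the standard
# tridiagonal whose spectrum is 2 s cos(k pi / (N+1)), folded to omega >= 0
line_spectrum_oracle <- function(n, s = 1) {
  2 * s * cos(seq_len(ceiling(n / 2)) * pi / (n + 1))
}

# central finite differences of the realified harmonic-balance residual
fd_jacobian <- function(z, conn, omega, f, h = 1e-6) {
  n <- length(z)
  g_real <- function(zt) {
    zz <- complex(real = zt[1:n], imaginary = zt[(n + 1):(2 * n)])
    g <- hb_residual(zz, conn, omega, f)
    c(Re(g), Im(g))
  }
  zt <- c(Re(z), Im(z))
  J <- matrix(0, 2 * n, 2 * n)
  for (j in seq_len(2 * n)) {
    e <- numeric(2 * n); e[j] <- h
    J[, j] <- (g_real(zt + e) - g_real(zt - e)) / (2 * h)
  }
  J
}

# reproducible random skew-symmetric coupling
random_skew <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n)
  custom_connectivity((m - t(m)) / 2)
}

max_modulus_spread <- function(spectrum) {
  max(apply(Mod(spectrum$vectors), 2, function(m) max(m) - min(m)))
}

# wrap a precomputed scalar residual series as a single-neuron trace so the
# decay fitter can be pointed at arbitrary observables (steady modulus 0)
distance_trace <- function(times, values) {
  structure(list(times = times, moduli = matrix(values, ncol = 1),
                 states = NULL, final_state = values[length(values)],
                 forcing_strength = NA_real_, neuron_index = 0L,
                 meta = list(frame = "derived")),
            class = "transient_trace")
}
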