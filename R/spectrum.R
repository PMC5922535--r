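#' Eigenmode spectrum of a critically balanced network
#'
#' Diagonalizes the skew-symmetric coupling matrix \eqn{A}.  Because \eqn{A}
#' is real skew-symmetric, \eqn{iA} is Hermitian and all eigenvalues of
#' \eqn{A} are purely imaginary, \eqn{\lambda = i\omega}: every mode is
#' marginally stable and responds resonantly when driven at its
#' eigenfrequency \eqn{\omega}.  Eigenvalues come in conjugate pairs
#' \eqn{\pm i\omega}; one mode per pair is kept (the \eqn{\omega \ge 0}
#' member), so a network of \eqn{N} neurons yields `ceiling(N/2)` modes,
#' sorted by descending eigenfrequency (`mode_rank` 1 = largest).  For odd
#' \eqn{N} the spectrum contains an exact zero eigenfrequency (the DC mode)
#' whose eigenvector is real.
#'
#' Eigenvector conventions: unit Euclidean norm, and the first component of
#' largest modulus is rotated to be real and positive.  For ring topologies,
#' degenerate eigenfrequency pairs (clockwise/counterclockwise travelling
#' waves) are disambiguated by simultaneously diagonalizing the two-neuron
#' translation operator on each degenerate subspace, which restores the
#' translation-covariant (uniform-modulus) basis that a numerical
#' eigensolver is free to mix.
#'
#' @param connectivity a [connectivity][line_connectivity] object (or skew
#'   matrix).
#' @param residual_tol maximum allowed eigenpair residual
#'   \eqn{\lVert Av - i\omega v\rVert_2}.
#' @param zero_tol relative threshold below which an eigenfrequency is
#'   treated as exactly zero.
#' @return An object of class `eigen_spectrum`: list with `omega`
#'   (descending), `vectors` (complex matrix, one column per mode),
#'   `mode_rank`, `spatial_frequency` (cycles per neuron, see
#'   [spatial_frequency()]), `residual`, and the originating topology/size.
#' @examples
#' sp <- eigenmodes(line_connectivity(8))
#' sp$omega                      # 2 * cos(k * pi / 9), k = 1..4
#' get_mode(sp, rank = 1)
#' @export
eigenmodes <- function(connectivity, residual_tol = 1e-9, zero_tol = 1e-12) {
  A <- as_conn_matrix(connectivity)
  n <- nrow(A)
  topology <- if (inherits(connectivity, "connectivity")) connectivity$topology else "custom"

  ed <- tryCatch(eigen(1i * A), error = function(e)
    critnet_stop("critnet_numerical_failure",
                 sprintf("eigendecomposition failed for %d x %d matrix (max |A| = %.3g): %s",
                         n, n, max(abs(A)), conditionMessage(e))))
  mu <- Re(ed$values)          # iA is Hermitian: eigenvalues real, decreasing
  omega_all <- -mu             # A v = i * omega * v  with  omega = -mu
  scale <- max(abs(mu), 1)

  S <- if (topology == "ring") ring_shift_operator(A) else NULL

  zero <- abs(omega_all) <= zero_tol * scale
  keep <- which(omega_all > 0 & !zero)
  V <- ed$vectors[, keep, drop = FALSE]
  omega <- omega_all[keep]
  if (any(zero)) {             # zero eigenvalues pair up too: keep half, realified
    zi <- which(zero)
    m <- ceiling(length(zi) / 2)
    Vz <- ed$vectors[, zi, drop = FALSE]
    W <- qr.Q(qr(cbind(Re(Vz), Im(Vz))))[, seq_len(length(zi)), drop = FALSE]
    if (!is.null(S) && length(zi) > 1) {
      # rotate the real null basis into shift eigenvectors; real eigenvalues
      # (+1/-1) give the translation-covariant DC modes
      es <- eigen(t(W) %*% S %*% W)
      if (max(abs(Im(es$values))) < 1e-8) {
        W <- W %*% Re(es$vectors)[, order(Re(es$values), decreasing = TRUE)]
        W <- apply(W, 2, function(v) v / sqrt(sum(v^2)))
      }
    }
    V <- cbind(V, W[, seq_len(m), drop = FALSE] + 0i)
    omega <- c(omega, rep(0, m))
  }
  ord <- order(omega, decreasing = TRUE)
  V <- V[, ord, drop = FALSE]
  omega <- omega[ord]

  if (!is.null(S))
    V <- symmetrize_degenerate(A, S, V, omega, residual_tol)

  V <- apply(V, 2, fix_phase)
  V <- matrix(V, nrow = n)
  resid <- vapply(seq_along(omega), function(k)
    sqrt(sum(Mod(A %*% V[, k] - 1i * omega[k] * V[, k])^2)), 0)
  if (max(resid) > residual_tol)
    critnet_stop("critnet_numerical_failure",
                 sprintf("eigenpair residual %.3g exceeds %.3g", max(resid), residual_tol))

  sf <- apply(V, 2, spatial_frequency)
  structure(list(omega = omega, vectors = V, mode_rank = seq_along(omega),
                 spatial_frequency = sf, residual = resid,
                 n_neurons = n, topology = topology,
                 coupling_strength = if (inherits(connectivity, "connectivity"))
                   connectivity$coupling_strength else NA_real_),
            class = "eigen_spectrum")
}

# rotate so the first component of largest modulus is real positive;
# zap negligible imaginary parts (real DC eigenvectors come out exactly real)
fix_phase <- function(v) {
  v <- v / sqrt(sum(Mod(v)^2))
  i <- which.max(Mod(v))
  ph <- v[i] / Mod(v[i])
  v <- v * Conj(ph)
  if (max(abs(Im(v))) < 1e-10) v <- complex(real = Re(v), imaginary = 0)
  v
}

# Signed one-neuron shift operator of an alternating-sign ring:
# (Sv)_i = eps_i v_{i-1 mod n}, with the signs solving the commutation
# condition sigma_i = eps_{i+1} eps_i sigma_{i-1} for the nearest-neighbour
# bond signs sigma_i = sign(A[i+1, i]).  The consistency product around the
# ring telescopes to (prod sigma)^2 = 1, so S always exists; it commutes
# with the nearest-neighbour couplings (and with odd-offset long-range
# bonds), and its eigenvectors are the uniform-modulus travelling waves.
ring_shift_operator <- function(A) {
  n <- nrow(A)
  i <- 0:(n - 1)
  sigma <- sign(A[cbind((i + 1) %% n + 1, i + 1)])
  if (any(sigma == 0)) return(NULL)
  eps <- numeric(n)
  eps[1] <- 1
  for (k in seq_len(n - 1))      # eps_{i+1} = sigma_i sigma_{i-1} eps_i
    eps[k + 1] <- sigma[k] * sigma[((k - 2) %% n) + 1] * eps[k]
  S <- matrix(0, n, n)
  S[cbind(i + 1, ((i - 1) %% n) + 1)] <- eps
  S
}

# Within each degenerate eigenfrequency group, re-diagonalize the
# restriction of the signed shift S, restoring the translation-covariant
# (uniform-modulus) basis that a numerical eigensolver is free to mix.
# Rotated vectors are only accepted if they remain eigenvectors of A to
# residual_tol, so the step is a no-op on networks where the symmetry is
# broken (for example, even-offset long-range bonds).
symmetrize_degenerate <- function(A, S, V, omega, residual_tol) {
  groups <- split(seq_along(omega),
                  cumsum(c(1, abs(diff(omega)) > 1e-8 * max(1, max(abs(omega))))))
  for (g in groups) {
    if (length(g) < 2) next
    Vg <- V[, g, drop = FALSE]
    T <- Conj(t(Vg)) %*% (S %*% Vg)
    W <- Vg %*% eigen(T)$vectors
    W <- apply(W, 2, function(v) v / sqrt(sum(Mod(v)^2)))
    W <- matrix(W, nrow = nrow(V))
    ok <- all(vapply(seq_along(g), function(k)
      sqrt(sum(Mod(A %*% W[, k] - 1i * omega[g[k]] * W[, k])^2)) <= residual_tol, TRUE))
    if (ok) V[, g] <- W
  }
  V
}

#' Extract one eigenmode from a spectrum
#'
#' @param spectrum an `eigen_spectrum` from [eigenmodes()].
#' @param rank mode rank (1 = largest eigenfrequency), or
#' @param omega target eigenfrequency; the mode with the closest
#'   eigenfrequency is returned.
#' @return An object of class `eigen_mode`: list with `omega`, `eigenvector`
#'   (unit norm), `mode_rank`, `spatial_frequency`, `n_neurons`.
#' @export
get_mode <- function(spectrum, rank = NULL, omega = NULL) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  if (is.null(rank) == is.null(omega))
    critnet_stop("critnet_invalid_argument", "give exactly one of `rank` or `omega`")
  k <- if (!is.null(rank)) check_count(rank, "rank")
       else which.min(abs(spectrum$omega - omega))
  if (k > length(spectrum$omega))
    critnet_stop("critnet_invalid_argument",
                 sprintf("rank %d exceeds the %d available modes", k, length(spectrum$omega)))
  structure(list(omega = spectrum$omega[k],
                 eigenvector = spectrum$vectors[, k],
                 mode_rank = k,
                 spatial_frequency = spectrum$spatial_frequency[k],
                 n_neurons = spectrum$n_neurons,
                 topology = spectrum$topology),
            class = "eigen_mode")
}

#' Spatial frequency of an eigenvector's modulus envelope
#'
#' Eigenvectors of the alternating-sign chain are standing waves: a two-neuron
#' excitatory/inhibitory carrier under a slowly varying envelope
#' \eqn{|v_j| \propto |\sin(k\pi (j+1)/(N+1))|}.  The modulus envelope is
#' carrier-free by construction, but taking the modulus rectifies the standing
#' wave and doubles its frequency, so the dominant discrete-Fourier frequency
#' of the centred envelope is halved to recover the wave's spatial frequency
#' in cycles per neuron (mode \eqn{k} of an \eqn{N}-chain maps to
#' \eqn{k / (2(N+1))}).  A constant-modulus vector (for example a ring
#' travelling wave) returns 0.
#'
#' @param mode an `eigen_mode`, or a numeric/complex vector.
#' @return Spatial frequency in cycles per neuron (nonnegative).
#' @export
spatial_frequency <- function(mode) {
  v <- if (inherits(mode, "eigen_mode")) mode$eigenvector else mode
  if (!(is.numeric(v) || is.complex(v)) || length(v) == 0)
    critnet_stop("critnet_invalid_argument", "`mode` must carry an eigenvector")
  m <- Mod(v)
  n <- length(m)
  if (n < 4 || max(m) - min(m) <= 1e-8 * max(m, 1)) return(0)
  e <- m - mean(m)
  p <- Mod(stats::fft(e))^2
  q <- which.max(p[2:(floor(n / 2) + 1)])   # dominant non-DC bin, freq q/n
  (q / n) / 2
}

#' Fit an elliptical dispersion relation to a mode set
#'
#' Regresses squared eigenfrequency on squared spatial frequency,
#' \eqn{\omega^2 = \mathrm{scale} - c^2 k^2}, the elliptical dispersion
#' relation expected for critically balanced lattices.  The fit is reported,
#' not asserted: `goodness` is the coefficient of determination, and callers
#' decide whether the ellipse is an adequate description.
#'
#' @param modes an `eigen_spectrum`, a list of `eigen_mode` objects, or a
#'   data frame with columns `spatial_frequency` and `omega`.
#' @return An object of class `dispersion_fit` with `pairs` (sorted by k),
#'   `ellipse_constant` (c), `scale`, `goodness`.
#' @export
dispersion_fit <- function(modes) {
  if (inherits(modes, "eigen_spectrum"))
    df <- data.frame(spatial_frequency = modes$spatial_frequency, omega = modes$omega)
  else if (is.data.frame(modes))
    df <- modes[, c("spatial_frequency", "omega")]
  else if (is.list(modes))
    df <- data.frame(
      spatial_frequency = vapply(modes, function(m) m$spatial_frequency, 0),
      omega = vapply(modes, function(m) m$omega, 0))
  else
    critnet_stop("critnet_invalid_argument", "unsupported `modes` input")

  k <- df$spatial_frequency
  if (length(unique(k)) < 5)
    critnet_stop("critnet_fit_undetermined",
                 "dispersion fit needs at least 5 modes with distinct spatial frequencies")
  if (diff(range(k)) < 1e-12)
    critnet_stop("critnet_fit_undetermined", "degenerate spatial-frequency range")

  fit <- stats::lm(I(omega^2) ~ I(spatial_frequency^2), data = df)
  co <- stats::coef(fit)
  y <- df$omega^2
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst)) else 1
  pairs <- df[order(df$spatial_frequency), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 ellipse_constant = sqrt(max(0, -co[[2]])),
                 scale = co[[1]],
                 goodness = r2),
            class = "dispersion_fit")
}

#' Locate zeros and antinodes of an eigenvector modulus profile
#'
#' Zeros are interior local minima of \eqn{|v_j|} below `zero_frac` of the
#' profile maximum, plus the virtual Dirichlet zeros just outside a line
#' network; antinodes are local maxima above `antinode_frac` of the maximum.
#' Used to choose readout neurons programmatically: neurons near eigenvector
#' zeros show the strongest surround suppression, neurons at antinodes almost
#' none.
#'
#' @param mode an `eigen_mode`.
#' @param zero_frac,antinode_frac thresholds relative to `max(|v|)`.
#' @return list with integer vectors `zeros` and `antinodes` (0-based,
#'   virtual boundary zeros at -1 and N).
#' @export
mode_extrema <- function(mode, zero_frac = 0.25, antinode_frac = 0.75) {
  m <- Mod(if (inherits(mode, "eigen_mode")) mode$eigenvector else mode)
  n <- length(m)
  pad <- c(Inf, m, Inf)
  is_min <- vapply(seq_len(n), function(i) m[i] <= pad[i] && m[i] <= pad[i + 2], TRUE)
  pad0 <- c(-Inf, m, -Inf)
  is_max <- vapply(seq_len(n), function(i) m[i] >= pad0[i] && m[i] >= pad0[i + 2], TRUE)
  zeros <- which(is_min & m < zero_frac * max(m)) - 1L
  zeros <- c(-1L, zeros, n)     # Dirichlet boundary: envelope vanishes off-chain
  antinodes <- which(is_max & m > antinode_frac * max(m)) - 1L
  list(zeros = zeros, antinodes = antinodes)
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum: %s network, N = %d, %d modes>\n",
              x$topology, x$n_neurons, length(x$omega)))
  print(utils::head(as.data.frame(x), 8))
  if (length(x$omega) > 8) cat(sprintf("  ... %d more modes\n", length(x$omega) - 8))
  invisible(x)
}

#' @export
as.data.frame.eigen_spectrum <- function(x, ...) {
  data.frame(mode_rank = x$mode_rank, omega = x$omega,
             spatial_frequency = x$spatial_frequency)
}

#' @export
print.eigen_mode <- function(x, ...) {
  cat(sprintf("<eigen_mode: rank %d, omega = %.6g, spatial frequency = %.4g cycles/neuron>\n",
              x$mode_rank, x$omega, x$spatial_frequency))
  invisible(x)
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion_fit: omega^2 = %.4g - (%.4g k)^2, R^2 = %.4f, %d modes>\n",
              x$scale, x$ellipse_constant, x$goodness, nrow(x$pairs)))
  invisible(x)
}

#' @export
plot.eigen_spectrum <- function(x, ...) {
  graphics::plot(x$spatial_frequency, x$omega, xlab = "spatial frequency (cycles/neuron)",
                 ylab = expression(omega), main = "Dispersion of network eigenmodes", ...)
  invisible(x)
}
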