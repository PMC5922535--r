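#' Eigenvector-patterned forcing over a finite window
#'
#' Builds the complex drive pattern used in the length-tuning experiments: a
#' bar of "light" of strength \eqn{B} (linear in stimulus contrast) covering
#' the \eqn{2l+1} neurons centred on neuron \eqn{c}, spatially shaped by the
#' driving eigenvector,
#' \deqn{F_k = B v_k \;\; \mathrm{for}\; k \in [c-l,\, c+l] \cap [0, N-1],
#'       \qquad F_k = 0 \;\mathrm{otherwise}.}
#' On a line the window is clipped at the network boundary; on a ring
#' (periodic orientation space) it wraps around instead.  Either way the
#' realized input length is `min(2l+1, covered neurons)`.
#'
#' @param mode the driving [eigen_mode][get_mode] (supplies the eigenvector
#'   \eqn{v} and eigenfrequency \eqn{\omega}).
#' @param center 0-based index \eqn{c} of the centre neuron.
#' @param half_length nonnegative integer \eqn{l}; the input covers
#'   \eqn{2l+1} neurons before clipping.
#' @param strength input strength \eqn{B \ge 0}.
#' @return An object of class `forcing_pattern`: list with `vector` (length
#'   N, complex), `strength`, `center`, `half_length`, `input_length`
#'   (after clipping), `omega`, `mode_rank`.
#' @export
forcing_pattern <- function(mode, center, half_length, strength) {
  stopifnot(inherits(mode, "eigen_mode"))
  n <- mode$n_neurons
  c0 <- check_index(center, n, "center")
  l <- check_count(half_length + 1, "half_length + 1") - 1L
  B <- check_positive(strength, "strength", strict = FALSE)
  idx <- if (identical(mode$topology, "ring")) unique((c0 + (-l:l)) %% n)
         else max(0L, c0 - l):min(n - 1L, c0 + l)
  f <- complex(n)
  f[idx + 1L] <- B * mode$eigenvector[idx + 1L]
  structure(list(vector = f, strength = B, center = c0, half_length = l,
                 input_length = length(idx), omega = mode$omega,
                 mode_rank = mode$mode_rank),
            class = "forcing_pattern")
}

as_forcing_vector <- function(forcing, n) {
  f <- if (inherits(forcing, "forcing_pattern")) forcing$vector else forcing
  if (length(f) != n)
    critnet_stop("critnet_invalid_argument",
                 sprintf("forcing has length %d, expected %d", length(f), n))
  as.complex(f)
}

#' Harmonic-balance residual
#'
#' For monochromatic drive \eqn{I(t) = F e^{i\omega t}} the limit-cycle
#' ansatz \eqn{X(t) = Z e^{i\omega t}} reduces the network ODE to the
#' algebraic balance
#' \deqn{g(Z) = (A - i\omega I)Z - |Z|^2 \circ Z + F = 0,}
#' with the cubic term acting componentwise (nonlinearities are purely
#' local).  This function evaluates \eqn{g(Z)}.
#'
#' @param amplitude complex amplitude vector \eqn{Z}.
#' @param connectivity a `connectivity` object (or skew matrix).
#' @param omega driving frequency (rad per unit time).
#' @param forcing a `forcing_pattern` or complex vector \eqn{F}.
#' @return Complex residual vector \eqn{g(Z)}.
#' @export
hb_residual <- function(amplitude, connectivity, omega, forcing) {
  A <- as_conn_matrix(connectivity)
  n <- nrow(A)
  f <- as_forcing_vector(forcing, n)
  if (length(amplitude) != n)
    critnet_stop("critnet_invalid_argument",
                 sprintf("amplitude has length %d, expected %d", length(amplitude), n))
  z <- as.complex(amplitude)
  drop(A %*% z) - 1i * omega * z - Mod(z)^2 * z + f
}

#' Realified Jacobian of the harmonic-balance residual
#'
#' The residual is not complex-differentiable (it involves \eqn{|Z|^2}), so
#' Newton's method operates on the realified system: with \eqn{Z = u + iv}
#' and \eqn{\tilde g = [\mathrm{Re}\,g;\, \mathrm{Im}\,g]}, the analytic
#' Jacobian is the \eqn{2N \times 2N} block matrix
#' \deqn{J = \begin{pmatrix} A - \mathrm{diag}(3u^2+v^2) &
#'   \omega I - \mathrm{diag}(2uv) \\ -\omega I - \mathrm{diag}(2uv) &
#'   A - \mathrm{diag}(u^2+3v^2) \end{pmatrix}.}
#' At \eqn{Z = 0} with \eqn{\omega} an eigenfrequency this matrix is exactly
#' singular (resonance), which is why the Newton solver never seeds at zero.
#'
#' @inheritParams hb_residual
#' @return Real \eqn{2N \times 2N} matrix, ordered `[Re(Z); Im(Z)]`.
#' @export
hb_jacobian <- function(amplitude, connectivity, omega) {
  A <- as_conn_matrix(connectivity)
  n <- nrow(A)
  if (length(amplitude) != n)
    critnet_stop("critnet_invalid_argument",
                 sprintf("amplitude has length %d, expected %d", length(amplitude), n))
  u <- Re(amplitude); v <- Im(amplitude)
  wI <- diag(omega, n)
  rbind(cbind(A - diag(3 * u^2 + v^2, nrow = n),  wI - diag(2 * u * v, nrow = n)),
        cbind(-wI - diag(2 * u * v, nrow = n),    A - diag(u^2 + 3 * v^2, nrow = n)))
}

new_steady_state <- function(Z, omega, residual_norm, iterations, converged,
                             stable = NA, forcing = NULL) {
  structure(list(amplitude = Z, omega = omega, residual_norm = residual_norm,
                 iterations = iterations, converged = converged, stable = stable,
                 forcing = forcing),
            class = "steady_state")
}

#' Solve the harmonic-balance equation by damped Newton iteration
#'
#' Finds the forced limit-cycle amplitude \eqn{Z} with
#' \eqn{g(Z) = (A - i\omega)Z - |Z|^2 Z + F = 0} by multivariable
#' Newton-Raphson on the realified system, with optional step-halving
#' damping (up to 20 halvings whenever a full step fails to decrease the
#' residual max-norm; accepted full steps reproduce the undamped iteration).
#'
#' The default seed is the componentwise signed cube root
#' \eqn{Z^{(0)}_k = |F_k|^{1/3}\,\mathrm{phase}(F_k)}: at resonance the
#' Jacobian at \eqn{Z = 0} is singular, while the cube-root seed matches the
#' resonant balance \eqn{|Z|^2 Z \approx F} exactly in the uniform-mode
#' limit.  For the DC mode (\eqn{\omega = 0} with real forcing, the odd-N
#' direct-current input) the iteration runs on the N-dimensional real
#' system.
#'
#' @inheritParams hb_residual
#' @param initial_guess starting amplitude; `NULL` for the cube-root seed.
#' @param tolerance convergence threshold on the residual max-norm of the
#'   realified system.
#' @param max_iterations Newton step budget.
#' @param damping logical; enable step-halving.
#' @param regularize logical; when the Jacobian is numerically singular at
#'   an iterate (for example point forcing at a node of the driving
#'   eigenvector, which leaves the resonant operator essentially
#'   unperturbed), take a Levenberg-Marquardt step
#'   \eqn{(J^\top J + \lambda^2 I)^{-1} J^\top (-\tilde g)} instead of
#'   raising a singular-Jacobian error.  Off by default; the continuation
#'   sweep retries failed cells with it.
#' @return A `steady_state` object: `amplitude`, `omega`, `residual_norm`,
#'   `iterations`, `converged`, `stable` (`NA` until
#'   [verify_stability()] is run), `forcing`.
#' @examples
#' conn <- line_connectivity(1)          # single critical oscillator
#' st <- newton_solve(conn, 0, 8 + 0i)   # cubic balance: Z^3 = 8
#' Mod(st$amplitude)                     # 2
#' @export
newton_solve <- function(connectivity, omega, forcing, initial_guess = NULL,
                         tolerance = 1e-10, max_iterations = 100L, damping = TRUE,
                         regularize = FALSE) {
  A <- as_conn_matrix(connectivity)
  n <- nrow(A)
  f <- as_forcing_vector(forcing, n)
  tolerance <- check_positive(tolerance, "tolerance")
  max_iterations <- check_count(max_iterations, "max_iterations")

  if (is.null(initial_guess)) {
    m <- Mod(f)
    ph <- ifelse(m > 0, f / m, 0 + 0i)
    z <- m^(1 / 3) * ph
  } else {
    if (length(initial_guess) != n)
      critnet_stop("critnet_invalid_argument", "initial_guess has the wrong length")
    z <- as.complex(initial_guess)
  }

  real_dc <- omega == 0 && all(Im(f) == 0) && all(Im(z) == 0)

  g <- hb_residual(z, A, omega, f)
  rn <- resid_maxnorm(g)
  it <- 0L
  while (rn > tolerance && it < max_iterations) {
    it <- it + 1L
    if (real_dc) {
      J <- A - diag(3 * Re(z)^2, nrow = n)
      rhs <- -Re(g)
    } else {
      J <- hb_jacobian(z, A, omega)
      rhs <- -c(Re(g), Im(g))
    }
    delta <- tryCatch(solve(J, rhs), error = function(e) {
      if (!regularize)
        critnet_stop("critnet_singular_jacobian",
                     sprintf("singular Jacobian at Newton iteration %d: %s",
                             it, conditionMessage(e)),
                     data = list(iterate = z))
      lam2 <- (1e-7 * max(abs(J)))^2
      solve(crossprod(J) + diag(lam2, nrow(J)), crossprod(J, rhs))
    })
    dz <- if (real_dc) complex(real = delta, imaginary = 0)
          else complex(real = delta[1:n], imaginary = delta[(n + 1):(2 * n)])

    step <- 1
    for (h in 0:20) {
      z_new <- z + step * dz
      g_new <- hb_residual(z_new, A, omega, f)
      rn_new <- resid_maxnorm(g_new)
      if (!damping || (is.finite(rn_new) && rn_new < rn)) break
      step <- step / 2
    }
    if (!all(is.finite(c(Re(z_new), Im(z_new)))) || !is.finite(rn_new))
      critnet_stop("critnet_divergence",
                   sprintf("non-finite iterate at Newton iteration %d", it),
                   data = list(iterate = z))
    z <- z_new; g <- g_new; rn <- rn_new
  }
  new_steady_state(z, omega, rn, it, converged = rn <= tolerance,
                   forcing = if (inherits(forcing, "forcing_pattern")) forcing else NULL)
}

#' Warm-started steady-state sweep over strengths and input lengths
#'
#' Solves the harmonic-balance equation over the full (strength, half-length)
#' grid of a length-tuning experiment.  Each cell is warm-started from its
#' nearest previously solved neighbour (same strength and previous
#' half-length, falling back to the previous strength), which tracks the
#' weak-forcing solution branch by continuation; the very first cell uses
#' the cube-root seed.  Non-converged cells are kept in the grid, flagged,
#' and reported via a warning with their coordinates.
#'
#' @inheritParams newton_solve
#' @param mode driving [eigen_mode][get_mode].
#' @param center 0-based centre neuron of the forcing window.
#' @param strengths ascending vector of input strengths \eqn{B}.
#' @param half_lengths ascending vector of window half-lengths \eqn{l}.
#' @param verify logical; run [verify_stability()] on each converged cell.
#' @param stability_method passed to [verify_stability()].
#' @return An object of class `steady_state_grid`: `states` (list matrix,
#'   strengths by half-lengths), `strengths`, `half_lengths`, `iterations`,
#'   `converged`, `stable` matrices, and drive metadata.
#' @export
continuation_sweep <- function(connectivity, mode, center, strengths, half_lengths,
                               tolerance = 1e-10, max_iterations = 100L,
                               damping = TRUE, verify = FALSE,
                               stability_method = "eigen") {
  stopifnot(inherits(mode, "eigen_mode"))
  if (length(strengths) == 0 || is.unsorted(strengths, strictly = FALSE))
    critnet_stop("critnet_invalid_argument", "`strengths` must be nonempty and ascending")
  if (length(half_lengths) == 0 || is.unsorted(half_lengths, strictly = FALSE))
    critnet_stop("critnet_invalid_argument", "`half_lengths` must be nonempty and ascending")

  nS <- length(strengths); nL <- length(half_lengths)
  states <- vector("list", nS * nL)
  dim(states) <- c(nS, nL)
  iters <- conv <- stab <- matrix(NA, nS, nL)

  for (si in seq_len(nS)) {
    for (li in seq_len(nL)) {
      f <- forcing_pattern(mode, center, half_lengths[li], strengths[si])
      guess <- if (li > 1 && isTRUE(conv[si, li - 1])) states[[si, li - 1]]$amplitude
               else if (si > 1 && isTRUE(conv[si - 1, li])) states[[si - 1, li]]$amplitude
               else NULL
      st <- tryCatch(
        newton_solve(connectivity, mode$omega, f, initial_guess = guess,
                     tolerance = tolerance, max_iterations = max_iterations,
                     damping = damping),
        critnet_error = function(e) tryCatch(   # retry with a regularized step
          newton_solve(connectivity, mode$omega, f, initial_guess = guess,
                       tolerance = tolerance, max_iterations = max_iterations,
                       damping = damping, regularize = TRUE),
          critnet_error = function(e2)
            new_steady_state(e2$iterate %||% complex(mode$n_neurons), mode$omega,
                             Inf, NA_integer_, converged = FALSE, forcing = f)))
      if (verify && isTRUE(st$converged))
        st$stable <- verify_stability(st, connectivity, f, method = stability_method)
      states[[si, li]] <- st
      iters[si, li] <- st$iterations
      conv[si, li] <- st$converged
      stab[si, li] <- st$stable
    }
  }
  if (!all(conv)) {
    bad <- which(!conv, arr.ind = TRUE)
    warning(sprintf("%d grid cell(s) did not converge: %s", nrow(bad),
                    paste(sprintf("(B = %g, l = %d)", strengths[bad[, 1]],
                                  half_lengths[bad[, 2]]), collapse = ", ")))
  }
  structure(list(states = states, strengths = strengths, half_lengths = half_lengths,
                 iterations = iters, converged = conv, stable = stab,
                 center = center, omega = mode$omega, mode_rank = mode$mode_rank,
                 n_neurons = mode$n_neurons),
            class = "steady_state_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state: N = %d, omega = %.6g, |Z|max = %.6g, %s in %d iteration(s), residual %.3g, stable = %s>\n",
              length(x$amplitude), x$omega, max(Mod(x$amplitude)),
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations, x$residual_norm, format(x$stable)))
  invisible(x)
}

#' @export
print.steady_state_grid <- function(x, ...) {
  cat(sprintf("<steady_state_grid: %d strengths x %d half-lengths, omega = %.6g, %d/%d converged>\n",
              length(x$strengths), length(x$half_lengths), x$omega,
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' @export
as.data.frame.steady_state_grid <- function(x, ...) {
  grid <- expand.grid(si = seq_along(x$strengths), li = seq_along(x$half_lengths))
  data.frame(
    omega = x$omega,
    strength = x$strengths[grid$si],
    half_length = x$half_lengths[grid$li],
    input_length = vapply(seq_len(nrow(grid)), function(r)
      x$states[[grid$si[r], grid$li[r]]]$forcing$input_length %||% NA_integer_, 0L),
    response_modulus = vapply(seq_len(nrow(grid)), function(r)
      Mod(x$states[[grid$si[r], grid$li[r]]]$amplitude[x$center + 1L]), 0),
    iterations = x$iterations[as.matrix(grid)],
    converged = x$converged[as.matrix(grid)],
    stable = x$stable[as.matrix(grid)])
}
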