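#' Verify stability of a forced limit cycle
#'
#' The experiments must use the time-asymptotic *stable* limit cycle, so
#' every converged harmonic-balance solution can be certified before use.
#' Two routes are provided:
#'
#' * `method = "integrate"` (the defining check): perturb \eqn{Z} by a
#'   deterministic complex vector of relative size `rel_perturbation`,
#'   integrate the rotating-frame dynamics forward, and declare the state
#'   stable iff the trajectory returns to within `return_tol` (max
#'   componentwise distance) of \eqn{Z} before `max_time`.  A state that is
#'   not actually a fixed point of the rotating frame (for example a
#'   corrupted amplitude passed in by mistake) is never certified, because
#'   the flow leaves it.
#' * `method = "eigen"`: linearized check, stable iff every eigenvalue of
#'   the realified Jacobian [hb_jacobian()] at \eqn{Z} has negative real
#'   part.  Used by the experiment drivers, where integrating every grid
#'   cell would dominate the runtime; at a hyperbolic fixed point the two
#'   routes agree.
#'
#' @param state a converged `steady_state`.
#' @inheritParams hb_residual
#' @param method `"integrate"` or `"eigen"`.
#' @param rel_perturbation relative perturbation size (default `1e-3`).
#' @param return_tol certification radius (default `1e-6`).
#' @param max_time integration horizon; `NULL` chooses
#'   \eqn{\approx 3\log(\mathrm{perturbation}/\mathrm{tol})} e-foldings of
#'   the slowest linearized rate, capped at 2000.
#' @return `TRUE` or `FALSE`.
#' @export
verify_stability <- function(state, connectivity, forcing,
                             method = c("integrate", "eigen"),
                             rel_perturbation = 1e-3, return_tol = 1e-6,
                             max_time = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(state, "steady_state"))
  if (!isTRUE(state$converged))
    critnet_stop("critnet_invalid_argument", "`state` must be a converged steady state")
  A <- as_conn_matrix(connectivity)
  n <- nrow(A)
  z <- state$amplitude
  ev <- eigen(hb_jacobian(z, A, state$omega), only.values = TRUE)$values
  if (method == "eigen") return(max(Re(ev)) < 1e-8)

  f <- as_forcing_vector(forcing, n)
  scale <- max(Mod(z), 1e-12)
  w <- complex(modulus = 1, argument = 2 * pi * (0:(n - 1)) / n + 0.5) / sqrt(n)
  y0 <- z + rel_perturbation * scale * w
  if (is.null(max_time)) {
    slowest <- max(min(-Re(ev)), 1e-4)   # if linearly unstable, keep horizon short
    max_time <- min(2000, 3 * log(rel_perturbation * scale / return_tol + 2) / slowest + 10)
  }
  res <- integrate_rotating_frame(connectivity, state$omega, f, initial_state = y0,
                                  max_time = max_time, n_samples = 400,
                                  keep_states = TRUE)
  dist <- apply(res$states, 1, function(y) max(Mod(y - z)))
  any(dist < return_tol)
}

#' Resonance profile of a single critical oscillator
#'
#' Sweeps the driving frequency of a single critically poised oscillator
#' (\eqn{N = 1}, eigenfrequency 0) at fixed strength \eqn{B} and records the
#' steady response modulus at each frequency.  At resonance the response is
#' \eqn{B^{1/3}} (cubic-root compression); the half-width \eqn{\Gamma}, the
#' frequency span over which the response stays above half its maximum,
#' grows as \eqn{B^{2/3}} -- the frequency-domain face of the decay-constant
#' scaling measured in the time domain by [decay_scaling_experiment()].
#'
#' @param strength forcing strength \eqn{B > 0}.
#' @param frequency_grid frequencies at which to solve; must bracket the
#'   half-maximum crossings on both sides of resonance.
#' @param tolerance,max_iterations passed to [newton_solve()].
#' @return An object of class `resonance_profile`: `strength`,
#'   `frequency_grid`, `responses`, `halfwidth` (interpolated).
#' @export
resonance_profile <- function(strength, frequency_grid, tolerance = 1e-10,
                              max_iterations = 100L) {
  B <- check_positive(strength, "strength")
  om <- sort(as.numeric(frequency_grid))
  if (length(om) < 5)
    critnet_stop("critnet_invalid_argument", "frequency grid too small")
  conn <- line_connectivity(1)
  resp <- vapply(om, function(w)
    Mod(newton_solve(conn, w, B + 0i, tolerance = tolerance,
                     max_iterations = max_iterations)$amplitude), 0)
  half <- max(resp) / 2
  imax <- which.max(resp)
  cross <- function(idx) {      # interpolate the half-max crossing on one flank
    above <- resp[idx] >= half
    j <- which(diff(above) != 0)
    if (length(j) == 0) return(NA_real_)
    j <- j[1]
    i1 <- idx[j]; i2 <- idx[j + 1]
    om[i1] + (half - resp[i1]) * (om[i2] - om[i1]) / (resp[i2] - resp[i1])
  }
  lo <- cross(imax:1)
  hi <- cross(imax:length(om))
  if (!is.finite(lo) || !is.finite(hi))
    critnet_stop("critnet_halfwidth_undefined",
                 "frequency grid does not bracket the half-maximum response")
  structure(list(strength = B, frequency_grid = om, responses = resp,
                 halfwidth = abs(hi - lo)),
            class = "resonance_profile")
}

#' @export
print.resonance_profile <- function(x, ...) {
  cat(sprintf("<resonance_profile: B = %g, peak |Z| = %.6g, halfwidth = %.6g>\n",
              x$strength, max(x$responses), x$halfwidth))
  invisible(x)
}

#' @export
as.data.frame.resonance_profile <- function(x, ...) {
  data.frame(strength = x$strength, omega = x$frequency_grid,
             response_modulus = x$responses)
}
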