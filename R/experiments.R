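#' Length-tuning experiment: response versus input length per strength
#'
#' For each input strength \eqn{B} (a linear proxy for stimulus contrast),
#' sweeps the eigenvector-patterned forcing window from a single neuron up
#' to the whole network and records the steady response modulus
#' \eqn{|Z_c|} of the centre neuron, using the warm-started continuation
#' solver so every point lies on the weak-forcing branch.  The resulting
#' curves reproduce the contrast-dependent spatial summation phenomenology:
#' at weak strength the response rises monotonically with input length
#' (integration over the entire network), while at strong input the curve
#' peaks early and is suppressed beyond the peak, with the peak length
#' shrinking as strength grows.
#'
#' @inheritParams continuation_sweep
#' @param center 0-based centre neuron; default `floor(N/2)`.
#' @param max_half_length largest window half-length; default large enough
#'   to cover the whole network from `center`.
#' @return An object of class `length_response_set`: list of
#'   `length_response` curves (one per strength, each with `input_lengths`,
#'   `responses`, `peak_length`, `suppression_index`, convergence and
#'   stability flags) plus the underlying `steady_state_grid`.
#' @export
length_response_experiment <- function(connectivity, mode, center = NULL,
                                       strengths, max_half_length = NULL,
                                       tolerance = 1e-10, max_iterations = 100L,
                                       verify = TRUE, stability_method = "eigen") {
  stopifnot(inherits(mode, "eigen_mode"))
  n <- mode$n_neurons
  c0 <- check_index(center %||% (n %/% 2), n, "center")
  max_hl <- max_half_length %||% max(c0, n - 1 - c0)
  strengths <- sort(as.numeric(strengths))
  grid <- continuation_sweep(connectivity, mode, c0, strengths, 0:max_hl,
                             tolerance = tolerance, max_iterations = max_iterations,
                             verify = verify, stability_method = stability_method)
  curves <- lapply(seq_along(strengths), function(si)
    curve_from_grid(grid, si))
  structure(list(curves = curves, grid = grid, omega = mode$omega,
                 mode_rank = mode$mode_rank, center = c0,
                 strengths = strengths),
            class = "length_response_set")
}

curve_from_grid <- function(grid, si) {
  states <- grid$states[si, ]
  resp <- vapply(states, function(st) Mod(st$amplitude[grid$center + 1L]), 0)
  len <- vapply(states, function(st) st$forcing$input_length %||% NA_integer_, 0L)
  peak <- len[which.max(resp)]
  supp <- suppression_index(resp)
  structure(list(omega = grid$omega, strength = grid$strengths[si],
                 center = grid$center, input_lengths = len, responses = resp,
                 peak_length = peak, suppression_index = supp,
                 converged = grid$converged[si, ], stable = grid$stable[si, ]),
            class = "length_response")
}

# drop from the maximum response to the response at the longest input,
# relative to the maximum; 0 for monotonically rising curves
suppression_index <- function(responses) {
  m <- max(responses)
  if (m <= 0) return(0)
  max(0, (m - responses[length(responses)]) / m)
}

#' Surround suppression versus readout position
#'
#' Runs a fixed-strength length sweep for several centre neurons and relates
#' each neuron's suppression index to its position within the driving
#' eigenvector: neurons close to zeros of \eqn{|v|} are strongly suppressed
#' at long input lengths, neurons at antinodes barely at all.
#'
#' @inheritParams length_response_experiment
#' @param centers vector of 0-based centre neurons.
#' @param strength single forcing strength (use a strong drive to make
#'   suppression visible).
#' @return An object of class `suppression_map`: data frame `table`
#'   (`center`, `suppression_index`, `eigenvector_modulus`,
#'   `nearest_zero_distance`, `peak_length`, `all_converged`), the
#'   eigenvector modulus profile, zero positions, and the per-centre
#'   curves.
#' @export
suppression_vs_position <- function(connectivity, mode, centers, strength,
                                    max_half_length = NULL, tolerance = 1e-10,
                                    max_iterations = 100L, verify = TRUE,
                                    stability_method = "eigen") {
  stopifnot(inherits(mode, "eigen_mode"))
  n <- mode$n_neurons
  centers <- vapply(centers, check_index, 0L, n = n, name = "centers")
  ex <- mode_extrema(mode)
  curves <- lapply(centers, function(c0) {
    max_hl <- max_half_length %||% max(c0, n - 1 - c0)
    grid <- continuation_sweep(connectivity, mode, c0, strength, 0:max_hl,
                               tolerance = tolerance, max_iterations = max_iterations,
                               verify = verify, stability_method = stability_method)
    curve_from_grid(grid, 1L)
  })
  vmod <- Mod(mode$eigenvector)
  tab <- data.frame(
    center = centers,
    suppression_index = vapply(curves, function(cv) cv$suppression_index, 0),
    eigenvector_modulus = vmod[centers + 1L],
    nearest_zero_distance = vapply(centers, function(c0)
      min(abs(c0 - ex$zeros)), 0),
    peak_length = vapply(curves, function(cv) cv$peak_length, 0),
    all_converged = vapply(curves, function(cv) all(cv$converged), TRUE))
  structure(list(table = tab, omega = mode$omega, strength = strength,
                 eigenvector_modulus = vmod, zeros = ex$zeros,
                 antinodes = ex$antinodes, curves = curves),
            class = "suppression_map")
}

#' Decay-constant scaling experiment (response latency versus strength)
#'
#' For each input strength, solves the steady limit cycle, integrates the
#' stimulus-onset transient from rest in the rotating frame, fits the
#' exponential decay regimes of the readout residual with
#' [fit_decay_segments()], and finally regresses \eqn{\log b} on
#' \eqn{\log B} separately for the fast and slow regimes.  For a critically
#' poised system both regimes scale as \eqn{b \propto B^{2/3}}: stronger
#' input drives faster relaxation, i.e. shorter response latencies.
#'
#' @inheritParams length_response_experiment
#' @param half_length forcing window half-length \eqn{l} (input covers
#'   \eqn{2l+1} neurons).
#' @param min_segment_points,slope_ratio,envelope,tail_margin passed to
#'   [fit_decay_segments()].
#' @param n_samples samples per transient trace.
#' @param horizon_e_folds integration horizon in e-foldings of the slowest
#'   linearized decay rate at the solution (the rate is read off the
#'   realified Jacobian spectrum, so the horizon adapts to the strength).
#' @param rtol,atol integrator tolerances.
#' @return An object of class `decay_scaling`: `table` (one row per fitted
#'   segment: `strength`, `regime`, `decay_constant`, `goodness`,
#'   `t_start`, `t_end`), `power_laws` (list of `power_law_fit` for the
#'   fast and, when present, slow regimes), per-strength `fits` and
#'   `states`, and `excluded` strengths (no valid segment).
#' @export
decay_scaling_experiment <- function(connectivity, mode, center = NULL,
                                     strengths, half_length,
                                     min_segment_points = 12L, slope_ratio = 1.5,
                                     envelope = TRUE, tail_margin = 1.5,
                                     n_samples = 4000, horizon_e_folds = 28,
                                     tolerance = 1e-10, max_iterations = 100L,
                                     rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(mode, "eigen_mode"))
  n <- mode$n_neurons
  c0 <- check_index(center %||% (n %/% 2), n, "center")
  strengths <- sort(as.numeric(strengths))
  A <- as_conn_matrix(connectivity)

  fits <- vector("list", length(strengths))
  states <- vector("list", length(strengths))
  rows <- list()
  excluded <- numeric(0)
  prev <- NULL; prev_B <- NA_real_
  for (i in seq_along(strengths)) {
    B <- strengths[i]
    f <- forcing_pattern(mode, c0, half_length, B)
    guess <- if (!is.null(prev)) prev * (B / prev_B)^(1 / 3) else NULL
    st <- newton_solve(connectivity, mode$omega, f, initial_guess = guess,
                       tolerance = tolerance, max_iterations = max_iterations)
    if (!st$converged) { excluded <- c(excluded, B); next }
    prev <- st$amplitude; prev_B <- B
    ev <- eigen(hb_jacobian(st$amplitude, A, mode$omega), only.values = TRUE)$values
    rates <- -Re(ev)
    st$stable <- min(rates) > -1e-8
    states[[i]] <- st
    t_max <- horizon_e_folds / max(min(rates[rates > 0]), 1e-6)
    tr <- integrate_rotating_frame(connectivity, mode$omega, f,
                                   max_time = t_max, steady_state = st,
                                   rtol = rtol, atol = atol, n_samples = n_samples)
    fit <- tryCatch(
      fit_decay_segments(tr, st, neuron = c0,
                         min_segment_points = min_segment_points,
                         slope_ratio = slope_ratio, envelope = envelope,
                         tail_margin = tail_margin),
      critnet_fit_undetermined = function(e) NULL)
    if (is.null(fit)) { excluded <- c(excluded, B); next }
    fits[[i]] <- fit
    sg <- fit$segments
    rows[[length(rows) + 1]] <- data.frame(
      strength = B, regime = sg$label, decay_constant = -sg$slope,
      goodness = sg$goodness, t_start = sg$t_start, t_end = sg$t_end,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    critnet_stop("critnet_fit_undetermined", "no strength produced a valid decay fit")
  tab <- do.call(rbind, rows)
  power_laws <- lapply(split(tab, tab$regime), function(d) {
    if (nrow(d) < 3) return(NULL)
    fit <- ols_line(log(d$strength), log(d$decay_constant))
    structure(list(regime = d$regime[1], strengths = d$strength,
                   decay_constants = d$decay_constant, slope = fit$slope,
                   intercept = fit$intercept, goodness = fit$r2),
              class = "power_law_fit")
  })
  power_laws <- power_laws[!vapply(power_laws, is.null, TRUE)]
  if (length(excluded))
    warning(sprintf("strengths with no valid decay segment: %s",
                    paste(signif(excluded, 4), collapse = ", ")))
  structure(list(table = tab, power_laws = power_laws, fits = fits,
                 states = states, excluded = excluded, omega = mode$omega,
                 center = c0, half_length = half_length),
            class = "decay_scaling")
}

#' Orientation-space surround suppression on a ring
#'
#' Builds two critically balanced ring networks -- with and without
#' long-range couplings -- and runs matched length-tuning experiments on
#' both, the input arc length in neurons playing the role of extent in
#' orientation space.  The plain alternating ring has uniform-modulus
#' (travelling-wave) eigenvectors and shows no surround suppression; adding
#' long-range connections reshapes the eigenvectors (introducing modulus
#' zeros), and suppression beyond the response peak appears.
#'
#' @param n_neurons,coupling_strength,long_range ring parameters as in
#'   [ring_connectivity()]; `long_range` applies only to the augmented
#'   network.
#' @param mode_rank rank of the driving mode in each network's own
#'   spectrum (matched comparison); or give `target_omega`.
#' @param target_omega alternatively, pick the mode closest to this
#'   eigenfrequency.
#' @param center 0-based centre neuron; `NULL` (default) places the readout
#'   at the minimum of the long-range mode's eigenvector modulus, where
#'   surround suppression is strongest (for the plain ring the eigenvector
#'   modulus is uniform and the centre is immaterial; the same centre is
#'   used for a matched comparison).
#' @param strengths forcing strengths.
#' @param max_half_length largest half-length; default `floor(N/2)` (full
#'   ring coverage).
#' @param ... passed to [length_response_experiment()].
#' @return An object of class `orientation_ring_experiment`: experiments
#'   `with_long_range` and `without_long_range`, and a `suppression` data
#'   frame comparing suppression indices per strength.
#' @export
orientation_ring_experiment <- function(n_neurons, coupling_strength = 1,
                                        long_range = list(c(2, 1)),
                                        mode_rank = 2L, target_omega = NULL,
                                        center = NULL, strengths,
                                        max_half_length = NULL, ...) {
  ring_lr <- ring_connectivity(n_neurons, coupling_strength, long_range)
  ring_nn <- ring_connectivity(n_neurons, coupling_strength)
  max_hl <- max_half_length %||% (n_neurons %/% 2)
  pick <- function(conn) {
    sp <- eigenmodes(conn)
    if (!is.null(target_omega)) get_mode(sp, omega = target_omega)
    else get_mode(sp, rank = mode_rank)
  }
  mode_lr <- pick(ring_lr)
  if (is.null(center))
    center <- which.min(Mod(mode_lr$eigenvector)) - 1L
  run <- function(conn, mode) length_response_experiment(
    conn, mode, center = center, strengths = strengths,
    max_half_length = max_hl, ...)
  ex_lr <- run(ring_lr, mode_lr)
  ex_nn <- run(ring_nn, pick(ring_nn))
  supp <- data.frame(
    strength = ex_lr$strengths,
    with_long_range = vapply(ex_lr$curves, function(cv) cv$suppression_index, 0),
    without_long_range = vapply(ex_nn$curves, function(cv) cv$suppression_index, 0))
  structure(list(with_long_range = ex_lr, without_long_range = ex_nn,
                 suppression = supp, n_neurons = n_neurons,
                 center = center, long_range = ring_lr$long_range),
            class = "orientation_ring_experiment")
}

#' @export
print.length_response_set <- function(x, ...) {
  cat(sprintf("<length_response_set: omega = %.6g (rank %d), center %d, %d strengths, %d lengths>\n",
              x$omega, x$mode_rank, x$center, length(x$strengths),
              length(x$curves[[1]]$input_lengths)))
  for (cv in x$curves)
    cat(sprintf("  B = %-10g peak length %3d  suppression %.3f  %s\n",
                cv$strength, cv$peak_length, cv$suppression_index,
                if (all(cv$converged)) "all converged" else "HAS FAILED CELLS"))
  invisible(x)
}

#' @export
as.data.frame.length_response_set <- function(x, ...) as.data.frame(x$grid)

#' @export
plot.length_response_set <- function(x, log = "y", ...) {
  resp <- vapply(x$curves, function(cv) cv$responses, numeric(length(x$curves[[1]]$responses)))
  graphics::matplot(x$curves[[1]]$input_lengths, resp, type = "l", lty = 1,
                    xlab = "input length (neurons)", ylab = expression("|" * Z[c] * "|"),
                    log = log, main = sprintf("omega = %.3f", x$omega), ...)
  invisible(x)
}

#' @export
print.suppression_map <- function(x, ...) {
  cat(sprintf("<suppression_map: omega = %.6g, B = %g>\n", x$omega, x$strength))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.suppression_map <- function(x, ...) x$table

#' @export
plot.suppression_map <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$eigenvector_modulus) - 1, x$eigenvector_modulus,
                 type = "l", xlab = "", ylab = "|v|")
  graphics::points(x$table$center, x$eigenvector_modulus[x$table$center + 1])
  graphics::plot(x$table$center, x$table$suppression_index, xlab = "center neuron",
                 ylab = "suppression index", ...)
  invisible(x)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit (%s regime): b ~ B^%.4f, R^2 = %.4f, %d strengths>\n",
              x$regime, x$slope, x$goodness, length(x$strengths)))
  invisible(x)
}

#' @export
print.decay_scaling <- function(x, ...) {
  cat(sprintf("<decay_scaling: omega = %.6g, %d strengths, input length %d>\n",
              x$omega, length(unique(x$table$strength)), 2 * x$half_length + 1))
  for (pl in x$power_laws) print(pl)
  invisible(x)
}

#' @export
as.data.frame.decay_scaling <- function(x, ...) x$table

#' @export
print.orientation_ring_experiment <- function(x, ...) {
  cat(sprintf("<orientation_ring_experiment: N = %d, %d long-range coupling(s)>\n",
              x$n_neurons, length(x$long_range)))
  print(x$suppression, row.names = FALSE)
  invisible(x)
}
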