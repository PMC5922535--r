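#' Fit exponential decay regimes of the approach to the limit cycle
#'
#' During the transient approach to a forced limit cycle the readout
#' residual \eqn{r(t) = \bigl||x_i(t)| - |Z_i|\bigr|} decays exponentially,
#' possibly over two distinct regimes (a fast decay guiding the early
#' dynamics and a slow decay immediately preceding the limit cycle, the
#' latter emerging at strong input).  This fitter works on \eqn{\log r(t)}:
#' residuals at or below the numerical `floor` are discarded, a single line
#' and an exhaustively searched one-changepoint piecewise-linear model are
#' both fit, and the two-segment model is accepted only when it beats the
#' single line, both slopes are negative, the slope magnitudes differ by at
#' least `slope_ratio`, and each segment keeps at least
#' `min_segment_points` samples.
#'
#' Network transients approach the limit cycle through a mixture of
#' linearized modes, so \eqn{\log r(t)} carries beating oscillations with
#' sharp downward spikes wherever \eqn{|x_i(t)|} crosses \eqn{|Z_i|}.  With
#' `envelope = TRUE` (the default) the segments are therefore fit on the
#' upper envelope of \eqn{\log r(t)} -- the samples not exceeded by any
#' later sample within a short look-ahead window -- which tracks the decay
#' amplitude through the interference nulls.  The fit is also truncated
#' once the envelope first comes within `tail_margin` (natural-log units)
#' of its eventual minimum, removing the flat tail of integrator noise that
#' appears when a trace is followed beyond the numerically resolvable
#' residual.
#'
#' When two segments are accepted and the residual is a sum of
#' exponentials, a straight line through the early samples blends the two
#' rates near the changepoint.  With `peel = TRUE` the early slope is
#' therefore refined by curve peeling (classical multi-exponential
#' stripping): the fitted late component is extrapolated and subtracted,
#' and the early rate is refit on the positive remainder.  The refinement
#' is skipped automatically when the subtraction leaves too few usable
#' points (for example when the late segment is the faster one, as in an
#' onset transient from rest).
#'
#' @param trace a [transient_trace][integrate_rotating_frame].
#' @param steady_state the limit-cycle reference: a converged
#'   `steady_state` or a numeric vector of steady moduli \eqn{|Z_i|}.
#' @param neuron 0-based readout neuron; defaults to the trace's readout
#'   (the forcing centre).
#' @param min_segment_points minimum samples per fitted segment.
#' @param floor numerical floor on \eqn{r(t)}; default
#'   `max(1e-10, 1e-8 * max(|Z|))`.
#' @param slope_ratio minimum ratio of slope magnitudes for accepting two
#'   regimes.
#' @param envelope fit on the upper envelope of \eqn{\log r(t)} (see
#'   Details); disable for clean monotone traces.
#' @param tail_margin stop fitting once the envelope is within this many
#'   natural-log units of its eventual minimum.
#' @param peel refine the early slope of a two-segment fit by subtracting
#'   the extrapolated late component (see Details).
#' @return An object of class `decay_fit`: `segments` (data frame with
#'   `label`, `t_start`, `t_end`, `slope`, `intercept`, `goodness`,
#'   `n_points`), `n_segments`, `changepoint`, `floor`, `floor_time`,
#'   `neuron`.  Labels assign `"fast"` to the larger slope magnitude.
#' @export
fit_decay_segments <- function(trace, steady_state, neuron = NULL,
                               min_segment_points = 10L, floor = NULL,
                               slope_ratio = 1.5, envelope = TRUE,
                               tail_margin = 1.5, peel = TRUE) {
  stopifnot(inherits(trace, "transient_trace"))
  zmod <- Mod(if (inherits(steady_state, "steady_state")) steady_state$amplitude
              else steady_state)
  j <- check_index(neuron %||% trace$neuron_index, ncol(trace$moduli), "neuron") + 1L
  min_segment_points <- check_count(min_segment_points, "min_segment_points")

  r <- abs(trace$moduli[, j] - zmod[j])
  if (is.null(floor)) floor <- max(1e-10, 1e-8 * max(zmod))
  if (min(r) > 10 * floor)
    critnet_stop("critnet_fit_undetermined",
                 sprintf("trace never comes within 10x floor of the limit cycle (min residual %.3g, floor %.3g)",
                         min(r), floor))
  below <- r <= floor
  floor_time <- NA_real_
  last <- length(r)
  if (any(below)) {            # time after which the residual stays at floor
    run <- rev(cumprod(rev(below)))
    if (run[length(run)] == 1) {
      first_perm <- which(run == 1)[1]
      floor_time <- trace$times[first_perm]
      last <- first_perm
    }
  }
  keep <- which(r[seq_len(last)] > floor)
  t <- trace$times[keep]
  y <- log(r[keep])
  if (envelope && length(y) > 20) {
    env <- upper_envelope(y, w = max(3L, as.integer(round(length(y) / 200))))
    t <- t[env]; y <- y[env]
  }
  if (is.finite(tail_margin) && length(y) > 2) {
    cut <- which(y <= min(y) + tail_margin)[1]
    if (!is.na(cut) && cut >= 2) { t <- t[seq_len(cut)]; y <- y[seq_len(cut)] }
  }
  npt <- length(t)
  if (npt < min_segment_points)
    critnet_stop("critnet_fit_undetermined",
                 sprintf("only %d usable points above the floor (need >= %d)",
                         npt, min_segment_points))

  one <- ols_line(t, y)
  segs <- data.frame(label = "fast", t_start = t[1], t_end = t[npt],
                     slope = one$slope, intercept = one$intercept,
                     goodness = one$r2, n_points = npt,
                     stringsAsFactors = FALSE)
  changepoint <- NA_real_
  n_segments <- 1L

  if (npt >= 2 * min_segment_points) {
    cp <- changepoint_search(t, y, min_segment_points)
    if (!is.null(cp)) {
      s1 <- cp$left; s2 <- cp$right
      ratio <- max(abs(s1$slope), abs(s2$slope)) /
               max(min(abs(s1$slope), abs(s2$slope)), .Machine$double.eps)
      if (s1$slope < 0 && s2$slope < 0 && ratio >= slope_ratio &&
          cp$sse < one$sse * 0.99) {
        if (peel && abs(s2$slope) < abs(s1$slope)) {
          # strip the extrapolated slow tail from the early samples and
          # refit the fast rate on what remains above it
          idx <- seq_len(cp$m)
          rem <- exp(y[idx]) - exp(s2$intercept + s2$slope * t[idx])
          ok <- idx[rem > pmax(floor, 0.2 * exp(y[idx]))]
          if (length(ok) >= min_segment_points) {
            ref <- ols_line(t[ok], log(rem[ok]))
            if (ref$slope < 0 && abs(ref$slope) / abs(s2$slope) >= slope_ratio)
              s1 <- ref
          }
        }
        lab <- if (abs(s1$slope) >= abs(s2$slope)) c("fast", "slow") else c("slow", "fast")
        segs <- data.frame(label = lab,
                           t_start = c(t[1], t[cp$m + 1]),
                           t_end = c(t[cp$m], t[npt]),
                           slope = c(s1$slope, s2$slope),
                           intercept = c(s1$intercept, s2$intercept),
                           goodness = c(s1$r2, s2$r2),
                           n_points = c(cp$m, npt - cp$m),
                           stringsAsFactors = FALSE)
        changepoint <- (t[cp$m] + t[cp$m + 1]) / 2
        n_segments <- 2L
      }
    }
  }
  structure(list(segments = segs, n_segments = n_segments,
                 changepoint = changepoint, floor = floor,
                 floor_time = floor_time, neuron = j - 1L),
            class = "decay_fit")
}

# indices of samples not exceeded by any of the next w samples: the upper
# envelope of a decaying oscillatory log-residual (all points, if monotone)
upper_envelope <- function(y, w) {
  n <- length(y)
  keep <- logical(n)
  keep[n] <- TRUE
  for (i in seq_len(n - 1))
    keep[i] <- y[i] >= max(y[(i + 1):min(n, i + w)])
  which(keep)
}

ols_line <- function(t, y) {
  n <- length(t)
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  sxy <- sum((t - mt) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  sse <- max(syy - slope * sxy, 0)
  list(slope = slope, intercept = my - slope * mt,
       r2 = if (syy > 0) 1 - sse / syy else 1, sse = sse)
}

# exhaustive one-changepoint search in O(n) using running sums
changepoint_search <- function(t, y, min_pts) {
  n <- length(t)
  ct <- cumsum(t); cy <- cumsum(y)
  ctt <- cumsum(t^2); cyy <- cumsum(y^2); cty <- cumsum(t * y)
  seg_stats <- function(i, j) {         # closed range [i, j]
    k <- j - i + 1
    st <- ct[j] - if (i > 1) ct[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    stt <- ctt[j] - if (i > 1) ctt[i - 1] else 0
    syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
    sty <- cty[j] - if (i > 1) cty[i - 1] else 0
    sxx <- stt - st^2 / k
    sxy <- sty - st * sy / k
    syy0 <- syy - sy^2 / k
    slope <- sxy / sxx
    sse <- max(syy0 - slope * sxy, 0)
    list(slope = slope, intercept = (sy - slope * st) / k,
         r2 = if (syy0 > 0) 1 - sse / syy0 else 1, sse = sse)
  }
  best <- NULL
  for (m in min_pts:(n - min_pts)) {
    L <- seg_stats(1, m); R <- seg_stats(m + 1, n)
    tot <- L$sse + R$sse
    if (is.null(best) || tot < best$sse)
      best <- list(m = m, left = L, right = R, sse = tot)
  }
  best
}

#' Generate synthetic multi-exponential decay traces
#'
#' Reproducible fixture generator for exercising [fit_decay_segments()]
#' against known ground truth.  With `breakpoints = NULL` the residual is a
#' sum of exponentials \eqn{r(t) = \sum_m a_m e^{b_m t}}; with breakpoints
#' it is a continuous piecewise exponential, segment \eqn{m} decaying at
#' rate \eqn{b_m}.  Optional multiplicative log-normal noise is controlled
#' exactly by `seed` (the same seed reproduces the same trace; the global
#' RNG state is restored afterwards).
#'
#' @param slopes negative decay rates \eqn{b_m} (1/time).
#' @param amplitudes positive amplitudes \eqn{a_m}; for the piecewise form
#'   only `amplitudes[1]` is used (continuity fixes the rest).
#' @param times sampling grid (increasing, from 0).
#' @param breakpoints optional increasing changepoint times.
#' @param noise standard deviation of multiplicative log-normal noise.
#' @param seed RNG seed for the noise.
#' @param steady_modulus modulus of the underlying limit cycle; the trace
#'   stores `steady_modulus + r(t)`.
#' @return A `transient_trace` (single neuron) with the generating truth in
#'   `meta$truth`; fit it with
#'   `fit_decay_segments(trace, steady_state = steady_modulus)`.
#' @export
synthetic_trace <- function(slopes, amplitudes, times, breakpoints = NULL,
                            noise = 0, seed = NULL, steady_modulus = 1) {
  if (any(slopes >= 0))
    critnet_stop("critnet_invalid_argument", "`slopes` must all be negative")
  if (length(amplitudes) < 1 || any(amplitudes <= 0))
    critnet_stop("critnet_invalid_argument", "`amplitudes` must be positive")
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    critnet_stop("critnet_invalid_argument", "`times` must be strictly increasing")

  if (is.null(breakpoints)) {
    if (length(amplitudes) != length(slopes))
      critnet_stop("critnet_invalid_argument", "need one amplitude per slope")
    r <- rowSums(vapply(seq_along(slopes),
                        function(m) amplitudes[m] * exp(slopes[m] * times),
                        numeric(length(times))))
  } else {
    bp <- c(0, sort(breakpoints), Inf)
    if (length(slopes) != length(bp) - 1)
      critnet_stop("critnet_invalid_argument",
                   "need length(slopes) == length(breakpoints) + 1")
    a <- amplitudes[1]
    starts <- numeric(length(slopes)); starts[1] <- a
    for (m in seq_along(slopes)[-1])
      starts[m] <- starts[m - 1] * exp(slopes[m - 1] * (bp[m] - bp[m - 1]))
    seg <- findInterval(times, bp, rightmost.closed = FALSE)
    r <- starts[seg] * exp(slopes[seg] * (times - bp[seg]))
  }
  if (noise > 0)
    r <- r * exp(with_seed(seed, function() stats::rnorm(length(r), 0, noise)))

  structure(list(times = times, moduli = matrix(steady_modulus + r, ncol = 1),
                 states = NULL, final_state = steady_modulus + r[length(r)],
                 forcing_strength = NA_real_, neuron_index = 0L,
                 meta = list(frame = "synthetic", truth = list(
                   slopes = slopes, amplitudes = amplitudes,
                   breakpoints = breakpoints, noise = noise, seed = seed))),
            class = "transient_trace")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: %d segment(s), neuron %d>\n", x$n_segments, x$neuron))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.decay_fit <- function(x, ...) x$segments
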