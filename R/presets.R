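#' Named experiment presets
#'
#' Ready-made configurations for the package's standard analyses, at the
#' scales used throughout the documentation:
#'
#' * `"length_response"`: line network, N = 64, s = 1, centre neuron 32,
#'   strengths \eqn{B = 2^i} for \eqn{i = -10, \dots, 2} (weak to strong),
#'   driving modes of rank 1-6 (eigenfrequencies 2.00 down to 1.92).
#' * `"suppression_map"`: the N = 64 mode with eigenfrequency
#'   \eqn{\approx 1.92} at strong drive \eqn{B = 4}, with readout centres
#'   chosen programmatically at the zeros and antinodes of the eigenvector
#'   modulus (plus intermediate positions).
#' * `"decay_scan"`: line network, N = 32, near-full input length 29
#'   (half-length 14) centred at neuron 16, strengths \eqn{2^{-10}} to
#'   \eqn{2^2}.
#' * `"orientation_ring"`: ring of 32 neurons with a long-range coupling at
#'   offset 2, driven at mode rank 2, strengths \eqn{2^{-4}} to \eqn{2^2},
#'   readout at the minimum of the driving eigenvector modulus.
#'
#' @param name preset name.
#' @return A list of arguments for the corresponding experiment function
#'   (with `topology`/`n_neurons`/... fields as documented there).
#' @export
preset_config <- function(name = c("length_response", "suppression_map",
                                   "decay_scan", "orientation_ring")) {
  name <- match.arg(name)
  switch(name,
    length_response = list(
      topology = "line", n_neurons = 64L, coupling_strength = 1,
      center = 32L, mode_ranks = 1:6, strengths = 2^(-10:2),
      max_half_length = 32L),
    suppression_map = list(
      topology = "line", n_neurons = 64L, coupling_strength = 1,
      target_omega = 1.92, strength = 4, max_half_length = NULL),
    decay_scan = list(
      topology = "line", n_neurons = 32L, coupling_strength = 1,
      center = 16L, mode_rank = 1L, half_length = 14L,
      strengths = 2^(-10:2)),
    orientation_ring = list(
      topology = "ring", n_neurons = 32L, coupling_strength = 1,
      long_range = list(c(2, 1)), mode_rank = 2L, center = NULL,
      strengths = 2^(-4:2), max_half_length = 16L))
}

#' Run a preset experiment end to end
#'
#' Convenience driver used by the command-line interface: builds the
#' network, selects the driving mode(s) and runs the experiment named by
#' the preset, returning the experiment object(s).
#'
#' @param name preset name, see [preset_config()].
#' @param ... overrides merged over the preset fields.
#' @return The experiment object; for `"length_response"` a list of
#'   `length_response_set`, one per preset mode rank.
#' @export
run_preset <- function(name, ...) {
  p <- utils::modifyList(preset_config(name), list(...))
  conn <- if (identical(p$topology, "ring"))
    ring_connectivity(p$n_neurons, p$coupling_strength, p$long_range %||% list())
  else line_connectivity(p$n_neurons, p$coupling_strength)
  switch(name,
    length_response = {
      sp <- eigenmodes(conn)
      stats::setNames(
        lapply(p$mode_ranks, function(r)
          length_response_experiment(conn, get_mode(sp, rank = r),
                                     center = p$center, strengths = p$strengths,
                                     max_half_length = p$max_half_length)),
        sprintf("omega_%.4f", sp$omega[p$mode_ranks]))
    },
    suppression_map = {
      mode <- get_mode(eigenmodes(conn), omega = p$target_omega)
      centers <- p$centers %||% suppression_preset_centers(mode)
      suppression_vs_position(conn, mode, centers = centers,
                              strength = p$strength,
                              max_half_length = p$max_half_length)
    },
    decay_scan = {
      mode <- get_mode(eigenmodes(conn), rank = p$mode_rank)
      decay_scaling_experiment(conn, mode, center = p$center,
                               strengths = p$strengths,
                               half_length = p$half_length)
    },
    orientation_ring =
      orientation_ring_experiment(p$n_neurons, p$coupling_strength,
                                  long_range = p$long_range,
                                  mode_rank = p$mode_rank, center = p$center,
                                  strengths = p$strengths,
                                  max_half_length = p$max_half_length),
    critnet_stop("critnet_invalid_argument", sprintf("unknown preset `%s`", name)))
}

# readout centres at the interior eigenvector zeros and antinodes, plus the
# midpoints between them, away from the chain boundary
suppression_preset_centers <- function(mode, margin = 4L) {
  n <- mode$n_neurons
  ex <- mode_extrema(mode)
  cand <- sort(unique(c(ex$zeros, ex$antinodes,
                        round((ex$zeros[-length(ex$zeros)] + ex$zeros[-1]) / 4 +
                                ex$zeros[-length(ex$zeros)] / 2))))
  cand[cand >= margin & cand <= n - 1 - margin]
}
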