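#' Critically balanced line connectivity
#'
#' Builds the coupling matrix of a finite chain of alternating excitatory and
#' inhibitory neurons with equal-strength nearest-neighbour connections,
#' \deqn{A_{ij} = (-1)^j s\,(\delta_{i,j+1} + \delta_{i,j-1}),\qquad
#'       i, j = 0, \dots, N-1,}
#' with zero (Dirichlet) boundaries: activity is pinned to zero outside the
#' chain.  The alternating column sign makes \eqn{A} exactly skew-symmetric,
#' so its spectrum is purely imaginary and every eigenmode of the network sits
#' at the edge of instability (a full-dimensional centre manifold) -- the
#' "critically balanced" configuration.
#'
#' @param n_neurons number of neurons \eqn{N} (positive integer).
#' @param coupling_strength synaptic strength \eqn{s > 0} (dimensionless).
#' @return An object of class `connectivity`: a list with elements `entries`
#'   (the \eqn{N \times N} matrix), `n_neurons`, `coupling_strength`,
#'   `topology` and `long_range`.
#' @examples
#' line_connectivity(4)
#' as.matrix(line_connectivity(2))   # [[0, -1], [1, 0]]
#' @seealso [ring_connectivity()], [custom_connectivity()], [eigenmodes()]
#' @export
line_connectivity <- function(n_neurons, coupling_strength = 1) {
  n <- check_count(n_neurons, "n_neurons")
  s <- check_positive(coupling_strength, "coupling_strength")
  A <- matrix(0, n, n)
  if (n > 1) {
    j <- 0:(n - 2)                        # bond between neurons j and j+1
    A[cbind(j + 2, j + 1)] <- (-1)^j * s  # A[j+1, j] = (-1)^j s
    A[cbind(j + 1, j + 2)] <- (-1)^(j + 1) * s
  }
  new_connectivity(A, n, s, "line", list())
}

#' Critically balanced ring connectivity
#'
#' Builds a ring of alternating-sign nearest-neighbour couplings with periodic
#' boundary conditions, optionally augmented with skew long-range connections.
#' Rings model orientation space in V1: position on the ring is preferred
#' orientation rather than visuotopic position.
#'
#' For even `n_neurons` the nearest-neighbour signs follow the same
#' \eqn{(-1)^j} column convention as [line_connectivity()] and close
#' consistently around the ring.  For odd `n_neurons` a strictly alternating
#' pattern cannot close periodically; the builder then uses the documented
#' convention that every bond has magnitude `s` with the sign of the wrap bond
#' chosen to preserve skew-symmetry (only skew-symmetry, not the sign pattern,
#' is needed for a purely imaginary spectrum).
#'
#' @inheritParams line_connectivity
#' @param long_range list of long-range couplings, each a pair
#'   `c(offset, strength)` (or `list(offset =, strength =)`) with integer
#'   offset in `[2, floor(N/2)]`.  Each offset adds skew couplings between
#'   all neuron pairs `(i, i + offset mod N)`, with alternating sign
#'   \eqn{(-1)^i} on the source index.
#' @return A `connectivity` object with `topology = "ring"`.
#' @examples
#' ring_connectivity(6, 1, long_range = list(c(3, 0.5)))
#' @export
ring_connectivity <- function(n_neurons, coupling_strength = 1, long_range = list()) {
  n <- check_count(n_neurons, "n_neurons")
  if (n < 3)
    critnet_stop("critnet_invalid_argument", "a ring needs at least 3 neurons")
  s <- check_positive(coupling_strength, "coupling_strength")
  lr <- normalize_long_range(long_range, n)

  i <- 0:(n - 1)
  M <- matrix(0, n, n)
  M[cbind((i + 1) %% n + 1, i + 1)] <- (-1)^i * s
  for (b in lr) {
    d <- b$offset
    src <- if (2 * d == n) 0:(n / 2 - 1) else 0:(n - 1)
    idx <- cbind((src + d) %% n + 1, src + 1)
    M[idx] <- M[idx] + (-1)^src * b$strength
  }
  A <- M - t(M)   # skew by construction, row by row
  new_connectivity(A, n, s, "ring", lr)
}

normalize_long_range <- function(long_range, n) {
  if (is.null(long_range) || length(long_range) == 0) return(list())
  if (is.data.frame(long_range) || is.matrix(long_range))
    long_range <- lapply(seq_len(nrow(long_range)), function(r) as.list(long_range[r, ]))
  lapply(long_range, function(b) {
    if (!is.null(names(b)) && all(c("offset", "strength") %in% names(b)))
      b <- c(b[["offset"]], b[["strength"]])
    b <- unlist(b, use.names = FALSE)
    if (length(b) != 2 || !is.numeric(b))
      critnet_stop("critnet_invalid_argument",
                   "each long_range entry must be a (offset, strength) pair")
    d <- b[1]
    if (d %% 1 != 0 || d < 2 || d > floor(n / 2))
      critnet_stop("critnet_invalid_argument",
                   sprintf("long_range offset must be an integer in [2, %d]", floor(n / 2)))
    list(offset = as.integer(d), strength = as.numeric(b[2]))
  })
}

#' Wrap a user-supplied matrix as a connectivity object
#'
#' Accepts an arbitrary coupling matrix provided it is skew-symmetric within
#' `1e-12` (relative to its largest entry).  The model's criticality -- every
#' eigenvalue purely imaginary -- depends on exact balance, so dissipative
#' matrices are rejected rather than symmetrized.
#'
#' @param entries a square numeric matrix.
#' @return A `connectivity` object with `topology = "custom"`.
#' @export
custom_connectivity <- function(entries) {
  if (!is.matrix(entries) || !is.numeric(entries) || nrow(entries) != ncol(entries))
    critnet_stop("critnet_invalid_argument", "`entries` must be a square numeric matrix")
  dev <- max(abs(entries + t(entries)))
  if (dev > 1e-12 * max(1, max(abs(entries))))
    critnet_stop("critnet_invalid_argument",
                 sprintf("matrix is not skew-symmetric: max |A + t(A)| = %.3g", dev))
  A <- (entries - t(entries)) / 2   # remove roundoff asymmetry exactly
  new_connectivity(A, nrow(A), max(abs(A)), "custom", list())
}

new_connectivity <- function(entries, n, s, topology, long_range) {
  dimnames(entries) <- NULL
  structure(list(entries = entries, n_neurons = n, coupling_strength = s,
                 topology = topology, long_range = long_range),
            class = "connectivity")
}

as_conn_matrix <- function(connectivity) {
  if (inherits(connectivity, "connectivity")) return(connectivity$entries)
  if (is.matrix(connectivity)) return(custom_connectivity(connectivity)$entries)
  critnet_stop("critnet_invalid_argument",
               "`connectivity` must be a connectivity object or a square matrix")
}

#' @export
as.matrix.connectivity <- function(x, ...) x$entries

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity: %s, N = %d, s = %g>\n",
              x$topology, x$n_neurons, x$coupling_strength))
  if (length(x$long_range))
    cat("  long range:",
        paste(vapply(x$long_range,
                     function(b) sprintf("(offset %d, strength %g)", b$offset, b$strength),
                     ""), collapse = ", "), "\n")
  if (x$n_neurons <= 8) print(x$entries)
  invisible(x)
}

#' Export / import a connectivity matrix
#'
#' `write_connectivity()` writes the dense matrix as a plain CSV (no header)
#' plus a JSON sidecar `<path>.json` holding `n_neurons`, `coupling_strength`,
#' `topology` and `long_range`.  `read_connectivity()` reads the pair back;
#' without a sidecar the matrix is imported as a custom topology (and must be
#' skew-symmetric).
#'
#' @param connectivity a `connectivity` object.
#' @param path CSV file path.
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns a `connectivity` object.
#' @export
write_connectivity <- function(connectivity, path) {
  A <- as_conn_matrix(connectivity)
  utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(n_neurons = connectivity$n_neurons,
               coupling_strength = connectivity$coupling_strength,
               topology = connectivity$topology,
               long_range = lapply(connectivity$long_range, unclass))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  if (!file.exists(path))
    critnet_stop("critnet_io_error", sprintf("file not found: %s", path))
  A <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(A) <- NULL
  sidecar <- paste0(path, ".json")
  conn <- custom_connectivity(A)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    conn$topology <- meta$topology
    conn$coupling_strength <- meta$coupling_strength
    if (length(meta$long_range))
      conn$long_range <- normalize_long_range(meta$long_range, conn$n_neurons)
  }
  conn
}
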