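# Internal helpers: argument checking and structured error conditions.
# All user-visible errors carry a condition subclass so callers can
# distinguish invalid arguments from numerical failures programmatically.

critnet_stop <- function(subclass, msg, data = list()) {
  cond <- structure(c(list(message = msg, call = NULL), data),
                    class = c(subclass, "critnet_error", "error", "condition"))
  stop(cond)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x %% 1 != 0)
    critnet_stop("critnet_invalid_argument",
                 sprintf("`%s` must be a positive integer", name))
  as.integer(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    critnet_stop("critnet_invalid_argument",
                 sprintf("`%s` must be a %s real number", name,
                         if (strict) "positive" else "nonnegative"))
  as.numeric(x)
}

# neuron indices are 0-based throughout the package (they enter the
# alternating sign convention (-1)^j, which is only meaningful 0-based)
check_index <- function(x, n, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x %% 1 != 0 ||
      x < 0 || x > n - 1)
    critnet_stop("critnet_invalid_argument",
                 sprintf("`%s` must be a 0-based neuron index in [0, %d]", name, n - 1))
  as.integer(x)
}

# max-norm of the realified residual [Re g; Im g]
resid_maxnorm <- function(g) max(abs(c(Re(g), Im(g))))

# evaluate fn with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}
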