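# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the caller's
#' RNG state, so seeded generators do not disturb the session stream. A `NULL`
#' seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Wrap an angle difference (degrees) into [-180, 180).
wrap180 <- function(a) ((a + 180) %% 360) - 180

# Euclidean lengths of the segments of an ordered point matrix (n x d).
segment_lengths <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(numeric(0))
  d <- points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE]
  sqrt(rowSums(d^2))
}

# Total polyline length.
polyline_length <- function(points) sum(segment_lengths(points))

stop_config <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_config(msg)
  invisible(TRUE)
}
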