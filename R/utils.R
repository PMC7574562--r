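# Internal helpers shared across modules.

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. All user-facing stochastic functions route their
# sampling through this so that a given (input, seed) pair is reproducible
# while library calls never clobber the session RNG.
# RNG: R's default Mersenne-Twister ("Mersenne-Twister", "Inversion").
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic derived seed for sub-tasks (replicate r of stage s, ...).
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    # affine step in double precision; products stay < 2^53
    x <- (x * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(x)
}

# Membership of 0-based point positions in a set of 0-based half-open
# [start, end) intervals (possibly overlapping). Returns a logical vector.
points_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  if (any(ends <= starts)) stop("intervals must satisfy start < end", call. = FALSE)
  o <- order(starts, ends)
  s <- starts[o]
  e <- cummax(ends[o])
  # merge the union: a new merged interval starts where s exceeds the
  # running maximum end of everything before it
  new_run <- c(TRUE, s[-1] > e[-length(e)])
  run_id <- cumsum(new_run)
  ms <- s[new_run]
  me <- tapply(e, run_id, max)
  idx <- findInterval(pos, ms)
  inside <- idx >= 1L
  inside[inside] <- pos[inside] < me[idx[inside]]
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number in (0, 1)", name), call. = FALSE)
  }
}
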