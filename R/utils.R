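## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporarily fixed RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded helpers do not perturb surrounding randomness. `seed = NULL` runs
#' `code` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Replicates and per-catalog bootstraps each get an independent,
#' individually reproducible stream by hashing (master, index) into a
#' 31-bit seed with a multiplicative congruence.
#'
#' @param master Integer master seed.
#' @param index Non-negative stream index.
#' @return A positive integer seed `< 2^31`.
#' @export
spawn_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  x <- (as.numeric(master) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.numeric(index) * 1103515245 + 12345) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1)) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## assert a scalar count
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}
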