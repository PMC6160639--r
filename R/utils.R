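#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based mixing (Lehmer step per index) so that, e.g., adding a
#' participant to a cohort never reshuffles the streams of existing
#' participants. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (integer-like)
#' @param ... non-negative integer indices identifying the substream
#'   (e.g. cohort, participant, run)
#' @return an integer seed
#' @export
child_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- as.double(abs(as.integer(seed))) %% m
  for (k in as.double(c(...))) {
    x <- (x * 48271 + k + 1) %% m
  }
  as.integer(x + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# upper-triangle (no diagonal) of a square matrix, column-major order
upper_tri_vec <- function(m) m[upper.tri(m)]
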