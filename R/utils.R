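#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL uses the current stream (still deterministic if
# the caller seeded it).
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' @noRd
assert_numeric_vector <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  as.numeric(x)
}

# Root mean square.
#' @noRd
rms <- function(x) sqrt(mean(x^2))

# milliseconds <-> 1-based sample index at rate fs (Hz)
#' @noRd
ms_to_idx <- function(ms, fs) as.integer(round(ms * fs / 1000)) + 1L

#' @noRd
idx_to_ms <- function(idx, fs) (idx - 1) / fs * 1000
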