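`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  is.finite(x) & abs(x - round(x)) < tol
}

stop_umni <- function(...) stop(..., call. = FALSE)
warn_umni <- function(...) warning(..., call. = FALSE)
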