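# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulators never perturb the global stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one named stream per generator so two
# simulators called with the same top-level seed do not share draws.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(stream)) {
    s <- (s * 31 + ch) %% 2147483629
  }
  as.integer(s + 1)
}

# 3-vector coercion with validation
as_vec3 <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite 3-vector", name), call. = FALSE)
  }
  x
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x * x))

# full-precision numeric formatting for text writers (round-trips doubles)
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
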