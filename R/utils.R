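#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic generators in this package take an explicit `seed` argument
#' and leave the caller's global random state untouched. This helper seeds the
#' RNG, evaluates `expr`, and restores whatever `.Random.seed` was before.
#'
#' @param seed Integer seed, or `NULL` to use (and advance) the current state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Wrap phase angles to (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to the principal interval `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  atan2(sin(x), cos(x))
}

# stop() with call. = FALSE and sprintf-style formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
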