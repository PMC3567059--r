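#' @keywords internal
"_PACKAGE"

#' @importFrom stats dpois ppois dbinom runif rpois optimize pchisq lm coef
#'   ks.test var sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic functions take `seed = NULL`; a non-NULL seed makes
# the call fully reproducible without disturbing the session RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_probability <- function(p, name = "p") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_bad_arg("`", name, "` must be a single probability in [0, 1]")
  invisible(p)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop_bad_arg("`", name, "` must be a single integer >= ", min)
  as.integer(x)
}
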