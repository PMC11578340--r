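#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rlnorm rbinom pnorm pwilcox psignrank glm
#'   binomial glm.control coef predict p.adjust rank var sd quantile median
#'   kruskal.test pt setNames complete.cases
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a parent seed; kept well below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629L)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  }
  invisible(TRUE)
}
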