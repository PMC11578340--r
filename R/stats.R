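## Shared nonparametric statistics.
##
## Mann-Whitney and Wilcoxon signed-rank are implemented here rather than via
## stats::wilcox.test so that the exact-vs-approximate switching rule is the
## package's own documented contract (exact closed-form null distribution when
## samples are small and untied, tie-corrected normal approximation with
## continuity correction otherwise). Both are cross-checked against full
## enumeration oracles in the test suite.

#' Mann-Whitney U test (two-sided)
#'
#' Computes the U statistic for the first sample (number of pairs `(a_i, b_j)`
#' with `a_i > b_j`, ties counting 1/2) and a two-sided p-value. The exact
#' null distribution is used when `min(length(a), length(b)) <= exact_limit`
#' and there are no ties across the pooled sample; otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_limit use the exact distribution when the smaller sample has
#'   at most this many observations (and there are no ties).
#' @return list with elements `U`, `p`, `exact` (logical).
#' @export
mann_whitney_u <- function(a, b, exact_limit = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("mann_whitney_u: both groups must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && min(na, nb) <= exact_limit) {
    ## stats::pwilcox is the exact Mann-Whitney null CDF
    lo <- pwilcox(U, na, nb)
    hi <- 1 - pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(lo, hi))
    return(list(U = U, p = p, exact = TRUE))
  }
  n <- na + nb
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = U, p = 1, exact = FALSE))
  }
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p = min(1, 2 * pnorm(-z)), exact = FALSE)
}

#' Wilcoxon signed-rank test (two-sided, paired)
#'
#' Tests whether paired differences `x - y` (or the one-sample values `x` when
#' `y` is NULL) are symmetric about zero. Zero differences are dropped
#' (reported in `n_used`). Exact null distribution when `n_used <= exact_limit`
#' and the absolute differences are untied, tie-corrected normal approximation
#' with continuity correction otherwise. All-zero differences give p = 1.
#'
#' @param x,y numeric vectors (`y` optional; same length as `x` when given).
#' @param exact_limit exact-distribution cutoff on the number of non-zero
#'   differences.
#' @return list with `V` (sum of positive ranks), `p`, `n_used`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12L) {
  x <- as.numeric(x)
  d <- if (is.null(y)) x else {
    y <- as.numeric(y)
    if (length(x) != length(y)) {
      stop("wilcoxon_signed_rank: x and y must have equal length", call. = FALSE)
    }
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(V = 0, p = 1, n_used = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_limit) {
    lo <- psignrank(V, n)
    hi <- 1 - psignrank(V - 1, n)
    p <- min(1, 2 * min(lo, hi))
    return(list(V = V, p = p, n_used = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) {
    return(list(V = V, p = 1, n_used = n, exact = FALSE))
  }
  z <- max(0, (abs(V - mu) - 0.5) / sqrt(sigma2))
  list(V = V, p = min(1, 2 * pnorm(-z)), n_used = n, exact = FALSE)
}

#' Rank correlation between two vectors
#'
#' Spearman rank correlation on tie-corrected (mid-)ranks with a two-sided
#' p-value from the t approximation; Pearson available for completeness.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n != length(y)) stop("correlate: unequal lengths", call. = FALSE)
  if (n < 3L) stop("correlate: need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("correlate: undefined correlation for a constant vector", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  rho <- stats::cor(x, y)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Kruskal-Wallis rank-sum test across more than two groups
#'
#' Thin wrapper over [stats::kruskal.test()], kept in the shared statistics
#' layer for >2-group comparisons.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor/vector parallel to `values`.
#' @return list with `statistic`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- kruskal.test(values, as.factor(groups))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}
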