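#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test used throughout the package. For small groups (at most
#' `max_enum` distinct group-label assignments) the null distribution of U is
#' enumerated exactly over all assignments of the pooled observations to the
#' two groups, which remains exact under ties; the two-sided p-value is
#' `min(1, 2 * min(P(U' <= U), P(U' >= U)))`. For larger groups the normal
#' approximation with the standard tie correction is used (no continuity
#' correction).
#'
#' U counts, over all cross-group pairs, the pairs where the first group's
#' value exceeds the second's (ties count 1/2), i.e.
#' `U = R1 - n1(n1+1)/2` with `R1` the first group's rank sum.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) decides by `choose(n1+n2, n1) <= max_enum`.
#' @param max_enum enumeration budget.
#' @return list with `U`, `p`, and `exact` (logical).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL, max_enum = 1e5) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stop_if_not(n1 >= 1 && n2 >= 1, "both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- choose(n1 + n2, n1) <= max_enum
  if (exact) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + tol), mean(Us >= U - tol)))
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(U - mu) / sqrt(sigma2))
    p <- min(1, p)
  }
  list(U = U, p = p, exact = exact)
}
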