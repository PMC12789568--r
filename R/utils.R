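# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Dirichlet draws via normalized gammas; alpha is a vector.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Zero-truncated negative binomial draw (inverse-CDF on the conditional).
rztnbinom <- function(n, mu, size) {
  p0 <- dnbinom(0, mu = mu, size = size)
  u <- runif(n, min = p0, max = 1)
  qnbinom(u, mu = mu, size = size)
}

# Derive k independent substream seeds (< 2^31) from a root seed.
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

# Round half to even (base R round) or half up; integers only.
round_mode <- function(x, mode = c("half_even", "half_up")) {
  mode <- match.arg(mode)
  if (mode == "half_even") round(x) else floor(x + 0.5)
}

is_proportion <- function(x) is.numeric(x) && all(x >= 0 & x <= 1, na.rm = TRUE)

# expm1 on a sparse matrix without densifying.
sparse_expm1 <- function(x) {
  if (is(x, "sparseMatrix")) {
    x <- as(x, "CsparseMatrix")
    x@x <- expm1(x@x)
    x
  } else {
    expm1(x)
  }
}

row_vars_sparse <- function(x) {
  n <- ncol(x)
  m <- Matrix::rowMeans(x)
  m2 <- Matrix::rowMeans(x^2)
  (m2 - m^2) * n / (n - 1)
}
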