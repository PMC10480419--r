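#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes rho as the Pearson correlation of average-rank vectors, and a
#' two-sided p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. A constant input yields `rho = NA` with
#' `constant = TRUE` rather than an error, mirroring how undefined ranks are
#' treated throughout the package.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A one-row tibble: `rho`, `p`, `n`, `constant`.
#' @export
#' @examples
#' spearman(c(1, 2, 2, 3), c(1, 2, 3, 4))
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  constant <- var(x) == 0 || var(y) == 0
  if (constant) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n, constant = TRUE))
  }
  rho <- cor(rank(x), rank(y))
  tibble::tibble(rho = rho, p = spearman_pvalue(rho, n), n = n,
                 constant = FALSE)
}

# two-sided p from the t-approximation; rho = +/-1 maps to p = 0 (the
# denominator is clamped so rank-rounding cannot push it negative)
spearman_pvalue <- function(rho, n) {
  den <- pmax(1 - rho^2, 1e-300)
  p <- 2 * pt(-abs(rho) * sqrt((n - 2) / den), n - 2)
  p[is.na(rho)] <- NA_real_
  p
}

# column-wise average ranks; the workhorse behind every correlation op:
# rank once, then correlate ranks with a single Pearson matrix product
rank_columns <- function(values) {
  apply(values, 2, rank)
}
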