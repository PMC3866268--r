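#' Least-squares regression across clades
#'
#' Ordinary least squares of `y` on `x` (degree 1) or on `x` and `x^2`
#' (degree 2), as used for cross-clade comparisons of diversification rates,
#' felsens, overlap and spatial structure. Reports coefficients, r-squared
#' and the overall F-test p-value.
#'
#' @param x,y numeric vectors of equal length (`n >= degree + 2`).
#' @param degree 1 (linear, default) or 2 (quadratic polynomial).
#' @return object of class `clade_regression`: `coefficients`, `r_squared`,
#'   `p_value`, `n`, `degree`, and the underlying `lm` fit.
#' @export
ols <- function(x, y, degree = 1) {
  stopifnot(degree %in% 1:2, length(x) == length(y))
  if (length(x) < degree + 2) stop("need at least degree + 2 points")
  fit <- if (degree == 1) stats::lm(y ~ x) else
    stats::lm(y ~ x + I(x^2))
  s <- summary(fit)
  if (any(is.na(stats::coef(fit)))) stop("degenerate (collinear) design")
  p <- unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                        lower.tail = FALSE))
  structure(list(coefficients = stats::coef(fit),
                 r_squared = s$r.squared, p_value = p,
                 n = length(x), degree = degree, fit = fit),
            class = "clade_regression")
}

#' @export
print.clade_regression <- function(x, ...) {
  cat(sprintf("degree-%d OLS (n = %d): r^2 = %.3f, P = %.4g\n",
              x$degree, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' For combined sample sizes up to `exact_max` (default 12) the null
#' distribution of U is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the observed values (midranks
#' under ties, with the `exact` flag downgraded since ties make the
#' enumeration conditional on the tie pattern); larger samples use the
#' normal approximation with tie correction. One-sided p is taken in the
#' direction of the observed shift; two-sided doubles it (capped at 1).
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact_max largest `n1 + n2` for full enumeration.
#' @return object of class `mwu_test`: `U` (for group `a`), `U_min`,
#'   `p_one_sided`, `p_two_sided`, `exact`, `ties`, group sizes.
#' @export
mann_whitney_exact <- function(a, b, exact_max = 12) {
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both groups must be nonempty")
  r <- rank(c(a, b))              # midranks under ties
  U_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (n1 + n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(Us <= U_a)
    p_ge <- mean(Us >= U_a)
    exact <- !ties
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    sig <- sqrt(n1 * n2 / 12 *
                  (n1 + n2 + 1 - sum(tab^3 - tab) /
                     ((n1 + n2) * (n1 + n2 - 1))))
    # continuity-corrected normal tails
    p_le <- stats::pnorm((U_a + 0.5 - mu) / sig)
    p_ge <- stats::pnorm((U_a - 0.5 - mu) / sig, lower.tail = FALSE)
    exact <- FALSE
  }
  p_one <- min(p_le, p_ge)
  structure(list(U = unname(U_a), U_min = unname(min(U_a, n1 * n2 - U_a)),
                 n1 = n1, n2 = n2,
                 p_one_sided = p_one,
                 p_two_sided = min(1, 2 * p_one),
                 exact = exact, ties = ties),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf(paste0("Mann-Whitney U = %g (n1 = %d, n2 = %d, %s%s)\n",
                     "one-sided P = %.4g, two-sided P = %.4g\n"),
              x$U, x$n1, x$n2,
              if (x$exact) "exact" else "approximate",
              if (x$ties) ", ties" else "",
              x$p_one_sided, x$p_two_sided))
  invisible(x)
}
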