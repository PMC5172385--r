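#' Williams's t for two dependent overlapping correlations
#'
#' Tests whether two correlations that share one variable differ:
#' `r_ja` (variables j and a) against `r_ka` (variables k and a), with
#' `r_jk` the correlation between the two non-shared variables. Uses
#' Williams's modification of Hotelling's test with df = n - 3:
#'
#' \deqn{t = (r_{ja} - r_{ka}) \sqrt{\frac{(n-1)(1+r_{jk})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{jk})^3}}}
#'
#' where `|R|` is the determinant of the 3x3 correlation matrix and
#' `rbar = (r_ja + r_ka)/2`.
#'
#' @param r_ja,r_ka The two correlations sharing variable `a`.
#' @param r_jk Correlation between the non-shared variables.
#' @param n Sample size (> 3).
#' @return List of class `dediff_cor_cmp`: the inputs, `t`, `df` (n - 3)
#'   and the two-sided `p`.
#' @export
williams_t <- function(r_ja, r_ka, r_jk, n) {
  if (any(abs(c(r_ja, r_ka, r_jk)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  if (n <= 3) stop("n must exceed 3")
  detR <- 1 - r_ja^2 - r_ka^2 - r_jk^2 + 2 * r_ja * r_ka * r_jk
  rbar <- (r_ja + r_ka) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_jk)^3
  t <- (r_ja - r_ka) * sqrt((n - 1) * (1 + r_jk) / denom)
  df <- n - 3
  structure(list(r_ja = r_ja, r_ka = r_ka, r_jk = r_jk, n = n,
                 t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df)),
            class = "dediff_cor_cmp")
}

#' Smallest detectable bivariate effect
#'
#' The smallest standardized bivariate association (correlation) detectable
#' with the given power at a two-sided significance level, from the power
#' function of the correlation test. The default inverts the noncentral-t
#' power of the t test for a correlation; `"fisher-z"` uses the Fisher
#' z approximation.
#'
#' @param n Sample size (> 3).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param method `"exact"` (noncentral t, default) or `"fisher-z"`.
#' @param digits Decimal places for the reported value (default 3, the
#'   conventional reporting precision); `NULL` for full precision.
#' @return Detectable correlation magnitude.
#' @export
detectable_effect <- function(n, alpha = 0.05, power = 0.80,
                              method = c("exact", "fisher-z"), digits = 3) {
  method <- match.arg(method)
  if (n <= 3 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("need n > 3, alpha and power strictly inside (0, 1)")
  if (method == "fisher-z") {
    r <- tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
  } else {
    tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
    pow <- function(rho) {
      ncp <- rho * sqrt(n - 2) / sqrt(1 - rho^2)
      stats::pt(tcrit, n - 2, ncp, lower.tail = FALSE) +
        stats::pt(-tcrit, n - 2, ncp)
    }
    if (pow(0.999999) < power) stop("requested power infeasible at this n")
    r <- stats::uniroot(function(rho) pow(rho) - power,
                        c(1e-8, 0.999999), tol = 1e-10)$root
  }
  if (!is.null(digits)) round(r, digits) else r
}
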