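#' Age-moderated one-factor model (MNLFA)
#'
#' Extends the one-factor model so that age moderates the factor loadings
#' and the unique-factor loadings. For tract `t` and subject `n` with
#' centered age `a_n` the model is
#'
#' \deqn{y_{tn} = \nu_t + \alpha_{1t} age_n + \alpha_{2t} age_n^2 +
#'   \alpha_{3t} sex_n + \lambda_{1t}(1 + \lambda_1' a_n)\, g_n +
#'   \lambda_{2t}(1 + \lambda_2' a_n)\, u_{tn}}
#'
#' In `"invariant"` mode the two moderation slopes are shared across tracts
#' (moderation acts proportionally to each tract's loading); in
#' `"tract_specific"` mode each tract gets its own pair of slopes (44
#' parameters for 22 tracts). `"none"` fixes both at zero, which reproduces
#' [fit_one_factor()] exactly. Residual covariances carried over from the
#' base fit are not age-moderated. The age-squared mean term is included
#' for all measures except FA.
#'
#' The likelihood is evaluated on age-binned second moments of the
#' covariate-adjusted tracts (bin width `bin_width` years); the binning is
#' exact under no moderation and introduces error far below sampling noise
#' otherwise. Standard errors come from the observed information.
#'
#' @inheritParams fit_one_factor
#' @param mode `"invariant"`, `"tract_specific"` or `"none"`.
#' @param base_fit Optional `dediff_factor_fit` supplying starting values
#'   and residual-covariance pairs; fitted internally when omitted.
#' @param bin_width Age bin width in years (default 0.75).
#' @param compute_se Compute the observed-information covariance (needed
#'   for Wald tests and communality CIs; default `TRUE`).
#' @return Object of class `dediff_mod_fit` extending the base-fit fields
#'   with `mode`, `lambda1p`, `lambda2p` (scalars or per-tract vectors),
#'   their standard errors, the parameter covariance, and the observed age
#'   range.
#' @export
fit_moderated_factor <- function(table, subjects, measure,
                                 mode = c("invariant", "tract_specific", "none"),
                                 tracts = core_tracts(), base_fit = NULL,
                                 resid_pairs = NULL,
                                 covariates = NULL,
                                 age_center = 60, age_scale = 7.5,
                                 bin_width = 0.75, compute_se = TRUE,
                                 on_heywood = "error") {
  mode <- match.arg(mode)
  if (is.null(covariates))
    covariates <- c("age", if (measure != "FA") "age2", "sex")
  if (!is.null(base_fit)) {
    tracts <- base_fit$tracts
    if (is.null(resid_pairs)) resid_pairs <- base_fit$resid_pairs
    covariates <- base_fit$covariates
  }
  prep <- .fof_prepare(table, subjects, measure, tracts, covariates,
                       age_center, age_scale)
  pairs <- .fof_pair_idx(resid_pairs, tracts)
  p <- length(tracts)
  max_abs_a <- max(abs(prep$a_centered))
  spec <- .fe_spec(p, mode, pairs, max_abs_a = max_abs_a)
  bins <- .fe_bins(prep$E, prep$a_centered, width = bin_width,
                   center = age_center)

  start <- numeric(spec$npar)
  if (is.null(base_fit)) {
    start0 <- .fe_start(bins, .fe_spec(p, "none", pairs))
    start[spec$idx$l1] <- start0[seq_len(p)]
    start[spec$idx$l2] <- start0[p + seq_len(p)]
  } else {
    start[spec$idx$l1] <- base_fit$loadings
    start[spec$idx$l2] <- base_fit$uniquenesses
    if (!is.null(pairs) && !is.null(base_fit$resid_pairs))
      start[spec$idx$r] <- base_fit$resid_pairs$value
  }
  fit <- .fe_fit(bins, spec, start = start)
  .fe_check_heywood(fit, tracts, on_heywood)

  out <- .fof_result(fit, bins, tracts, measure, resid_pairs, prep,
                     compute_se = FALSE, covariates, age_center, age_scale)
  pars <- .fe_unpack(fit$par, spec)
  out$mode <- mode
  out$lambda1p <- if (spec$nmod == p) stats::setNames(pars$l1p, tracts) else pars$l1p
  out$lambda2p <- if (spec$nmod == p) stats::setNames(pars$l2p, tracts) else pars$l2p
  out$age_range_observed <- range(prep$a_centered) + age_center
  # unique SD must stay positive over the observed age span
  v_lo <- 1 + out$lambda2p * (out$age_range_observed[1] - age_center)
  v_hi <- 1 + out$lambda2p * (out$age_range_observed[2] - age_center)
  if (any(v_lo <= 0) || any(v_hi <= 0))
    stop("unique-loading moderation collapses within the observed age range",
         " for tract ", tracts[which(pmin(v_lo, v_hi) <= 0)[1]])
  if (compute_se) {
    V <- .fe_vcov(fit, bins)
    out$vcov <- V
    se <- sqrt(pmax(diag(V), 0))
    out$se_loadings <- stats::setNames(se[spec$idx$l1], tracts)
    out$se_uniquenesses <- stats::setNames(se[spec$idx$l2], tracts)
    if (spec$nmod > 0) {
      out$se_lambda1p <- se[spec$idx$l1p]
      out$se_lambda2p <- se[spec$idx$l2p]
      if (spec$nmod == p) {
        names(out$se_lambda1p) <- names(out$se_lambda2p) <- tracts
      }
    }
  }
  class(out) <- c("dediff_mod_fit", "dediff_factor_fit")
  out
}

#' @export
print.dediff_mod_fit <- function(x, ...) {
  cat("Age-moderated one-factor model:", x$measure,
      sprintf("(mode = %s, n = %d)\n", x$mode, x$n))
  if (x$mode == "invariant") {
    cat(sprintf("  loading moderation  lambda1' = %+.5f /yr", x$lambda1p))
    if (!is.null(x$se_lambda1p)) cat(sprintf(" (SE %.5f)", x$se_lambda1p))
    cat("\n")
    cat(sprintf("  uniqueness moderation lambda2' = %+.5f /yr", x$lambda2p))
    if (!is.null(x$se_lambda2p)) cat(sprintf(" (SE %.5f)", x$se_lambda2p))
    cat("\n")
  }
  cat("  -2 log-likelihood:", sprintf("%.1f", x$neg2ll),
      " AIC:", sprintf("%.1f", x$AIC), "\n")
  invisible(x)
}

#' Wald and likelihood-ratio tests of age moderation
#'
#' Per-parameter Wald z tests of the moderation slopes against zero, and
#' (optionally) a likelihood-ratio test of the whole moderated model against
#' the unmoderated fit.
#'
#' @param fit A `dediff_mod_fit` with standard errors.
#' @param table,subjects Pass the data to also compute the overall LR test
#'   against the unmoderated model; omit for Wald only.
#' @return List with `wald` (data frame: parameter, estimate, se, z, p) and,
#'   when data are supplied, `lr` (statistic, df, p).
#' @export
test_moderation_significance <- function(fit, table = NULL, subjects = NULL) {
  if (fit$mode == "none") stop("fit has no moderation parameters")
  if (is.null(fit$se_lambda1p))
    stop("fit was computed without standard errors; refit with compute_se = TRUE")
  lab1 <- if (length(fit$lambda1p) > 1) paste0("lambda1p[", names(fit$lambda1p), "]")
          else "lambda1p"
  lab2 <- if (length(fit$lambda2p) > 1) paste0("lambda2p[", names(fit$lambda2p), "]")
          else "lambda2p"
  est <- c(fit$lambda1p, fit$lambda2p)
  se <- c(fit$se_lambda1p, fit$se_lambda2p)
  z <- est / se
  wald <- data.frame(parameter = c(lab1, lab2), estimate = est, se = se,
                     z = z, p = 2 * stats::pnorm(-abs(z)),
                     row.names = NULL)
  out <- list(wald = wald)
  if (!is.null(table) && !is.null(subjects)) {
    base <- fit_moderated_factor(table, subjects, fit$measure, mode = "none",
                                 tracts = fit$tracts,
                                 resid_pairs = fit$resid_pairs,
                                 covariates = fit$covariates,
                                 age_center = fit$age_center,
                                 age_scale = fit$age_scale,
                                 compute_se = FALSE, on_heywood = "warn")
    stat <- max(base$neg2ll - fit$neg2ll, 0)
    df <- 2 * length(fit$lambda1p)
    out$lr <- data.frame(statistic = stat, df = df,
                         p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  out
}

# per-tract communality at centered age(s) a from moderated parameters
.mod_communality <- function(fit, a) {
  l1p <- fit$lambda1p %||% 0
  l2p <- fit$lambda2p %||% 0
  w2 <- (1 + outer(rep_len(l1p, length(fit$loadings)), a, `*`))^2
  v2 <- (1 + outer(rep_len(l2p, length(fit$loadings)), a, `*`))^2
  s <- fit$loadings^2 * w2
  u <- fit$uniquenesses^2 * v2
  h <- s / (s + u)
  rownames(h) <- fit$tracts
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
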