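#' Eigen spectrum of the tract correlation matrix
#'
#' Eigen-decomposition of the pairwise-complete correlation matrix of the
#' tract units for one measure, the exploratory precursor to the one-factor
#' models. A weak first factor (first-eigenvalue share below `weak_threshold`)
#' is flagged; such measures are not carried into factor-score analyses.
#'
#' @param table Tidy metric table.
#' @param measure Measure label.
#' @param tracts Tract units to use (default: the 22 core units).
#' @param weak_threshold First-factor share below which the factor is
#'   flagged weak (default 0.15).
#' @return List with `measure`, `eigenvalues` (descending), `first_share`
#'   and `weak_first_factor`.
#' @export
eigen_spectrum <- function(table, measure, tracts = core_tracts(),
                           weak_threshold = 0.15) {
  W <- metric_wide(table, measure, tracts)
  if (ncol(W) < 2) stop("need at least 2 tracts")
  R <- stats::cor(W, use = "pairwise.complete.obs")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("pairwise-complete correlation matrix not PSD; ",
            "eigenvalues clipped at zero for the share computation")
    ev <- pmax(ev, 0)
  }
  share <- ev[1] / sum(ev)
  list(measure = measure, eigenvalues = ev, first_share = share,
       weak_first_factor = share < weak_threshold)
}

#' One-factor confirmatory model for a measure
#'
#' Maximum-likelihood one-factor model of the tract units for one measure,
#' with each tract adjusted for the chosen covariates (standardized age,
#' age squared for all measures except FA, and sex), the latent factor
#' variance fixed to 1 for identification, and optional residual
#' covariances between listed tract pairs. Tracts are residualized on the
#' covariates by per-tract least squares (the exact ML mean structure for a
#' common covariance) and the covariance structure
#' `Sigma = lambda1 lambda1' + diag(lambda2^2) + R` is fitted to the
#' residual moment matrix by maximum likelihood.
#'
#' @param table Tidy metric table.
#' @param subjects Covariate data frame (columns `subject_id`, `age`, `sex`).
#' @param measure Measure label.
#' @param tracts Tract units to model (default: 22 core units).
#' @param resid_pairs `NULL`, or a data frame with columns `t1`, `t2` naming
#'   tract pairs given free residual covariances.
#' @param covariates Character subset of `c("age", "age2", "sex")`. The
#'   default adjusts for sex and age, adding age^2 for measures other than
#'   FA. Use `c("sex")` for the score-extraction model.
#' @param age_center,age_scale Age metric (years).
#' @param compute_se Compute observed-information standard errors.
#' @param on_heywood `"error"` (default), `"warn"` or `"ignore"` when a
#'   unique variance collapses to its bound.
#' @return An object of class `dediff_factor_fit`: loadings, unique SDs,
#'   standardized loadings, per-tract communality, variance explained,
#'   deviance and information criteria, chi-square against the saturated
#'   model, and the residualized data needed for factor scores.
#' @export
fit_one_factor <- function(table, subjects, measure, tracts = core_tracts(),
                           resid_pairs = NULL,
                           covariates = NULL,
                           age_center = 60, age_scale = 7.5,
                           compute_se = FALSE,
                           on_heywood = "error") {
  if (is.null(covariates))
    covariates <- c("age", if (measure != "FA") "age2", "sex")
  prep <- .fof_prepare(table, subjects, measure, tracts, covariates,
                       age_center, age_scale)
  if (nrow(prep$E) < 10 * (2 * length(tracts)))
    warning("sample size below 10 x parameter count; estimates may be unstable")
  pairs <- .fof_pair_idx(resid_pairs, tracts)
  spec <- .fe_spec(length(tracts), "none", pairs)
  bins <- .fe_bins(prep$E)
  fit <- .fe_fit(bins, spec)
  .fe_check_heywood(fit, tracts, on_heywood)
  .fof_result(fit, bins, tracts, measure, resid_pairs, prep, compute_se,
              covariates, age_center, age_scale)
}

# shared preparation: wide matrix, covariate design, residualization
.fof_prepare <- function(table, subjects, measure, tracts, covariates,
                         age_center, age_scale) {
  W <- metric_wide(table, measure, tracts)
  if (ncol(W) < 3) stop("need at least 3 tracts for a factor model")
  X <- .covariate_design(subjects, rownames(W), age_center, age_scale,
                         include_age2 = "age2" %in% covariates,
                         include_age = "age" %in% covariates)
  res <- .fe_residualize(W, X)
  ids <- rownames(W)[res$ok]
  i <- match(ids, subjects$subject_id)
  list(E = res$E, ids = ids, ok = res$ok,
       a_centered = subjects$age[i] - age_center,
       n_covariates = ncol(X))
}

.fof_pair_idx <- function(resid_pairs, tracts) {
  if (is.null(resid_pairs) || !nrow(resid_pairs)) return(NULL)
  j <- match(resid_pairs$t1, tracts)
  k <- match(resid_pairs$t2, tracts)
  if (anyNA(j) || anyNA(k))
    stop("residual-pair tract not among modelled tracts")
  data.frame(j = j, k = k)
}

.fof_result <- function(fit, bins, tracts, measure, resid_pairs, prep,
                        compute_se, covariates, age_center, age_scale) {
  p <- length(tracts)
  pars <- .fe_unpack(fit$par, fit$spec)
  Sigma <- .fe_sigma(pars, fit$spec, 0)
  dimnames(Sigma) <- list(tracts, tracts)
  std_load <- pars$l1 / sqrt(diag(Sigma))
  communality <- pars$l1^2 / (pars$l1^2 + pars$l2^2)
  names(pars$l1) <- names(pars$l2) <- names(std_load) <- names(communality) <- tracts
  S <- bins[[1]]$M
  if (length(bins) > 1L)
    S <- Reduce(`+`, lapply(bins, function(b) b$n * b$M)) / fit$n
  f_sat <- fit$n * (determinant(S, logarithm = TRUE)$modulus[1] + p)
  k <- fit$spec$npar
  out <- list(
    measure = measure, tracts = tracts,
    loadings = pars$l1, uniquenesses = pars$l2,
    std_loadings = std_load, communality = communality,
    variance_explained = mean(communality),
    resid_pairs = if (!is.null(resid_pairs))
      cbind(resid_pairs[, c("t1", "t2")], value = pars$r) else NULL,
    neg2ll = fit$neg2ll, npar = k,
    AIC = fit$neg2ll + 2 * k, BIC = fit$neg2ll + log(fit$n) * k,
    chisq = max(fit$objective - f_sat, 0),
    df = p * (p + 1) / 2 - k,
    n = fit$n, convergence = fit$convergence, grad_norm = fit$grad_norm,
    covariates = covariates, age_center = age_center, age_scale = age_scale,
    implied_cov = Sigma,
    E = prep$E, subject_ids = prep$ids, a_centered = prep$a_centered,
    engine = fit, bins = bins
  )
  if (compute_se) {
    V <- .fe_vcov(fit, bins)
    out$vcov <- V
    se <- sqrt(pmax(diag(V), 0))
    out$se_loadings <- stats::setNames(se[fit$spec$idx$l1], tracts)
    out$se_uniquenesses <- stats::setNames(se[fit$spec$idx$l2], tracts)
  }
  class(out) <- "dediff_factor_fit"
  out
}

#' @export
print.dediff_factor_fit <- function(x, ...) {
  cat("One-factor model:", x$measure, "(", length(x$tracts), "tracts, n =",
      x$n, ")\n")
  cat("  variance explained by factor:",
      sprintf("%.1f%%", 100 * x$variance_explained), "\n")
  cat("  -2 log-likelihood:", sprintf("%.1f", x$neg2ll),
      " AIC:", sprintf("%.1f", x$AIC), " BIC:", sprintf("%.1f", x$BIC), "\n")
  if (!is.null(x$resid_pairs) && nrow(x$resid_pairs))
    cat("  residual covariances:", nrow(x$resid_pairs), "pair(s)\n")
  invisible(x)
}

#' Tracts with weak general-factor loadings
#'
#' Returns the tract units whose absolute standardized loading falls below
#' the threshold, i.e. the candidates for removal from the core indicator
#' set.
#'
#' @param fit A `dediff_factor_fit`.
#' @param threshold Absolute standardized-loading cutoff (default 0.3).
#' @return Character vector (possibly empty) of tract units to remove.
#' @export
prune_low_loadings <- function(fit, threshold = 0.3) {
  names(fit$std_loadings)[abs(fit$std_loadings) < threshold]
}

#' Greedy residual-covariance augmentation
#'
#' Starting from a converged one-factor fit, repeatedly adds the tract pair
#' with the largest modification score (the expected likelihood improvement
#' from freeing that residual covariance), confirms each addition with a
#' likelihood-ratio test, and stops when the improvement p-value exceeds
#' `p_threshold` or `max_pairs` have been added. Bilateral homologue pairs
#' are preferred on ties.
#'
#' @inheritParams fit_one_factor
#' @param fit The base `dediff_factor_fit`.
#' @param max_pairs Maximum number of pairs to add (default 10).
#' @param p_threshold Stop when the LR improvement p-value exceeds this
#'   (default 0.001).
#' @return The augmented fit, with an `addition_path` data frame recording
#'   each step (pair, modification score, LR statistic, p-value, accepted).
#' @export
add_residual_covariances <- function(table, subjects, fit, max_pairs = 10,
                                     p_threshold = 0.001) {
  if (max_pairs <= 0) {
    fit$addition_path <- data.frame()
    return(fit)
  }
  tracts <- fit$tracts
  homologue <- function(t1, t2) {
    sub("_[LR]$", "", t1) == sub("_[LR]$", "", t2) & t1 != t2
  }
  current <- fit
  path <- list()
  for (step in seq_len(max_pairs)) {
    mi <- .modification_scores(current)
    have <- current$resid_pairs
    if (!is.null(have) && nrow(have)) {
      used <- paste(pmin(have$t1, have$t2), pmax(have$t1, have$t2))
      mi <- mi[!(paste(pmin(mi$t1, mi$t2), pmax(mi$t1, mi$t2)) %in% used), ]
    }
    if (!nrow(mi)) break
    # rank by score; on effective ties prefer left-right homologues
    mi <- mi[order(-mi$score, -homologue(mi$t1, mi$t2)), ]
    top_tie <- mi$score >= mi$score[1] - 1e-6
    if (any(top_tie & homologue(mi$t1, mi$t2)))
      mi <- mi[order(-(top_tie & homologue(mi$t1, mi$t2)), -mi$score), ]
    cand <- mi[1, ]
    new_pairs <- rbind(
      if (!is.null(have)) have[, c("t1", "t2")] else NULL,
      data.frame(t1 = cand$t1, t2 = cand$t2))
    refit <- fit_one_factor(table, subjects, fit$measure, tracts,
                            resid_pairs = new_pairs,
                            covariates = fit$covariates,
                            age_center = fit$age_center,
                            age_scale = fit$age_scale,
                            on_heywood = "warn")
    lr <- max(current$neg2ll - refit$neg2ll, 0)
    pval <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    accept <- pval < p_threshold
    path[[step]] <- data.frame(t1 = cand$t1, t2 = cand$t2,
                               score = cand$score, lr = lr, p = pval,
                               accepted = accept)
    if (!accept) break
    current <- refit
  }
  current$addition_path <- if (length(path)) do.call(rbind, path) else data.frame()
  current
}

# Univariate modification scores for freeing each residual covariance:
# score^2 / (2 * curvature) of the deviance, the expected chi-square(1)
# improvement.
.modification_scores <- function(fit) {
  pars <- .fe_unpack(fit$engine$par, fit$engine$spec)
  Sigma <- .fe_sigma(pars, fit$engine$spec, 0)
  S <- Reduce(`+`, lapply(fit$bins, function(b) b$n * b$M)) / fit$n
  Sinv <- solve(Sigma)
  Wm <- fit$n * (Sinv - Sinv %*% S %*% Sinv)
  p <- length(fit$tracts)
  out <- list()
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    gr <- 2 * Wm[j, k]
    hess <- 2 * fit$n * (Sinv[j, k]^2 + Sinv[j, j] * Sinv[k, k])
    out[[length(out) + 1L]] <- data.frame(
      t1 = fit$tracts[j], t2 = fit$tracts[k], score = gr^2 / (2 * hess))
  }
  do.call(rbind, out)
}

#' Regression factor scores
#'
#' Posterior-mean (regression-method) factor scores from a fitted one-factor
#' model: `g_hat = lambda' Sigma^{-1} e` per subject, using the
#' covariate-adjusted tract residuals stored in the fit. Scores have mean
#' approximately 0 and variance equal to the score reliability
#' `lambda' Sigma^{-1} lambda` (at most 1).
#'
#' @param fit A `dediff_factor_fit`.
#' @return Data frame with `subject_id` and `score`; the score reliability
#'   is attached as attribute `"reliability"`.
#' @export
factor_scores <- function(fit) {
  Sigma <- fit$implied_cov
  wts <- solve(Sigma, fit$loadings)
  sc <- as.vector(fit$E %*% wts)
  rel <- sum(fit$loadings * wts)
  out <- data.frame(subject_id = fit$subject_ids, score = sc,
                    stringsAsFactors = FALSE)
  attr(out, "reliability") <- rel
  out
}

#' Thalamic-radiation composite (gTR)
#'
#' First unrotated principal component of the six thalamic-radiation tract
#' units (bilateral anterior, superior and posterior radiations) for one
#' measure, sign-aligned so that higher scores correspond to higher mean
#' tract values.
#'
#' @param table Tidy metric table.
#' @param measure Measure label.
#' @return List with `scores` (data frame `subject_id`, `score`),
#'   `loadings`, and `var_share` (the largest eigenvalue share of the 6x6
#'   correlation matrix).
#' @export
fit_gtr <- function(table, measure) {
  units <- c("ATR_L", "ATR_R", "STR_L", "STR_R", "PTR_L", "PTR_R")
  W <- metric_wide(table, measure)
  units <- intersect(units, colnames(W))
  if (length(units) < 2) stop("need at least 2 thalamic-radiation tracts")
  W <- W[, units, drop = FALSE]
  ok <- stats::complete.cases(W)
  Z <- scale(W[ok, , drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1]
  sc <- pc$x[, 1]
  if (sum(load) < 0) { load <- -load; sc <- -sc }
  list(scores = data.frame(subject_id = rownames(W)[ok], score = as.vector(sc),
                           stringsAsFactors = FALSE),
       loadings = load,
       var_share = pc$sdev[1]^2 / sum(pc$sdev^2))
}
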