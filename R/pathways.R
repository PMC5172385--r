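#' Common versus independent age-pathway models
#'
#' Tests whether age variation in the tracts is carried by the general
#' factor alone (common pathway: age predicts only the latent factor), by
#' tract-specific paths alone (independent pathways: age predicts each
#' tract, the factor carries no age variance), or by both (common +
#' independent). Fitted as joint covariance-structure ML over the tracts
#' (sex-adjusted) and the exogenous age block (standardized age and, for
#' all measures except FA, its square), with the exogenous covariance fixed
#' at its sample value. For the common+independent model, tract-specific
#' age paths are forward-selected: candidates are ranked by modification
#' score and confirmed by likelihood-ratio refit, the age and age-squared
#' paths always entering together.
#'
#' @inheritParams fit_one_factor
#' @param select_p Forward-selection significance threshold (default 0.05).
#' @param max_add Maximum tracts given direct paths (default 10).
#' @return List of class `dediff_pathways`: per-model fits (`common`,
#'   `independent`, `common_independent`) each with `neg2ll`, `npar`,
#'   `AIC`, `BIC`; a `comparison` table including chi-square difference
#'   tests; and `selected_tracts`.
#' @export
fit_pathway_models <- function(table, subjects, measure,
                               tracts = core_tracts(), resid_pairs = NULL,
                               age_center = 60, age_scale = 7.5,
                               select_p = 0.05, max_add = 10) {
  W <- metric_wide(table, measure, tracts)
  ids <- rownames(W)
  i <- match(ids, subjects$subject_id)
  A <- (subjects$age[i] - age_center) / age_scale
  sex <- subjects$sex[i]
  X <- if (measure == "FA") cbind(age = A) else cbind(age = A, age2 = A^2 - mean(A^2))
  ok <- stats::complete.cases(W) & !is.na(A) & !is.na(sex)
  E <- qr.resid(qr(cbind(1, sex[ok])), W[ok, , drop = FALSE])
  Xc <- scale(X[ok, , drop = FALSE], scale = FALSE)
  dat <- cbind(E, Xc)
  n <- nrow(dat)
  S <- crossprod(dat) / n
  p <- length(tracts); q <- ncol(Xc)
  pairs <- .fof_pair_idx(resid_pairs, tracts)

  common <- .pw_fit(S, n, p, q, gamma_free = TRUE, b_rows = integer(0), pairs)
  independent <- .pw_fit(S, n, p, q, gamma_free = FALSE, b_rows = seq_len(p), pairs)

  ## forward selection for common+independent
  current <- common
  b_rows <- integer(0)
  sel_log <- list()
  for (step in seq_len(max_add)) {
    cand <- setdiff(seq_len(p), b_rows)
    if (!length(cand)) break
    scores <- vapply(cand, function(t_idx)
      .pw_candidate_score(current, S, n, p, q, t_idx), numeric(1))
    t_best <- cand[which.max(scores)]
    trial <- .pw_fit(S, n, p, q, TRUE, sort(c(b_rows, t_best)), pairs,
                     start_from = current)
    lr <- max(current$neg2ll - trial$neg2ll, 0)
    pval <- stats::pchisq(lr, df = q, lower.tail = FALSE)
    sel_log[[step]] <- data.frame(tract = tracts[t_best], lr = lr, p = pval,
                                  accepted = pval < select_p)
    if (pval >= select_p) break
    b_rows <- sort(c(b_rows, t_best))
    current <- trial
  }
  ci <- current

  cmp <- data.frame(
    model = c("common", "independent", "common_independent"),
    npar = c(common$npar, independent$npar, ci$npar),
    neg2ll = c(common$neg2ll, independent$neg2ll, ci$neg2ll),
    AIC = c(common$AIC, independent$AIC, ci$AIC),
    BIC = c(common$BIC, independent$BIC, ci$BIC))
  lr_ci <- max(common$neg2ll - ci$neg2ll, 0)
  df_ci <- ci$npar - common$npar
  cmp$chisq_vs_common <- c(NA, NA, lr_ci)
  cmp$p_vs_common <- c(NA, NA,
                       if (df_ci > 0) stats::pchisq(lr_ci, df_ci, lower.tail = FALSE)
                       else NA)
  structure(list(common = common, independent = independent,
                 common_independent = ci, comparison = cmp,
                 selected_tracts = tracts[b_rows],
                 selection_log = if (length(sel_log)) do.call(rbind, sel_log)
                                 else data.frame(),
                 tracts = tracts, measure = measure, n = n),
            class = "dediff_pathways")
}

# joint covariance model: y = B x + lambda (gamma'x + z) + u (+ pair terms)
.pw_sigma <- function(th, p, q, gamma_free, b_rows, pairs, Sxx) {
  l1 <- th[seq_len(p)]
  l2 <- th[p + seq_len(p)]
  at <- 2L * p
  gam <- rep(0, q)
  if (gamma_free) { gam <- th[at + seq_len(q)]; at <- at + q }
  B <- matrix(0, p, q)
  if (length(b_rows)) {
    B[b_rows, ] <- matrix(th[at + seq_len(length(b_rows) * q)],
                          length(b_rows), q, byrow = TRUE)
    at <- at + length(b_rows) * q
  }
  r <- if (!is.null(pairs)) th[at + seq_len(nrow(pairs))] else numeric(0)
  Tm <- B + tcrossprod(l1, gam)
  Syy <- Tm %*% Sxx %*% t(Tm) + tcrossprod(l1) + diag(l2^2, p)
  if (!is.null(pairs)) for (qq in seq_len(nrow(pairs))) {
    j <- pairs$j[qq]; k <- pairs$k[qq]
    Syy[j, k] <- Syy[j, k] + r[qq]; Syy[k, j] <- Syy[k, j] + r[qq]
  }
  Syx <- Tm %*% Sxx
  rbind(cbind(Syy, Syx), cbind(t(Syx), Sxx))
}

.pw_fit <- function(S, n, p, q, gamma_free, b_rows, pairs, start_from = NULL) {
  Sxx <- S[p + seq_len(q), p + seq_len(q), drop = FALSE]
  npar <- 2L * p + gamma_free * q + length(b_rows) * q +
    if (!is.null(pairs)) nrow(pairs) else 0L
  obj <- function(th) {
    Sig <- .pw_sigma(th, p, q, gamma_free, b_rows, pairs, Sxx)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    n * (2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S))
  }
  th0 <- numeric(npar)
  Syy <- S[seq_len(p), seq_len(p)]
  ev <- eigen(Syy, symmetric = TRUE)
  l1 <- sqrt(max(ev$values[1], 0.1)) * ev$vectors[, 1]
  if (sum(l1) < 0) l1 <- -l1
  th0[seq_len(p)] <- l1
  th0[p + seq_len(p)] <- sqrt(pmax(diag(Syy) - l1^2, 0.05 * diag(Syy)))
  if (!is.null(start_from)) {
    th0[seq_len(p)] <- start_from$lambda
    th0[p + seq_len(p)] <- start_from$uniq
    if (gamma_free && !is.null(start_from$gamma) &&
        length(start_from$gamma) == q)
      th0[2 * p + seq_len(q)] <- start_from$gamma
  }
  lower <- c(rep(-Inf, p), rep(1e-3, p), rep(-Inf, npar - 2 * p))
  opt <- stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = 2000, factr = 1e7))
  neg2ll <- opt$value + n * (p + q) * log(2 * pi)
  at <- 2L * p
  gam <- if (gamma_free) opt$par[at + seq_len(q)] else rep(0, q)
  if (gamma_free) at <- at + q
  Bsel <- if (length(b_rows))
    matrix(opt$par[at + seq_len(length(b_rows) * q)], length(b_rows), q,
           byrow = TRUE) else NULL
  list(lambda = opt$par[seq_len(p)], uniq = opt$par[p + seq_len(p)],
       gamma = gam, b_rows = b_rows, B = Bsel,
       objective = opt$value, neg2ll = neg2ll, npar = npar,
       AIC = neg2ll + 2 * npar, BIC = neg2ll + log(n) * npar,
       convergence = opt$convergence,
       spec = list(p = p, q = q, gamma_free = gamma_free, pairs = pairs))
}

# squared-gradient modification score for adding tract t's direct age paths
.pw_candidate_score <- function(fit, S, n, p, q, t_idx, h = 1e-4) {
  Sxx <- S[p + seq_len(q), p + seq_len(q), drop = FALSE]
  sp <- fit$spec
  base_rows <- fit$b_rows
  rows_new <- sort(c(base_rows, t_idx))
  pos <- which(rows_new == t_idx)
  th_base <- c(fit$lambda, fit$uniq,
               if (sp$gamma_free) fit$gamma,
               if (length(base_rows)) as.vector(t(fit$B)),
               numeric(0))
  # insert zeros for the candidate's b-row at its sorted position
  bvec <- numeric(length(rows_new) * q)
  if (length(base_rows)) {
    old <- matrix(as.vector(t(fit$B)), length(base_rows), q, byrow = TRUE)
    newm <- matrix(0, length(rows_new), q)
    newm[match(base_rows, rows_new), ] <- old
    bvec <- as.vector(t(newm))
  }
  th <- c(fit$lambda, fit$uniq, if (sp$gamma_free) fit$gamma, bvec)
  obj <- function(tt) {
    Sig <- .pw_sigma(tt, p, q, sp$gamma_free, rows_new, sp$pairs, Sxx)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    n * (2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S))
  }
  off <- 2 * p + sp$gamma_free * q + (pos - 1) * q
  g2 <- 0
  for (jj in seq_len(q)) {
    tp <- th; tp[off + jj] <- h
    tm <- th; tm[off + jj] <- -h
    g2 <- g2 + ((obj(tp) - obj(tm)) / (2 * h))^2
  }
  g2
}
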