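#' Bootstrapped elastic-net predictor selection
#'
#' Identifies a stable predictor set for a target (chronological age) from
#' highly collinear candidates. Subjects are split into equal train and
#' test halves; within the train half, an elastic net (default mixing 0.5,
#' penalty chosen by internal 10-fold cross-validation) is refitted on
#' `n_boot` bootstrap resamples, and predictors whose coefficient is
#' nonzero in more than `freq_threshold` of the resamples are selected.
#'
#' @param candidates Numeric matrix / data frame of candidate predictors
#'   (named columns).
#' @param target Numeric target vector (e.g. age).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param freq_threshold Inclusion-frequency threshold (default 0.60).
#' @param split_seed Seed governing the half split, the resamples and the
#'   cross-validation folds.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param refit_lambda Re-run the penalty cross-validation inside every
#'   resample (default `TRUE`); `FALSE` fixes the penalty once on the full
#'   train half.
#' @param lambda_choice Cross-validated penalty rule: `"1se"` (default,
#'   the parsimonious one-standard-error rule, which keeps noise
#'   predictors' inclusion frequencies low) or `"min"`.
#' @return List of class `dediff_enet`: `frequency` (per candidate),
#'   `selected`, `train_idx`, `test_idx`, and the settings used.
#' @export
bootstrap_enet_select <- function(candidates, target, n_boot = 1000,
                                  freq_threshold = 0.60, split_seed = 1,
                                  alpha = 0.5, refit_lambda = TRUE,
                                  lambda_choice = c("1se", "min")) {
  lambda_choice <- match.arg(lambda_choice)
  s_rule <- paste0("lambda.", lambda_choice)
  Xall <- as.matrix(candidates)
  if (is.null(colnames(Xall))) colnames(Xall) <- paste0("V", seq_len(ncol(Xall)))
  ok <- stats::complete.cases(Xall) & !is.na(target)
  Xall <- Xall[ok, , drop = FALSE]; yall <- target[ok]
  n <- nrow(Xall)
  if (n < 10 * ncol(Xall)) stop("need at least 10 subjects per candidate")
  set.seed(split_seed)
  train_idx <- sort(sample.int(n, floor(n / 2)))
  test_idx <- setdiff(seq_len(n), train_idx)
  Xtr <- Xall[train_idx, , drop = FALSE]; ytr <- yall[train_idx]
  ntr <- length(ytr)

  lambda_fixed <- NULL
  if (!refit_lambda) {
    cv0 <- glmnet::cv.glmnet(Xtr, ytr, alpha = alpha, nfolds = 10)
    lambda_fixed <- cv0[[s_rule]]
  }
  hits <- matrix(0L, n_boot, ncol(Xall), dimnames = list(NULL, colnames(Xall)))
  for (b in seq_len(n_boot)) {
    i <- sample.int(ntr, ntr, replace = TRUE)
    if (refit_lambda) {
      cv <- glmnet::cv.glmnet(Xtr[i, , drop = FALSE], ytr[i], alpha = alpha,
                              nfolds = 10)
      cf <- stats::coef(cv, s = s_rule)
    } else {
      fitb <- glmnet::glmnet(Xtr[i, , drop = FALSE], ytr[i], alpha = alpha,
                             lambda = lambda_fixed)
      cf <- stats::coef(fitb)
    }
    hits[b, ] <- as.integer(as.vector(cf)[-1] != 0)
  }
  freq <- colMeans(hits)
  selected <- names(freq)[freq > freq_threshold]
  if (!length(selected))
    warning("no predictor exceeded the inclusion-frequency threshold")
  structure(list(frequency = freq, selected = selected,
                 train_idx = train_idx, test_idx = test_idx,
                 n_boot = n_boot, freq_threshold = freq_threshold,
                 alpha = alpha, refit_lambda = refit_lambda,
                 lambda_choice = lambda_choice, lambda_fixed = lambda_fixed),
            class = "dediff_enet")
}

#' Confirmatory train/test regression of the selected predictors
#'
#' Fits the identical multiple-regression formula in the train and test
#' halves and reports standardized coefficients, R-squared and variance
#' inflation factors, the check that the selected predictor set generalizes.
#'
#' @param selected Character vector of selected predictor names.
#' @param candidates Candidate matrix (as passed to
#'   [bootstrap_enet_select()]).
#' @param target Target vector.
#' @param train_idx,test_idx Row indices of the two halves.
#' @return List of class `dediff_confirm`: per-half coefficient tables,
#'   `r_squared`, and `vif` (from the train half).
#' @export
confirm_train_test <- function(selected, candidates, target,
                               train_idx, test_idx) {
  if (!length(selected)) stop("selected predictor set is empty")
  Xall <- as.matrix(candidates)[, selected, drop = FALSE]
  halves <- list(train = train_idx, test = test_idx)
  out <- list()
  r2 <- c(train = NA_real_, test = NA_real_)
  for (h in names(halves)) {
    i <- halves[[h]]
    d <- data.frame(scale(cbind(y = target[i], Xall[i, , drop = FALSE])))
    fit <- stats::lm(y ~ ., data = d)
    sm <- summary(fit)
    out[[h]] <- data.frame(term = rownames(sm$coefficients)[-1],
                           beta = sm$coefficients[-1, 1],
                           se = sm$coefficients[-1, 2],
                           p = sm$coefficients[-1, 4], row.names = NULL)
    r2[h] <- sm$r.squared
  }
  ## VIFs on the train half: 1 / (1 - R^2_j) regressing each predictor on
  ## the others
  Xtr <- scale(Xall[train_idx, , drop = FALSE])
  vif <- vapply(seq_len(ncol(Xtr)), function(j) {
    if (ncol(Xtr) == 1) return(1)
    r2j <- summary(stats::lm(Xtr[, j] ~ Xtr[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2j)
  }, numeric(1))
  names(vif) <- colnames(Xtr)
  structure(list(train = out$train, test = out$test, r_squared = r2,
                 vif = vif, selected = selected),
            class = "dediff_confirm")
}

#' Incremental age variance from thalamic volume and gTR
#'
#' Nested regressions of age on thalamic volume and the thalamic-radiation
#' composite, without and with total brain volume, to ask whether the
#' thalamus-specific measures carry age information beyond global atrophy.
#' All variables are z-standardized.
#'
#' @param thal_volume,gtr,total_brain_volume,age Numeric vectors.
#' @return List with `base` and `with_tbv` coefficient tables and an
#'   `r_squared` pair.
#' @export
thalamus_increment <- function(thal_volume, gtr, total_brain_volume, age) {
  d <- data.frame(age = age, thal = thal_volume, gtr = gtr,
                  tbv = total_brain_volume)
  d <- as.data.frame(scale(d[stats::complete.cases(d), ]))
  f1 <- stats::lm(age ~ thal + gtr, data = d)
  f2 <- stats::lm(age ~ thal + gtr + tbv, data = d)
  tab <- function(f) {
    sm <- summary(f)$coefficients
    data.frame(term = rownames(sm)[-1], beta = sm[-1, 1], se = sm[-1, 2],
               p = sm[-1, 4], row.names = NULL)
  }
  list(base = tab(f1), with_tbv = tab(f2),
       r_squared = c(base = summary(f1)$r.squared,
                     with_tbv = summary(f2)$r.squared))
}
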