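# Covariance-structure maximum-likelihood engine.
#
# Fits Sigma(a) = L(a) L(a)' + Psi(a) + R to age-binned second moments,
# where L(a) = lambda1 * (1 + lambda1' a), Psi(a) = diag(lambda2^2 (1 + lambda2' a)^2)
# and R is a sparse symmetric matrix of residual covariances. The deviance
# (up to the constant N p log 2pi) is
#   f(theta) = sum_b n_b [ log|Sigma(a_b)| + tr(Sigma(a_b)^{-1} M_b) ]
# with M_b the uncentered second-moment matrix of the covariate-adjusted
# tract values in age bin b. With moderation fixed at zero the binned sum
# collapses algebraically to the usual single-group ML discrepancy, so the
# unmoderated fit is exact regardless of binning. Analytic gradients keep
# fits at n ~ 3,500, p = 22 around a second.

# --- parameter packing ------------------------------------------------------

.fe_spec <- function(p, mode = c("none", "invariant", "tract_specific"),
                     pairs = NULL, max_abs_a = 18) {
  mode <- match.arg(mode)
  nmod <- switch(mode, none = 0L, invariant = 1L, tract_specific = p)
  q <- if (is.null(pairs)) 0L else nrow(pairs)
  idx <- list(l1 = seq_len(p), l2 = p + seq_len(p))
  at <- 2L * p
  if (nmod > 0) {
    idx$l1p <- at + seq_len(nmod); at <- at + nmod
    idx$l2p <- at + seq_len(nmod); at <- at + nmod
  }
  if (q > 0) { idx$r <- at + seq_len(q); at <- at + q }
  # keep 1 + lambda' a bounded away from 0 over the supported age range
  mod_bound <- 0.95 / max_abs_a
  lower <- c(rep(-Inf, p), rep(1e-3, p), rep(-mod_bound, 2L * nmod), rep(-Inf, q))
  upper <- c(rep(Inf, p), rep(Inf, p), rep(mod_bound, 2L * nmod), rep(Inf, q))
  list(p = p, mode = mode, nmod = nmod, pairs = pairs, q = q, idx = idx,
       npar = at, lower = lower, upper = upper)
}

.fe_unpack <- function(theta, spec) {
  out <- list(l1 = theta[spec$idx$l1], l2 = theta[spec$idx$l2])
  out$l1p <- if (spec$nmod > 0) theta[spec$idx$l1p] else 0
  out$l2p <- if (spec$nmod > 0) theta[spec$idx$l2p] else 0
  out$r <- if (spec$q > 0) theta[spec$idx$r] else numeric(0)
  out
}

.fe_sigma <- function(pars, spec, a) {
  w <- 1 + pars$l1p * a
  v <- 1 + pars$l2p * a
  L <- pars$l1 * w
  S <- tcrossprod(L) + diag((pars$l2 * v)^2, spec$p)
  if (spec$q > 0) {
    for (q in seq_len(spec$q)) {
      j <- spec$pairs$j[q]; k <- spec$pairs$k[q]
      S[j, k] <- S[j, k] + pars$r[q]
      S[k, j] <- S[k, j] + pars$r[q]
    }
  }
  S
}

# --- objective and gradient over binned moments -----------------------------

.fe_objective <- function(theta, spec, bins) {
  pars <- .fe_unpack(theta, spec)
  f <- 0
  for (b in bins) {
    S <- .fe_sigma(pars, spec, b$a)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    f <- f + b$n * (ld + sum(Sinv * b$M))
  }
  f
}

.fe_gradient <- function(theta, spec, bins) {
  pars <- .fe_unpack(theta, spec)
  g <- numeric(spec$npar)
  for (b in bins) {
    a <- b$a
    w <- 1 + pars$l1p * a
    v <- 1 + pars$l2p * a
    L <- pars$l1 * w
    S <- .fe_sigma(pars, spec, a)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, spec$npar))
    Sinv <- chol2inv(ch)
    W <- b$n * (Sinv - Sinv %*% b$M %*% Sinv)
    WL <- as.vector(W %*% L)
    dW <- diag(W)
    wv <- if (length(w) == 1L) rep(w, spec$p) else w
    vv <- if (length(v) == 1L) rep(v, spec$p) else v
    g[spec$idx$l1] <- g[spec$idx$l1] + 2 * wv * WL
    g[spec$idx$l2] <- g[spec$idx$l2] + 2 * pars$l2 * vv^2 * dW
    if (spec$mode == "invariant") {
      g[spec$idx$l1p] <- g[spec$idx$l1p] + 2 * a * sum(pars$l1 * WL)
      g[spec$idx$l2p] <- g[spec$idx$l2p] + 2 * a * sum(pars$l2^2 * vv * dW)
    } else if (spec$mode == "tract_specific") {
      g[spec$idx$l1p] <- g[spec$idx$l1p] + 2 * a * pars$l1 * WL
      g[spec$idx$l2p] <- g[spec$idx$l2p] + 2 * a * pars$l2^2 * vv * dW
    }
    if (spec$q > 0)
      for (q in seq_len(spec$q))
        g[spec$idx$r[q]] <- g[spec$idx$r[q]] + 2 * W[spec$pairs$j[q], spec$pairs$k[q]]
  }
  g
}

# --- data preparation -------------------------------------------------------

# Residualize a wide matrix on a covariate design (complete cases).
.fe_residualize <- function(Y, X) {
  ok <- stats::complete.cases(Y) & stats::complete.cases(X)
  E <- qr.resid(qr(X[ok, , drop = FALSE]), Y[ok, , drop = FALSE])
  list(E = E, ok = ok)
}

# Age-binned uncentered second moments. With a single bin this is the
# pooled moment matrix (equals the ML covariance since columns of E have
# mean zero by construction). Bin breaks are anchored on absolute age so
# the binning is independent of the centering constant (which makes the
# model family exactly invariant to re-centering).
.fe_bins <- function(E, a_centered = NULL, width = 0.75, center = 0) {
  if (is.null(a_centered)) {
    return(list(list(n = nrow(E), M = crossprod(E) / nrow(E), a = 0)))
  }
  age <- a_centered + center
  br <- seq(floor(min(age)), ceiling(max(age)) + width, by = width)
  cut_idx <- findInterval(age, br, rightmost.closed = TRUE)
  out <- list()
  for (b in sort(unique(cut_idx))) {
    i <- which(cut_idx == b)
    out[[length(out) + 1L]] <- list(n = length(i),
                                    M = crossprod(E[i, , drop = FALSE]) / length(i),
                                    a = mean(a_centered[i]))
  }
  out
}

# --- optimisation -----------------------------------------------------------

.fe_start <- function(bins, spec) {
  N <- sum(vapply(bins, `[[`, numeric(1), "n"))
  S <- Reduce(`+`, lapply(bins, function(b) b$n * b$M)) / N
  ev <- eigen(S, symmetric = TRUE)
  l1 <- sqrt(max(ev$values[1], 0.1)) * ev$vectors[, 1]
  if (sum(l1) < 0) l1 <- -l1
  psi <- pmax(diag(S) - l1^2, 0.05 * diag(S))
  theta <- numeric(spec$npar)
  theta[spec$idx$l1] <- l1
  theta[spec$idx$l2] <- sqrt(psi)
  theta
}

.fe_fit <- function(bins, spec, start = NULL, n_starts = 5L, seed_jitter = 11L) {
  if (is.null(start)) start <- .fe_start(bins, spec)
  best <- NULL
  set.seed(seed_jitter)
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) start else
      start * (1 + stats::rnorm(length(start), 0, 0.05)) +
        stats::rnorm(length(start), 0, 0.01)
    th0 <- pmin(pmax(th0, spec$lower + 1e-6), spec$upper - 1e-6)
    opt <- try(stats::optim(th0, .fe_objective, .fe_gradient,
                            spec = spec, bins = bins, method = "L-BFGS-B",
                            lower = spec$lower, upper = spec$upper,
                            control = list(maxit = 1000, factr = 1e7)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
    if (!is.null(best) && best$convergence == 0 && s >= 1L) break
  }
  if (is.null(best)) stop("covariance-structure optimisation failed for all starts")
  gn <- sqrt(sum(.fe_gradient(best$par, spec, bins)^2))
  if (best$convergence != 0 && gn > 1e-2)
    warning("optimiser did not report convergence (gradient norm ",
            signif(gn, 3), ")")
  # orient the general factor positively
  if (sum(best$par[spec$idx$l1]) < 0)
    best$par[spec$idx$l1] <- -best$par[spec$idx$l1]
  N <- sum(vapply(bins, `[[`, numeric(1), "n"))
  p <- spec$p
  list(par = best$par, objective = best$value,
       neg2ll = best$value + N * p * log(2 * pi),
       convergence = best$convergence, grad_norm = gn,
       n = N, spec = spec)
}

# Observed-information covariance of the estimates: numerical Jacobian of
# the analytic gradient of the negative log-likelihood (= f/2).
.fe_vcov <- function(fit, bins, h = 1e-5) {
  th <- fit$par; k <- length(th)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    step <- h * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + step
    tm <- th; tm[j] <- tm[j] - step
    H[, j] <- (.fe_gradient(tp, fit$spec, bins) -
               .fe_gradient(tm, fit$spec, bins)) / (2 * step)
  }
  H <- (H + t(H)) / 4   # gradient of f = -2 loglik, so information = H_f / 2
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) {
    V <- tryCatch(solve(H + diag(1e-8, k)), error = function(e) matrix(NA, k, k))
  }
  V
}

# Heywood check: unique SD stuck at its lower bound.
.fe_check_heywood <- function(fit, tract_names, action = c("error", "warn", "ignore")) {
  action <- match.arg(action)
  if (action == "ignore") return(invisible(character(0)))
  l2 <- fit$par[fit$spec$idx$l2]
  bad <- tract_names[l2 <= 2e-3]
  if (length(bad)) {
    msg <- paste0("Heywood case (unique variance collapsed) for tract(s): ",
                  paste(bad, collapse = ", "))
    if (action == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(bad)
}
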