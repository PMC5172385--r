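#' Communality-versus-age trajectory
#'
#' Computes per-tract and mean-across-tract communality (the proportion of
#' age-conditional variance explained by the general factor,
#' `h(a) = s(a)/(s(a)+u(a))` with `s(a) = (lambda1(1+lambda1'a))^2` and
#' `u(a) = (lambda2(1+lambda2'a))^2`) at 5-year anchor ages, with
#' delta-method standard errors, then interpolates the mean curve and its
#' SE band onto a dense age grid. The default interpolant is a natural
#' cubic spline through the anchors (so the dense curve passes exactly
#' through the anchor values); a single least-squares cubic polynomial is
#' available as an alternative.
#'
#' @param fit A `dediff_mod_fit` (standard errors required for CIs).
#' @param grid Dense age grid (default every 0.25 years over 45-75).
#' @param anchors Anchor ages (default 45, 50, ..., 75).
#' @param level Confidence level for the band (default 0.95).
#' @param interp `"spline"` (natural cubic spline, default) or `"cubic"`
#'   (single cubic polynomial fitted to the anchors).
#' @return Object of class `dediff_comm_curve`: `age` (grid), `h_mean`,
#'   `se`, `lo`, `hi`, `anchors` (data frame with age, h, se), and
#'   `per_tract` (tracts x grid matrix of exact model-implied communality).
#' @export
communality_curve <- function(fit, grid = seq(45, 75, by = 0.25),
                              anchors = seq(45, 75, by = 5), level = 0.95,
                              interp = c("spline", "cubic")) {
  interp <- match.arg(interp)
  a_anchor <- anchors - fit$age_center
  H <- .mod_communality(fit, a_anchor)
  h_anchor <- colMeans(H)
  se_anchor <- rep(NA_real_, length(anchors))
  if (!is.null(fit$vcov)) {
    se_anchor <- vapply(a_anchor, function(a) .mean_comm_se(fit, a), numeric(1))
  }
  dense <- interpolate_anchors(anchors, h_anchor, grid, method = interp)
  se_dense <- if (all(is.finite(se_anchor)))
    interpolate_anchors(anchors, se_anchor, grid, method = interp)
  else rep(NA_real_, length(grid))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    age = grid, h_mean = dense, se = se_dense,
    lo = pmax(dense - zq * se_dense, 0), hi = pmin(dense + zq * se_dense, 1),
    anchors = data.frame(age = anchors, h = h_anchor, se = se_anchor),
    per_tract = .mod_communality(fit, grid - fit$age_center),
    measure = fit$measure, interp = interp
  ), class = "dediff_comm_curve")
}

#' Interpolate anchor values onto a dense grid
#'
#' The interpolation contract used for communality trajectories: a natural
#' cubic spline reproduces the anchors exactly and is monotone between
#' monotone anchors in the cases arising here; the `"cubic"` method fits a
#' single cubic polynomial by least squares.
#'
#' @param anchor_x,anchor_y Anchor locations and values.
#' @param grid Output locations.
#' @param method `"spline"` or `"cubic"`.
#' @return Numeric vector along `grid`.
#' @export
interpolate_anchors <- function(anchor_x, anchor_y, grid,
                                method = c("spline", "cubic")) {
  method <- match.arg(method)
  if (method == "spline") {
    stats::spline(anchor_x, anchor_y, xout = grid, method = "natural")$y
  } else {
    x <- anchor_x - mean(anchor_x)   # center for conditioning
    cf <- stats::lm.fit(cbind(1, x, x^2, x^3), anchor_y)$coefficients
    xg <- grid - mean(anchor_x)
    as.vector(cbind(1, xg, xg^2, xg^3) %*% cf)
  }
}

# delta-method SE of the mean communality at centered age a
.mean_comm_se <- function(fit, a, h = 1e-6) {
  spec <- fit$engine$spec
  th <- fit$engine$par
  mean_h <- function(theta) {
    pars <- .fe_unpack(theta, spec)
    w <- 1 + rep_len(pars$l1p, spec$p) * a
    v <- 1 + rep_len(pars$l2p, spec$p) * a
    s <- (pars$l1 * w)^2; u <- (pars$l2 * v)^2
    mean(s / (s + u))
  }
  g <- vapply(seq_along(th), function(j) {
    step <- h * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + step
    tm <- th; tm[j] <- tm[j] - step
    (mean_h(tp) - mean_h(tm)) / (2 * step)
  }, numeric(1))
  sqrt(max(as.numeric(t(g) %*% fit$vcov %*% g), 0))
}

#' Change in mean communality between two ages
#'
#' The mean-across-tracts communality at `age_hi` minus at `age_lo`,
#' reported in percentage points, with a delta-method standard error — the
#' headline de-differentiation quantity (how much more variance the general
#' factor explains at the old end of the age range than at the young end).
#'
#' @param fit A `dediff_mod_fit`.
#' @param age_lo,age_hi Ages in years (defaults 45 and 75); must lie within
#'   the fitted age range.
#' @return List with `delta_pp` (percentage points), `se_pp`, and the two
#'   mean communalities.
#' @export
communality_delta <- function(fit, age_lo = 45, age_hi = 75) {
  rng <- fit$age_range_observed
  if (age_lo < rng[1] - 1 || age_hi > rng[2] + 1)
    stop("requested ages fall outside the fitted age range [",
         round(rng[1], 1), ", ", round(rng[2], 1), "]")
  a <- c(age_lo, age_hi) - fit$age_center
  H <- .mod_communality(fit, a)
  hs <- colMeans(H)
  delta <- 100 * (hs[2] - hs[1])
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    spec <- fit$engine$spec
    th <- fit$engine$par
    fdelta <- function(theta) {
      pars <- .fe_unpack(theta, spec)
      hh <- vapply(a, function(ai) {
        w <- 1 + rep_len(pars$l1p, spec$p) * ai
        v <- 1 + rep_len(pars$l2p, spec$p) * ai
        s <- (pars$l1 * w)^2; u <- (pars$l2 * v)^2
        mean(s / (s + u))
      }, numeric(1))
      hh[2] - hh[1]
    }
    g <- vapply(seq_along(th), function(j) {
      step <- 1e-6 * max(1, abs(th[j]))
      tp <- th; tp[j] <- tp[j] + step
      tm <- th; tm[j] <- tm[j] - step
      (fdelta(tp) - fdelta(tm)) / (2 * step)
    }, numeric(1))
    se <- 100 * sqrt(max(as.numeric(t(g) %*% fit$vcov %*% g), 0))
  }
  list(delta_pp = as.numeric(delta), se_pp = se,
       h_lo = as.numeric(hs[1]), h_hi = as.numeric(hs[2]))
}
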