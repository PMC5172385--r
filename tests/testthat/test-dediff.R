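test_that("moderated fit with moderation fixed at zero equals the one-factor fit", {
  co <- default_cohort()
  base <- fit_one_factor(co$table, co$subjects, "MD")
  none <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "none",
                               compute_se = FALSE)
  expect_lt(max(abs(base$loadings - none$loadings)), 1e-4)
  expect_lt(max(abs(base$uniquenesses - none$uniquenesses)), 1e-4)
  expect_equal(base$neg2ll, none$neg2ll, tolerance = 1e-8)
})

test_that("moderation estimates are null-consistent on unmoderated data", {
  gm <- gm_plain("MD")
  co <- generate_cohort(gm, 3500, seed = 71)
  mf <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant")
  expect_lt(abs(mf$lambda1p), 2 * mf$se_lambda1p + 1e-4)
  expect_lt(abs(mf$lambda2p), 2 * mf$se_lambda2p + 1e-4)
  none <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "none",
                               compute_se = FALSE)
  lr <- none$neg2ll - mf$neg2ll
  expect_gte(lr, -1e-6)
  expect_lt(lr, qchisq(0.999, df = 2))
})

test_that("planted loading moderation is recovered", {
  co <- moderated_cohort()    # lambda1' = 0.013/yr
  mf <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant")
  expect_lt(abs(mf$lambda1p - 0.013) / 0.013, 0.25)
  expect_lt(abs(mf$lambda1p - 0.013), 3 * mf$se_lambda1p)
  # Wald test flags the loading moderation
  w <- test_moderation_significance(mf)$wald
  expect_lt(w$p[w$parameter == "lambda1p"], 0.001)
})

test_that("likelihood weakly increases along the nesting chain", {
  co <- moderated_cohort()
  f0 <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "none",
                             compute_se = FALSE)
  f1 <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant",
                             compute_se = FALSE)
  f2 <- fit_moderated_factor(co$table, co$subjects, "MD",
                             mode = "tract_specific", compute_se = FALSE)
  expect_lte(f1$neg2ll, f0$neg2ll + 1e-6)
  expect_lte(f2$neg2ll, f1$neg2ll + 1e-6)
})

test_that("tract-specific moderation is not preferred under invariant truth", {
  co <- moderated_cohort()
  f1 <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant",
                             compute_se = FALSE)
  f2 <- fit_moderated_factor(co$table, co$subjects, "MD",
                             mode = "tract_specific", compute_se = FALSE)
  lr <- f1$neg2ll - f2$neg2ll
  df <- 2 * 22 - 2
  expect_gt(pchisq(lr, df, lower.tail = FALSE), 0.01)
})

test_that("re-centering age leaves likelihood and communality invariant", {
  co <- moderated_cohort()
  f60 <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant",
                              age_center = 60, compute_se = FALSE)
  f55 <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant",
                              age_center = 55, compute_se = FALSE)
  # algebraic invariance: transform the center-60 solution to center 55 and
  # evaluate the center-55 deviance there -- identical to machine precision
  d <- 55 - 60   # center shift
  s1 <- 1 + f60$lambda1p * d; s2 <- 1 + f60$lambda2p * d
  th <- f60$engine$par
  spec <- f60$engine$spec
  th[spec$idx$l1] <- th[spec$idx$l1] * s1
  th[spec$idx$l2] <- th[spec$idx$l2] * s2
  th[spec$idx$l1p] <- f60$lambda1p / s1
  th[spec$idx$l2p] <- f60$lambda2p / s2
  f_at <- dediffwm:::.fe_objective(th, spec, f55$bins)
  expect_equal(f_at, f60$engine$objective, tolerance = 1e-9)
  # and the two independently optimized fits agree closely
  expect_equal(f60$neg2ll, f55$neg2ll, tolerance = 1e-6)
  h60 <- dediffwm:::.mod_communality(f60, c(48, 66, 74) - 60)
  h55 <- dediffwm:::.mod_communality(f55, c(48, 66, 74) - 55)
  expect_lt(max(abs(h60 - h55)), 5e-3)
})

test_that("communality curve is flat without moderation and tracks truth with it", {
  gm0 <- gm_plain("MD")
  co0 <- generate_cohort(gm0, 3500, seed = 72)
  mf0 <- fit_moderated_factor(co0$table, co0$subjects, "MD", mode = "none",
                              compute_se = FALSE)
  cc0 <- communality_curve(mf0)
  expect_lt(diff(range(cc0$h_mean)), 1e-10)

  co <- moderated_cohort()
  gm <- co$genmodel
  mf <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant")
  cc <- communality_curve(mf)
  truth <- true_mean_communality(gm, "MD", cc$age)
  expect_lt(max(abs(cc$h_mean - truth)), 0.03)
  # dense curve passes exactly through its anchors
  at <- match(cc$anchors$age, cc$age)
  expect_equal(cc$h_mean[at], cc$anchors$h, tolerance = 1e-10)
  # CI band is ordered and inside [0, 1]
  expect_true(all(cc$lo <= cc$h_mean & cc$h_mean <= cc$hi))
  expect_true(all(cc$lo >= 0 & cc$hi <= 1))
})

test_that("anchor interpolation reproduces anchors and monotone trends", {
  anchors_x <- seq(45, 75, by = 5)
  anchors_y <- c(0.30, 0.35, 0.40, 0.44, 0.47, 0.49, 0.50)
  grid <- seq(45, 75, by = 0.25)
  dense <- interpolate_anchors(anchors_x, anchors_y, grid)
  expect_equal(dense[match(anchors_x, grid)], anchors_y, tolerance = 1e-12)
  expect_true(all(diff(dense) > -1e-9))
})

test_that("communality delta matches the generating difference and flips sign", {
  co <- moderated_cohort()
  gm <- co$genmodel
  mf <- fit_moderated_factor(co$table, co$subjects, "MD", mode = "invariant")
  cd <- communality_delta(mf)
  truth <- 100 * (true_mean_communality(gm, "MD", 75) -
                    true_mean_communality(gm, "MD", 45))
  expect_lt(abs(cd$delta_pp - truth), 3)
  expect_gt(cd$se_pp, 0)
  # negating the loading moderation flips the delta exactly
  neg <- mf
  neg$lambda1p <- -mf$lambda1p
  neg$lambda2p <- 0
  pos <- mf
  pos$lambda2p <- 0
  expect_equal(communality_delta(neg)$delta_pp,
               -communality_delta(pos)$delta_pp, tolerance = 1e-10)
  expect_error(communality_delta(mf, age_lo = 30), "outside")
})

test_that("no-moderation delta is zero", {
  gm0 <- gm_plain("MD")
  co0 <- generate_cohort(gm0, 1500, seed = 73)
  mf0 <- fit_moderated_factor(co0$table, co0$subjects, "MD", mode = "none",
                              compute_se = FALSE)
  expect_equal(communality_delta(mf0)$delta_pp, 0, tolerance = 1e-10)
})

test_that("LOSEM trajectory agrees with the moderated-model oracle", {
  co <- moderated_cohort()
  gm <- co$genmodel
  lo <- fit_losem(co$table, co$subjects, "MD", n_targets = 30)
  inner <- lo$targets >= 48 & lo$targets <= 72 & !lo$skipped
  truth <- true_mean_communality(gm, "MD", lo$targets[inner])
  expect_lt(max(abs(lo$h_mean[inner] - truth)), 0.04)
  expect_true(all(diff(lo$targets) > 0))
  expect_equal(lo$targets[1], 45)
  expect_equal(lo$targets[30], 75)
})

test_that("infinite LOSEM bandwidth reproduces the global fit", {
  gm <- gm_plain("MD")
  co <- generate_cohort(gm, 1200, seed = 74)
  base <- fit_one_factor(co$table, co$subjects, "MD")
  lo <- fit_losem(co$table, co$subjects, "MD", n_targets = 3,
                  bandwidth = 1e6)
  for (ti in 1:3)
    expect_lt(max(abs(lo$loadings[, ti] - base$loadings)), 1e-3)
})

test_that("low effective-n targets are flagged and skipped", {
  gm <- gm_plain("MD")
  co <- generate_cohort(gm, 300, seed = 75, age_dist = "uniform")
  subj <- co$subjects
  subj$age <- pmin(subj$age, 65)    # nobody near the old end
  expect_warning(
    lo <- fit_losem(co$table, subj, "MD", n_targets = 20, min_eff_n = 40),
    "edge targets")
  expect_true(any(lo$skipped))
  expect_true(all(is.na(lo$h[, lo$skipped])))
})
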