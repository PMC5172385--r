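test_that("eigen spectrum basics: identity input and closed-form one-factor share", {
  # uncorrelated tracts: all eigenvalues near 1, weak first factor
  set.seed(51)
  n <- 3000
  ids <- sprintf("S%04d", 1:n)
  tr <- core_tracts()[1:12]
  tab <- data.table::data.table(
    subject_id = rep(ids, times = length(tr)),
    tract = rep(tr, each = n), hemisphere = "left", measure = "MD",
    value = rnorm(n * length(tr)))
  es <- eigen_spectrum(tab, "MD", tracts = tr)
  expect_lt(max(abs(es$eigenvalues - 1)), 0.2)
  expect_true(es$weak_first_factor)
  expect_equal(sum(es$eigenvalues), length(tr), tolerance = 1e-8)

  # one-factor structure: first eigenvalue share matches the eigenvalue of
  # the model-implied correlation matrix (closed-form oracle); covariate
  # effects are zeroed so the raw correlations carry only factor structure
  gm <- gm_plain("MD")
  for (cl in c("alpha1", "alpha2", "alpha3"))
    gm$measures$MD$params[[cl]] <- 0
  co <- generate_cohort(gm, 20000, seed = 52)
  es2 <- eigen_spectrum(co$table, "MD")
  R_true <- stats::cov2cor(implied_covariance(gm, "MD", 60, core_tracts()))
  share_true <- eigen(R_true, symmetric = TRUE,
                      only.values = TRUE)$values[1] / 22
  expect_lt(abs(es2$first_share - share_true), 0.02)
  expect_false(es2$weak_first_factor)
})

test_that("one-factor loadings are recovered from simulated data", {
  co <- default_cohort()
  gm <- co$genmodel
  fit <- fit_one_factor(co$table, co$subjects, "ICVF",
                        resid_pairs = default_resid_pairs()[, c("t1", "t2")])
  p <- gm$measures$ICVF$params
  idx <- match(core_tracts(), p$name)
  lam_true <- p$lambda1[idx] * sqrt(1 - gm$measures$ICVF$gamma^2)
  expect_lt(max(abs(fit$loadings - lam_true)), 0.06)
  expect_lt(max(abs(fit$uniquenesses - p$lambda2[idx])), 0.06)
  expect_equal(fit$variance_explained,
               mean(true_communality(gm, "ICVF", core_tracts(), 60)),
               tolerance = 0.04)
})

test_that("fit agrees with factanal as an independent oracle", {
  co <- default_cohort()
  fit <- fit_one_factor(co$table, co$subjects, "MD")
  W <- metric_wide(co$table, "MD", core_tracts())
  X <- cbind(1, (co$subjects$age - 60) / 7.5, ((co$subjects$age - 60) / 7.5)^2,
             co$subjects$sex)
  E <- qr.resid(qr(X), W)
  fa <- stats::factanal(covmat = stats::cov(E), factors = 1, n.obs = nrow(E))
  expect_lt(max(abs(abs(fit$std_loadings) - abs(fa$loadings[, 1]))), 0.01)
})

test_that("a just-identified 3-tract model has chi-square ~ 0 with df 0", {
  co <- default_cohort()
  fit <- fit_one_factor(co$table, co$subjects, "MD",
                        tracts = c("SLF_L", "ILF_L", "IFOF_L"))
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 0.05)
})

test_that("pruning flags exactly the weak planted tracts", {
  co <- default_cohort()
  all_fit <- fit_one_factor(co$table, co$subjects, "FA",
                            tracts = tract_catalog()$name, on_heywood = "warn")
  expect_setequal(prune_low_loadings(all_fit),
                  c("MCP", "ML_L", "ML_R", "CingPH_L", "CingPH_R"))
  strong <- all_fit
  strong$std_loadings[] <- 0.6
  expect_length(prune_low_loadings(strong), 0)
  expect_length(prune_low_loadings(all_fit, threshold = 0), 0)
})

test_that("residual-covariance search finds a planted homologue pair first", {
  gm <- generating_model(measures = "MD", gamma = c(MD = 0),
                         lambda1p = c(MD = 0),
                         resid_pairs = data.frame(t1 = "CST_L", t2 = "CST_R",
                                                  value = 0.2))
  co <- generate_cohort(gm, 3000, seed = 53)
  base <- fit_one_factor(co$table, co$subjects, "MD")
  aug <- add_residual_covariances(co$table, co$subjects, base, max_pairs = 3)
  expect_gte(nrow(aug$addition_path), 1)
  expect_equal(sort(unlist(aug$addition_path[1, c("t1", "t2")], use.names = FALSE)),
               c("CST_L", "CST_R"))
  expect_lt(aug$neg2ll, base$neg2ll)   # likelihood improves
  # max_pairs = 0 leaves the fit unchanged
  un <- add_residual_covariances(co$table, co$subjects, base, max_pairs = 0)
  expect_equal(un$neg2ll, base$neg2ll)
})

test_that("no residual pairs are added under a clean one-factor truth", {
  added <- vapply(1:5, function(r) {
    gm <- gm_plain("MD")
    co <- generate_cohort(gm, 2000, seed = 530 + r)
    base <- fit_one_factor(co$table, co$subjects, "MD")
    aug <- add_residual_covariances(co$table, co$subjects, base, max_pairs = 2)
    sum(aug$addition_path$accepted)
  }, numeric(1))
  # with 231 candidate pairs at p<0.001 the expected false-addition count is
  # ~0.2 per replicate; most replicates should add nothing
  expect_lt(mean(added), 0.6)
  expect_gte(mean(added == 0), 0.6)
})

test_that("factor scores track the true factor at the implied reliability", {
  gm <- gm_plain("ICVF")
  co <- generate_cohort(gm, 3000, seed = 54)
  fit <- fit_one_factor(co$table, co$subjects, "ICVF")
  sc <- factor_scores(fit)
  g_true <- co$latents$g[match(sc$subject_id, co$subjects$subject_id), "ICVF"]
  rel <- attr(sc, "reliability")
  expect_gte(cor(sc$score, g_true), sqrt(rel) - 0.03)
  expect_lt(abs(mean(sc$score)), 0.05)
  expect_lte(var(sc$score), 1.0)
  # permuted scores decorrelate
  expect_lt(abs(cor(sample(sc$score), g_true)), 0.06)
})

test_that("gTR composite equals the first principal component contract", {
  co <- default_cohort()
  g <- fit_gtr(co$table, "MD")
  units <- c("ATR_L", "ATR_R", "STR_L", "STR_R", "PTR_L", "PTR_R")
  Z <- scale(metric_wide(co$table, "MD", units))
  ev <- eigen(cor(Z), symmetric = TRUE)
  expect_equal(var(g$scores$score), ev$values[1], tolerance = 0.01)
  # symmetric block: loadings uniform
  expect_lt(diff(range(abs(g$loadings))), 0.05)
  # perfectly correlated inputs: component is the z-scored mean
  n <- 500
  ids <- sprintf("P%03d", 1:n)
  x <- rnorm(n)
  tab <- data.table::data.table(
    subject_id = rep(ids, times = 6),
    tract = rep(units, each = n),
    hemisphere = rep(rep(c("left", "right"), 3), each = n),
    measure = "FA", value = rep(x, times = 6))
  g2 <- fit_gtr(tab, "FA")
  expect_equal(cor(g2$scores$score, x), 1, tolerance = 1e-10)
  expect_equal(g2$var_share, 1, tolerance = 1e-10)
})

test_that("fitting data simulated from its own estimates is self-consistent", {
  co <- default_cohort()
  fit <- fit_one_factor(co$table, co$subjects, "MD")
  # simulate directly from the fitted covariance structure
  set.seed(55)
  n <- 10000
  Y <- matrix(rnorm(n), n, 1) %*% t(fit$loadings) +
    matrix(rnorm(n * 22), n, 22) %*% diag(fit$uniquenesses)
  colnames(Y) <- fit$tracts
  ids <- sprintf("Q%05d", 1:n)
  rownames(Y) <- ids
  tab <- data.table::as.data.table(as.table(Y))
  names(tab) <- c("subject_id", "tract", "value")
  tab$hemisphere <- "left"; tab$measure <- "MD"
  subj <- data.frame(subject_id = ids, age = runif(n, 45, 77),
                     sex = rbinom(n, 1, 0.5))
  refit <- fit_one_factor(tab, subj, "MD")
  expect_lt(max(abs(refit$loadings - fit$loadings)), 0.04)
  expect_lt(max(abs(refit$uniquenesses - fit$uniquenesses)), 0.04)
})
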