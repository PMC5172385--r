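test_that("per-tract regression recovers a planted standardized age slope", {
  # bespoke single-tract data: y = -0.3*A + e with unit total variance
  set.seed(21)
  n <- 3500
  age <- runif(n, 44.64, 77.12)
  A <- scale(age)
  y <- -0.3 * A + sqrt(1 - 0.09) * rnorm(n)
  tab <- data.table::data.table(subject_id = sprintf("S%04d", 1:n),
                                tract = "FMin", hemisphere = "midline",
                                measure = "FA", value = as.vector(y))
  subj <- data.frame(subject_id = sprintf("S%04d", 1:n), age = age,
                     sex = rbinom(n, 1, 0.5))
  fit <- fit_tract_regression(tab, subj, "FMin", "FA")
  b_age <- fit$coefficients$beta[fit$coefficients$term == "age"]
  expect_lt(abs(b_age - (-0.3)), 0.05)
  expect_true(fit$midline)
  expect_false("hemi" %in% fit$coefficients$term)
})

test_that("bivariate standardized beta equals the Pearson correlation", {
  set.seed(22)
  n <- 400
  age <- runif(n, 45, 77)
  y <- 0.2 * age / 10 + rnorm(n)
  tab <- data.table::data.table(subject_id = sprintf("S%04d", 1:n),
                                tract = "FMaj", hemisphere = "midline",
                                measure = "MD", value = y)
  subj <- data.frame(subject_id = sprintf("S%04d", 1:n), age = age,
                     sex = rbinom(n, 1, 0.5))
  fit <- fit_tract_regression(tab, subj, "FMaj", "MD", terms = "age")
  b <- fit$coefficients$beta[fit$coefficients$term == "age"]
  expect_equal(b, cor(age, y), tolerance = 1e-10)
})

test_that("permutation null yields no spurious large effects", {
  set.seed(23)
  n <- 3500
  subj <- data.frame(subject_id = sprintf("S%04d", 1:n),
                     age = runif(n, 45, 77), sex = rbinom(n, 1, 0.5))
  n_rep <- 200
  max_beta <- numeric(n_rep); any_sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- data.table::data.table(subject_id = sprintf("S%04d", 1:n),
                                  tract = "FMin", hemisphere = "midline",
                                  measure = "FA", value = rnorm(n))
    fit <- fit_tract_regression(tab, subj, "FMin", "FA")
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    max_beta[r] <- max(abs(cf$beta[cf$term %in% c("age", "I(age^2)")]))
    any_sig[r] <- any(cf$significant)
  }
  expect_gte(mean(max_beta < 0.05 & !any_sig), 0.95)
})

test_that("quadratic form is selected at ~5% under a linear truth", {
  set.seed(24)
  n <- 3500
  subj <- data.frame(subject_id = sprintf("S%04d", 1:n),
                     age = runif(n, 45, 77), sex = rbinom(n, 1, 0.5))
  A <- as.vector(scale(subj$age))
  n_rep <- 200
  quad <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- data.table::data.table(subject_id = subj$subject_id,
                                  tract = "FMin", hemisphere = "midline",
                                  measure = "MD",
                                  value = 0.3 * A + rnorm(n))
    quad[r] <- fit_tract_regression(tab, subj, "FMin", "MD")$model_form ==
      "quadratic"
  }
  expect_lt(mean(quad), 0.10)   # binomial 99% bound around 0.05 at 200 reps
  expect_gt(mean(quad), 0.005)
})

test_that("strong curvature is detected and beta reported from the quadratic fit", {
  set.seed(25)
  n <- 3500
  subj <- data.frame(subject_id = sprintf("S%04d", 1:n),
                     age = runif(n, 45, 77), sex = rbinom(n, 1, 0.5))
  A <- as.vector(scale(subj$age))
  hits <- vapply(1:20, function(r) {
    tab <- data.table::data.table(subject_id = subj$subject_id,
                                  tract = "FMin", hemisphere = "midline",
                                  measure = "MD",
                                  value = 0.3 * A + 0.15 * A^2 + rnorm(n))
    fit_tract_regression(tab, subj, "FMin", "MD")$model_form == "quadratic"
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("linear/quadratic comparison honours nesting and the 0.05 rule", {
  set.seed(26)
  d <- data.frame(y = rnorm(300), age = rnorm(300))
  f1 <- lm(y ~ age, d)
  expect_equal(compare_linear_quadratic(f1, f1), "linear")
  f2 <- lm(y ~ age + I(age^2), d)
  p <- anova(f1, f2)$`Pr(>F)`[2]
  expect_equal(compare_linear_quadratic(f1, f2),
               if (p < 0.05) "quadratic" else "linear")
  f_other <- lm(y ~ age, d[1:200, ])
  expect_error(compare_linear_quadratic(f_other, f2), "nested")
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(27)
  n <- 200
  subj <- data.frame(subject_id = sprintf("S%04d", 1:n),
                     age = runif(n, 45, 77),
                     sex = 1)                # constant sex -> age:sex aliased
  tab <- data.table::data.table(subject_id = subj$subject_id,
                                tract = "FMin", hemisphere = "midline",
                                measure = "FA", value = rnorm(n))
  expect_error(suppressWarnings(fit_tract_regression(tab, subj, "FMin", "FA")),
               "collinear")
})

test_that("bilateral tracts are fitted on stacked rows with a hemisphere term", {
  co <- default_cohort()
  fit <- fit_tract_regression(co$table, co$subjects, "SLF", "FA")
  expect_true("hemi" %in% fit$coefficients$term)
  expect_equal(fit$n, 2L * nrow(co$subjects))
  # hemisphere offset is planted negative for FA (right lower)
  b_h <- fit$coefficients$beta[fit$coefficients$term == "hemi"]
  expect_lt(b_h, -0.1)
})
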