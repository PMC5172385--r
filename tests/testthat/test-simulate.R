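test_that("seeded generation is exactly reproducible", {
  gm <- gm_plain("MD")
  a <- generate_cohort(gm, 200, seed = 5)
  b <- generate_cohort(gm, 200, seed = 5)
  expect_identical(a$table, b$table)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$volumetrics, b$volumetrics)
  c2 <- generate_cohort(gm, 200, seed = 6)
  expect_false(identical(a$table$value, c2$table$value))
})

test_that("exclusion cascade with the printed flag counts retains 3,513", {
  gm <- generating_model(measures = "MD")
  co <- generate_cohort(gm, 5455, seed = 1)
  casc <- apply_exclusion_cascade(co$subjects)
  expect_equal(unname(casc$counts),
               c(567L, 1314L, 59L, 2L, 3513L))
  expect_equal(nrow(casc$retained), 3513L)
  expect_equal(sum(casc$counts[1:4]) + casc$counts[["retained"]], 5455L)
})

test_that("cascade identity and empty edge cases", {
  subj <- data.frame(subject_id = c("a", "b"),
                     early_phase_flag = FALSE, qc_fail_flag = FALSE,
                     neuro_diagnosis_flag = FALSE, outlier_flag = FALSE)
  casc <- apply_exclusion_cascade(subj)
  expect_equal(casc$retained, subj)
  expect_equal(unname(casc$counts), c(0L, 0L, 0L, 0L, 2L))
  subj$early_phase_flag <- TRUE
  casc2 <- apply_exclusion_cascade(subj)
  expect_equal(unname(casc2$counts), c(2L, 0L, 0L, 0L, 0L))
})

test_that("cascade counts are order-dependent for overlapping flags", {
  subj <- data.frame(subject_id = "a",
                     early_phase_flag = TRUE, qc_fail_flag = TRUE,
                     neuro_diagnosis_flag = FALSE, outlier_flag = FALSE)
  casc <- apply_exclusion_cascade(subj)
  # counted at the first removing stage only
  expect_equal(unname(casc$counts[1:2]), c(1L, 0L))
})

test_that("sample moments match the implied covariance at fixed ages", {
  gm <- gm_plain("MD", lambda1p = 0.013)
  co <- generate_cohort(gm, 24000, seed = 7, age_dist = "uniform")
  W <- metric_wide(co$table, "MD", core_tracts())
  age <- co$subjects$age
  for (age0 in c(48, 60, 72)) {
    sel <- abs(age - age0) < 1.5
    X <- cbind(1, (age[sel] - 60) / 7.5, ((age[sel] - 60) / 7.5)^2,
               co$subjects$sex[sel])
    E <- qr.resid(qr(X), W[sel, ])
    S_hat <- crossprod(E) / nrow(E)
    S_true <- implied_covariance(gm, "MD", age0, core_tracts())
    expect_lt(max(abs(S_hat - S_true)), 0.12)   # ~1200 subjects per slice
    expect_gt(min(eigen(S_hat, only.values = TRUE, symmetric = TRUE)$values), 0)
  }
})

test_that("large-sample communality matches lambda1^2/(lambda1^2+lambda2^2)", {
  gm <- gm_plain("MD")
  co <- generate_cohort(gm, 20000, seed = 2)
  W <- metric_wide(co$table, "MD", core_tracts())
  X <- cbind(1, (co$subjects$age - 60) / 7.5, co$subjects$sex)
  E <- qr.resid(qr(X), W)
  r2 <- as.vector(cor(E, co$latents$g[, "MD"])^2)
  h <- unname(true_communality(gm, "MD", core_tracts(), 60))
  expect_lt(max(abs(r2 - h)), 0.03)
})

test_that("configurable MCAR missingness is honoured", {
  gm <- generating_model(measures = "MD", missing_rate = 0.05,
                         resid_pairs = NULL)
  co <- generate_cohort(gm, 1000, seed = 3)
  rate <- mean(is.na(co$table$value))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("ages stay inside the supported range under both distributions", {
  gm <- gm_plain("MD")
  for (dist in c("groups", "uniform")) {
    co <- generate_cohort(gm, 500, seed = 4, age_dist = dist)
    expect_gte(min(co$subjects$age), 44.64)
    expect_lte(max(co$subjects$age), 77.12)
  }
})
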