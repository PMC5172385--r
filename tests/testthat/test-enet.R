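# candidate matrix with 3 informative and 7 noise predictors
sim_candidates <- function(n, seed, effects = c(0.3, 0.25, 0.2)) {
  set.seed(seed)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  y <- X[, 1:3] %*% effects + rnorm(n) * 0.85
  list(X = X, y = as.vector(y))
}

test_that("true predictors are selected and noise excluded", {
  d <- sim_candidates(3512, seed = 91)
  sel <- bootstrap_enet_select(d$X, d$y, n_boot = 150, split_seed = 1)
  expect_setequal(sel$selected, c("p1", "p2", "p3"))
  expect_true(all(sel$frequency[c("p1", "p2", "p3")] > 0.6))
  expect_true(all(sel$frequency[paste0("p", 4:10)] < 0.6))
  # halves are disjoint and exhaustive
  expect_length(intersect(sel$train_idx, sel$test_idx), 0)
  expect_setequal(c(sel$train_idx, sel$test_idx), seq_len(3512))
})

test_that("selection is reproducible under the same seeds", {
  d <- sim_candidates(800, seed = 92)
  s1 <- bootstrap_enet_select(d$X, d$y, n_boot = 40, split_seed = 5)
  s2 <- bootstrap_enet_select(d$X, d$y, n_boot = 40, split_seed = 5)
  expect_identical(s1$frequency, s2$frequency)
  expect_identical(s1$train_idx, s2$train_idx)
})

test_that("single-resample frequencies are 0 or 1", {
  d <- sim_candidates(400, seed = 93)
  sel <- suppressWarnings(
    bootstrap_enet_select(d$X, d$y, n_boot = 1, split_seed = 2))
  expect_true(all(sel$frequency %in% c(0, 1)))
})

test_that("a duplicated predictor is co-selected and flagged by VIF", {
  d <- sim_candidates(2000, seed = 94)
  X2 <- cbind(d$X, p1_copy = d$X[, 1] + rnorm(2000) * 0.05)
  sel <- bootstrap_enet_select(X2, d$y, n_boot = 100, split_seed = 3)
  # the grouping property keeps the pair's combined frequency high
  expect_gt(sel$frequency["p1"] + sel$frequency["p1_copy"], 0.8)
  cf <- confirm_train_test(c("p1", "p1_copy", "p2"), X2, d$y,
                           sel$train_idx, sel$test_idx)
  expect_gt(max(cf$vif), 10)
})

test_that("confirmatory halves agree and a forced noise predictor stays null", {
  d <- sim_candidates(3000, seed = 95)
  sel <- bootstrap_enet_select(d$X, d$y, n_boot = 60, split_seed = 4)
  cf <- confirm_train_test(c(sel$selected, "p9"), d$X, d$y,
                           sel$train_idx, sel$test_idx)
  expect_lt(abs(cf$r_squared["train"] - cf$r_squared["test"]), 0.06)
  # generating R^2 = 0.1925 / (0.1925 + 0.85^2)
  r2_true <- 0.1925 / (0.1925 + 0.7225)
  expect_lt(abs(cf$r_squared["train"] - r2_true), 0.05)
  p9_test <- cf$test[cf$test$term == "p9", ]
  expect_gt(p9_test$p, 0.001)
  expect_true(all(cf$vif < 1.2))
  # identical halves give identical coefficients
  cf_same <- confirm_train_test(sel$selected, d$X, d$y,
                                sel$train_idx, sel$train_idx)
  expect_equal(cf_same$train$beta, cf_same$test$beta)
})

test_that("thalamus increment behaves under orthogonal and nested signals", {
  set.seed(96)
  n <- 2000
  thal <- rnorm(n); gtr <- rnorm(n)              # orthogonal predictors
  age <- 0.4 * thal + 0.3 * gtr + rnorm(n) * sqrt(1 - 0.25)
  ti <- thalamus_increment(thal, gtr, rnorm(n), age)
  r2_joint <- ti$r_squared["base"]
  expect_lt(abs(r2_joint - (cor(age, thal)^2 + cor(age, gtr)^2)), 0.02)
  # TBV constructed to contain thal's age signal shrinks the thal beta
  tbv <- thal + rnorm(n) * 0.2
  ti2 <- thalamus_increment(thal, gtr, tbv, age)
  b_thal_base <- ti2$base$beta[ti2$base$term == "thal"]
  b_thal_tbv <- ti2$with_tbv$beta[ti2$with_tbv$term == "thal"]
  expect_lt(abs(b_thal_tbv), abs(b_thal_base))
  # age-independent predictors explain ~nothing
  ti3 <- thalamus_increment(rnorm(n), rnorm(n), rnorm(n), age)
  expect_lt(ti3$r_squared["base"], 0.01)
})
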