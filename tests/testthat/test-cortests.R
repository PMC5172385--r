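test_that("Williams's t is zero under equal correlations and antisymmetric", {
  w <- williams_t(0.4, 0.4, 0.2, 100)
  expect_identical(w$t, 0)
  expect_equal(w$p, 1)
  expect_equal(w$df, 97)
  a <- williams_t(0.5, 0.3, 0.6, 100)
  b <- williams_t(0.3, 0.5, 0.6, 100)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("Williams's t matches an independently coded reference formula", {
  # independently written arrangement of Williams (1959) via Hotelling's
  # determinant form
  ref <- function(rja, rka, rjk, n) {
    R <- matrix(c(1, rjk, rja,
                  rjk, 1, rka,
                  rja, rka, 1), 3, 3)
    detR <- det(R)
    rb <- mean(c(rja, rka))
    (rja - rka) * sqrt(((n - 1) * (1 + rjk)) /
      (2 * detR * (n - 1) / (n - 3) + rb^2 * (1 - rjk)^3))
  }
  cases <- list(c(0.5, 0.3, 0.6, 100), c(-0.2, 0.4, 0.1, 50),
                c(0.7, 0.65, 0.8, 1000), c(0.1, -0.1, 0, 20))
  for (cs in cases) {
    expect_equal(williams_t(cs[1], cs[2], cs[3], cs[4])$t,
                 ref(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-6)
  }
})

test_that("Williams's t rejects invalid inputs", {
  expect_error(williams_t(1, 0.5, 0.2, 10), "strictly inside")
  expect_error(williams_t(0.2, 0.5, 0.2, 3), "exceed 3")
})

test_that("detectable effect reproduces the printed study values", {
  expect_equal(detectable_effect(1000, 0.05, 0.80), 0.088)
  expect_equal(detectable_effect(3513, 0.05, 0.80), 0.047)
  expect_equal(detectable_effect(1000, 0.05, 0.80, method = "fisher-z"), 0.088)
  expect_equal(detectable_effect(3513, 0.05, 0.80, method = "fisher-z"), 0.047)
})

test_that("detectable effect at power one-half approaches the z-test limit", {
  for (n in c(200, 1000, 5000)) {
    r <- detectable_effect(n, 0.05, 0.50, method = "fisher-z", digits = NULL)
    expect_lt(abs(r - qnorm(0.975) / sqrt(n - 3)), 2e-3)
  }
})

test_that("detectable effect is strictly decreasing in n and alpha", {
  ns <- c(100, 500, 1000, 3513, 10000)
  rs <- vapply(ns, function(n) detectable_effect(n, digits = NULL), numeric(1))
  expect_true(all(diff(rs) < 0))
  alphas <- c(0.001, 0.01, 0.05, 0.1)
  ra <- vapply(alphas, function(a)
    detectable_effect(1000, alpha = a, digits = NULL), numeric(1))
  expect_true(all(diff(ra) < 0))
  expect_error(detectable_effect(3), "n > 3")
})

test_that("Williams's t holds its type-I error under a trivariate normal null", {
  # equal population correlations with the shared variable
  rho_ja <- 0.4; rho_ka <- 0.4; rho_jk <- 0.3
  C <- matrix(c(1, rho_jk, rho_ja,
                rho_jk, 1, rho_ka,
                rho_ja, rho_ka, 1), 3, 3)
  ch <- chol(C)
  n <- 500; n_draws <- 4000
  set.seed(31)
  rej <- logical(n_draws)
  chunk <- 2000
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    Z <- array(rnorm(m * n * 3), c(m * n, 3)) %*% ch
    dim(Z) <- c(m, n, 3)
    cs <- function(i, j) {
      xi <- Z[, , i]; xj <- Z[, , j]
      sxi <- rowSums(xi); sxj <- rowSums(xj)
      num <- rowSums(xi * xj) - sxi * sxj / n
      den <- sqrt((rowSums(xi^2) - sxi^2 / n) * (rowSums(xj^2) - sxj^2 / n))
      num / den
    }
    r_ja <- cs(1, 3); r_ka <- cs(2, 3); r_jk <- cs(1, 2)
    for (b in seq_len(m)) {
      rej[done + b] <- williams_t(r_ja[b], r_ka[b], r_jk[b], n)$p < 0.05
    }
    done <- done + m
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})
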