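# Shared synthetic fixtures, generated in code and cached per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# single-measure model with no factor-age slope and no residual pairs:
# the setting in which the closed-form communality oracle is exact
gm_plain <- function(measure = "MD", lambda1p = 0, lambda2p = 0) {
  l1 <- stats::setNames(lambda1p, measure)
  l2 <- stats::setNames(lambda2p, measure)
  g0 <- stats::setNames(0, measure)
  generating_model(measures = measure, lambda1p = l1, lambda2p = l2,
                   gamma = g0, resid_pairs = NULL)
}

# moderately sized default cohort shared across read-only tests
default_cohort <- function() {
  fixture("default_cohort", function() {
    exclude_cohort(generate_cohort(generating_model(), 5455, seed = 101))
  })
}

# n=3500 cohort from the plain MD model with loading moderation 0.013/yr
moderated_cohort <- function() {
  fixture("moderated_cohort", function() {
    generate_cohort(gm_plain("MD", lambda1p = 0.013), 3500, seed = 202)
  })
}
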