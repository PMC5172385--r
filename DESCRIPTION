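Package: dediffwm
Title: Age De-Differentiation of Brain White-Matter Microstructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying age effects on tract-averaged diffusion MRI
    phenotypes (FA, MD and NODDI measures) in middle-aged and older cohorts:
    a synthetic cohort generator with known latent structure; per-tract
    age/sex/hemisphere regressions with linear-versus-quadratic comparison;
    Williams's t for dependent overlapping correlations and power utilities;
    maximum-likelihood one-factor models with loading pruning, residual
    covariances, factor scores and common/independent pathway comparisons;
    moderated nonlinear factor models in which age moderates loadings and
    unique variances, communality-versus-age trajectories, and a
    kernel-weighted local structural equation modelling confirmation;
    multiple-mediator decomposition of the age-gFA association; and
    bootstrapped elastic-net selection of brain predictors of age.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
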