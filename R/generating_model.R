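#' Ground-truth generating model for synthetic cohorts
#'
#' Builds the parameter set that [generate_cohort()] samples from and that
#' recovery tests treat as ground truth. For each diffusion measure and each
#' of the 27 tract units the model holds an intercept, age / age-squared /
#' sex regression slopes, a loading on the measure's general factor, a
#' unique-factor loading, and tract-invariant age-moderation slopes for the
#' general and unique loadings. The sampled value for subject *n*, tract *t* is
#'
#' \deqn{y = \nu_t + \alpha_{1t} A + \alpha_{2t} A^2 + \alpha_{3t}\,sex
#'   + \lambda_{1t}(1 + \lambda_1' a)\, g + \lambda_{2t}(1 + \lambda_2' a)\, u_t
#'   + \mathrm{hemi} + \mathrm{pair\ terms}}
#'
#' where `A` is age standardized by `age_scale`, `a` is age centered at
#' `age_center` in years (the moderation metric), `g` and `u_t` are
#' standard-normal latent draws, and pair terms add residual covariance
#' between listed tract pairs. The general factor is tied to age as
#' `g = gamma * A + sqrt(1 - gamma^2) * zeta`, so it is marginally standard
#' normal while carrying an age association of size `gamma`; conditional on
#' age its variance is `1 - gamma^2`, which [true_communality()] accounts for.
#'
#' Default parameters are calibrated so that, at the centering age, a
#' one-factor model explains about 41% of tract variance for FA, 38% for MD,
#' 68% for ICVF, 31% for ISOVF and 20% for OD, and so that the mean
#' communality rises from age 45 to 75 by about 11.5, 18.1, 7.2 and 12.9
#' percentage points (FA, MD, ICVF, ISOVF) and is flat for OD. The FA factor
#' is built structurally from the ICVF and OD factors plus a direct age path,
#' so that about three quarters of the age-FA association is mediated by the
#' two NODDI factors.
#'
#' @param measures Character vector of measure labels to generate (subset of
#'   the defaults is allowed; extra labels reuse MD-like settings).
#' @param lambda1p,lambda2p Optional named numeric overrides of the
#'   loading / uniqueness moderation slopes (per centered year).
#' @param gamma Optional named numeric overrides of the factor-age slopes.
#' @param resid_pairs Data frame with columns `t1`, `t2`, `value` giving
#'   residual covariances added between tract units (same pairs reused for
#'   every measure), or `NULL` for none.
#' @param missing_rate Per-cell MCAR missingness rate (default 0).
#' @param flag_counts Integer vector of exclusion-flag counts at the
#'   reference raw size `n_ref` (early scanning phase, diffusion QC failure,
#'   neurological diagnosis, extreme outlier), applied disjointly.
#' @param n_ref Reference raw cohort size for `flag_counts`.
#' @param age_center,age_scale Centering (years) for moderation and scale
#'   (years) for the standardized-age regression metric.
#' @return An object of class `dediff_genmodel`.
#' @seealso [generate_cohort()], [true_communality()]
#' @export
generating_model <- function(measures = c("FA", "MD", "ICVF", "ISOVF", "OD"),
                             lambda1p = NULL, lambda2p = NULL, gamma = NULL,
                             resid_pairs = default_resid_pairs(),
                             missing_rate = 0,
                             flag_counts = c(early_phase = 567L, qc_fail = 1314L,
                                             neuro_diagnosis = 59L, outlier = 2L),
                             n_ref = 5455L,
                             age_center = 60, age_scale = 7.5) {
  cat27 <- tract_catalog()

  ## per-measure calibration anchors (conditional communality at the
  ## centering age, moderation slope per centered year, factor-age slope,
  ## intercept level, hemisphere offset for right-side units, sex effect)
  defaults <- list(
    FA    = list(h0 = 0.414, l1p =  0.008074, gam = NA,     nu = 0.45,
                 hemi = -0.35, sex = 0.15, a2 = 0.00,
                 beta = c(association = -0.26, thalamic_radiation = -0.24,
                          projection = -0.05, callosal = -0.15)),
    MD    = list(h0 = 0.381, l1p =  0.013141, gam =  0.368, nu = 0.75,
                 hemi = 0.12, sex = -0.05, a2 = 0.06,
                 beta = c(association = 0.45, thalamic_radiation = 0.47,
                          projection = 0.10, callosal = 0.25)),
    ICVF  = list(h0 = 0.682, l1p =  0.005638, gam = -0.265, nu = 0.55,
                 hemi = 0.05, sex = 0.05, a2 = -0.05,
                 beta = c(association = -0.35, thalamic_radiation = -0.33,
                          projection = -0.08, callosal = -0.20)),
    ISOVF = list(h0 = 0.308, l1p =  0.010375, gam =  0.273, nu = 0.20,
                 hemi = 0.20, sex = -0.05, a2 = 0.05,
                 beta = c(association = 0.30, thalamic_radiation = 0.32,
                          projection = 0.10, callosal = 0.20)),
    OD    = list(h0 = 0.201, l1p = -0.000732, gam = -0.120, nu = 0.35,
                 hemi = 0.05, sex = -0.18, a2 = -0.06,
                 beta = c(association = -0.20, thalamic_radiation = -0.15,
                          projection = 0.05, callosal = -0.10))
  )
  ## structural definition of the FA factor: direct age path plus paths from
  ## the ICVF and OD factors (the mediation ground truth)
  fa_structure <- list(c_prime = -0.060, b = c(ICVF = 0.65, OD = 0.12))

  ## centered per-category communality offsets (core tracts)
  h_offset <- c(association = 0.0318, thalamic_radiation = 0.0518,
                projection = -0.1382, callosal = -0.0382)
  weak_h <- 0.03   # non-core tracts: standardized loading ~0.17 (< 0.3)

  meas <- list()
  for (m in measures) {
    d <- if (m %in% names(defaults)) defaults[[m]] else defaults[["MD"]]
    gam <- d$gam
    if (!is.null(gamma) && m %in% names(gamma)) gam <- gamma[[m]]
    l1p <- d$l1p
    if (!is.null(lambda1p) && m %in% names(lambda1p)) l1p <- lambda1p[[m]]
    l2p <- 0
    if (!is.null(lambda2p) && m %in% names(lambda2p)) l2p <- lambda2p[[m]]

    h <- ifelse(cat27$core_factor_member,
                pmin(pmax(d$h0 + h_offset[cat27$category], 0.02), 0.95),
                weak_h)
    gam_eff <- if (m == "FA" && is.na(gam)) {
      # implied total age correlation of the structural FA factor
      NA_real_
    } else gam
    params <- data.frame(
      name = cat27$name, category = cat27$category,
      laterality = cat27$laterality, core = cat27$core_factor_member,
      nu = d$nu + 0.01 * (seq_len(27) - 14),
      alpha2 = d$a2, alpha3 = d$sex,
      stringsAsFactors = FALSE
    )
    # lambda1 chosen so the age-conditional shared variance is h (the
    # conditional factor variance 1 - gamma^2 is divided back out)
    meas[[m]] <- list(params = params, h = h, lambda1p = l1p, lambda2p = l2p,
                      gamma = gam_eff, hemi_offset = d$hemi,
                      beta_target = d$beta)
  }

  gm <- structure(list(
    catalog = cat27, measures = meas, fa_structure = fa_structure,
    zeta_corr = 0.25,           # residual correlation among non-FA factors
    resid_pairs = resid_pairs, missing_rate = missing_rate,
    flag_counts = flag_counts, n_ref = as.integer(n_ref),
    age_center = age_center, age_scale = age_scale,
    age_range = c(44.64, 77.12),
    age_groups = data.frame(
      lo = c(44.64, 50.05, 55.00, 60.01, 65.00, 70.00),
      hi = c(49.98, 54.99, 60.00, 65.00, 70.00, 77.12),
      n  = c(290, 505, 559, 800, 876, 483)),
    volumetrics = data.frame(
      name = c("total_brain", "grey_matter", "white_matter",
               "hippocampus", "thalamus"),
      age_slope = c(-0.55, -0.60, -0.35, -0.30, -0.50),
      atrophy_loading = c(0.80, 0.70, 0.70, 0.40, 0.60),
      stringsAsFactors = FALSE)
  ), class = "dediff_genmodel")
  gm <- .finalize_genmodel(gm)
  validate_generating_model(gm)
  gm
}

# Resolve the FA structural factor and convert communality targets into
# lambda1 / lambda2 loadings on each measure's parameter table.
.finalize_genmodel <- function(gm) {
  # correlations among the age-independent parts (zeta) of the non-FA factors
  for (m in names(gm$measures)) {
    mm <- gm$measures[[m]]
    if (m == "FA" && is.na(mm$gamma)) {
      st <- gm$fa_structure
      need <- names(st$b)
      if (all(need %in% names(gm$measures))) {
        gI <- gm$measures[["ICVF"]]$gamma
        gO <- gm$measures[["OD"]]$gamma
        # total age correlation of the FA factor
        mm$gamma <- st$c_prime + st$b[["ICVF"]] * gI + st$b[["OD"]] * gO
        mm$structural <- TRUE
      } else {
        mm$gamma <- -0.247
        mm$structural <- FALSE
      }
    } else {
      mm$structural <- FALSE
      if (is.na(mm$gamma)) mm$gamma <- 0
    }
    cond <- 1 - mm$gamma^2
    if (cond <= 0) stop("factor-age slope must satisfy |gamma| < 1")
    mm$params$lambda1 <- sqrt(mm$h / cond)
    mm$params$lambda2 <- sqrt(1 - mm$h)
    # tract age slope = category target minus the factor-mediated part
    tgt <- mm$beta_target[mm$params$category]
    mm$params$alpha1 <- as.numeric(tgt) - mm$params$lambda1 * mm$gamma
    gm$measures[[m]] <- mm
  }
  gm
}

#' Default residual-covariance pairs
#'
#' Left-right homologue pairs given residual covariance beyond the general
#' factor, mimicking the bilateral dependence seen in tract data.
#' @return Data frame with columns `t1`, `t2`, `value`.
#' @export
default_resid_pairs <- function() {
  data.frame(t1 = c("CST_L", "CingG_L", "SLF_L"),
             t2 = c("CST_R", "CingG_R", "SLF_R"),
             value = c(0.15, 0.12, 0.10), stringsAsFactors = FALSE)
}

#' Model-implied age-conditional covariance
#'
#' Covariance of the tract units for one measure, conditional on age and sex,
#' at a given age: `S(a) = (1-gamma^2) w(a)^2 L L' + diag(l2^2 v(a)^2) + R`
#' with `w(a) = 1 + lambda1' a` and `v(a) = 1 + lambda2' a` (`a` centered).
#'
#' @param gm A `dediff_genmodel`.
#' @param measure Measure label.
#' @param age Age in years.
#' @param tracts Optional subset of tract unit names (default: all 27).
#' @return Covariance matrix with dimnames.
#' @export
implied_covariance <- function(gm, measure, age, tracts = NULL) {
  mm <- gm$measures[[measure]]
  if (is.null(mm)) stop("unknown measure: ", measure)
  p <- mm$params
  if (!is.null(tracts)) p <- p[match(tracts, p$name), ]
  a <- age - gm$age_center
  w <- 1 + mm$lambda1p * a
  v <- 1 + mm$lambda2p * a
  l1 <- p$lambda1 * w * sqrt(1 - mm$gamma^2)
  l2 <- p$lambda2 * v
  S <- tcrossprod(l1) + diag(l2^2, nrow(p))
  dimnames(S) <- list(p$name, p$name)
  if (!is.null(gm$resid_pairs) && nrow(gm$resid_pairs)) {
    for (i in seq_len(nrow(gm$resid_pairs))) {
      t1 <- gm$resid_pairs$t1[i]; t2 <- gm$resid_pairs$t2[i]
      if (t1 %in% rownames(S) && t2 %in% rownames(S)) {
        # correlated unique factors: covariance only, no extra variance
        r <- gm$resid_pairs$value[i] * v^2
        S[t1, t2] <- S[t1, t2] + r
        S[t2, t1] <- S[t2, t1] + r
      }
    }
  }
  S
}

#' Validate a generating model
#'
#' Checks that unique loadings stay positive and the implied covariance is
#' positive definite at every age on a 0.5-year grid spanning 44-78 years.
#' @param gm A `dediff_genmodel`.
#' @return Invisibly `TRUE`; errors naming the offending age otherwise.
#' @export
validate_generating_model <- function(gm) {
  ages <- seq(44, 78, by = 0.5)
  for (m in names(gm$measures)) {
    mm <- gm$measures[[m]]
    a <- ages - gm$age_center
    if (any(1 + mm$lambda2p * a <= 0))
      stop("unique-loading moderation collapses (1 + lambda2'*a <= 0) for ",
           m, " at age ", ages[which(1 + mm$lambda2p * a <= 0)[1]])
    for (ag in ages) {
      S <- implied_covariance(gm, m, ag)
      ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 0)
        stop("implied covariance for ", m, " is not positive definite at age ",
             ag, " (min eigenvalue ", signif(ev, 3), ")")
    }
  }
  invisible(TRUE)
}

#' Ground-truth communality at a given age
#'
#' The proportion of a tract's age-conditional variance explained by the
#' general factor: `s/(s+u)` with `s = (1-gamma^2) (lambda1 (1+lambda1' a))^2`
#' and `u = (lambda2 (1+lambda2' a))^2`, `a` in centered years. Residual
#' pair covariance is excluded from the total, matching the bookkeeping of
#' the fitted models. With no factor-age slope (`gamma = 0`) this is exactly
#' `lambda1^2(1+lambda1'a)^2 / (lambda1^2(1+lambda1'a)^2 + lambda2^2(1+lambda2'a)^2)`.
#'
#' @param gm A `dediff_genmodel`.
#' @param measure Measure label.
#' @param tract Tract unit name (or vector); `NULL` for all 27.
#' @param age Age(s) in years, inside the supported range.
#' @return If one tract: numeric vector along `age`. Otherwise a matrix
#'   (tracts x ages).
#' @export
true_communality <- function(gm, measure, tract = NULL, age) {
  mm <- gm$measures[[measure]]
  if (is.null(mm)) stop("unknown measure: ", measure)
  p <- mm$params
  if (!is.null(tract)) p <- p[match(tract, p$name), ]
  a <- age - gm$age_center
  w2 <- (1 + mm$lambda1p * outer(rep(1, nrow(p)), a))^2
  v2 <- (1 + mm$lambda2p * outer(rep(1, nrow(p)), a))^2
  s <- (1 - mm$gamma^2) * p$lambda1^2 * w2
  u <- p$lambda2^2 * v2
  if (any(s + u == 0)) stop("degenerate tract with zero total variance")
  h <- s / (s + u)
  rownames(h) <- p$name
  colnames(h) <- as.character(age)
  if (length(p$name) == 1L) drop(h) else h
}

#' Mean ground-truth communality over the core tracts
#'
#' @inheritParams true_communality
#' @return Numeric vector along `age`.
#' @export
true_mean_communality <- function(gm, measure, age) {
  h <- true_communality(gm, measure, tract = core_tracts(), age = age)
  if (is.matrix(h)) colMeans(h) else mean(h)
}
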