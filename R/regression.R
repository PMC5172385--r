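#' Per-tract regression of a diffusion measure on age, sex and hemisphere
#'
#' Multiple regression of one tract's measure values on standardized age,
#' sex (0 = female), an age-by-sex interaction and, for bilateral tracts, a
#' hemisphere indicator (0 = left) fitted on the stacked left+right rows.
#' The outcome and age are z-scored on the rows used, so continuous
#' coefficients are standardized betas while binary predictors stay on the
#' outcome-SD scale. Both the linear and the quadratic (added age-squared
#' term) forms are fitted; the quadratic form is reported only when it
#' improves fit at p < 0.05 (see [compare_linear_quadratic()]). Effects are
#' flagged significant at p < 0.001.
#'
#' @param table Tidy metric table.
#' @param subjects Covariate data frame (`subject_id`, `age`, `sex`).
#' @param tract Base tract name (e.g. `"SLF"`, stacking `SLF_L`/`SLF_R`) or
#'   a single unit name.
#' @param measure Measure label.
#' @param terms Model terms to include; defaults to age, sex, age x sex and
#'   (for bilateral tracts) hemisphere. Use `terms = "age"` for a bivariate
#'   model, whose standardized beta equals the Pearson correlation.
#' @param sig_threshold Significance flag threshold (default 0.001).
#' @return List of class `dediff_tract_reg`: `coefficients` (term, beta,
#'   se, t, p, significant) for the selected form, `model_form`, both fits'
#'   statistics (`fit_stats`), the improvement test, and `n`.
#' @export
fit_tract_regression <- function(table, subjects, tract, measure,
                                 terms = c("age", "sex", "age_sex", "hemisphere"),
                                 sig_threshold = 0.001) {
  tab <- data.table::as.data.table(table)
  units <- unique(tab$tract[tab$tract == tract |
                              sub("_[LR]$", "", tab$tract) == tract])
  if (!length(units)) stop("no rows for tract ", tract)
  d <- tab[tab$tract %in% units & tab$measure == measure, ]
  i <- match(d$subject_id, subjects$subject_id)
  df <- data.frame(value = d$value,
                   age = subjects$age[i],
                   sex = subjects$sex[i],
                   hemi = as.integer(d$hemisphere == "right"))
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 50) stop("fewer than 50 complete rows for ", tract, "/", measure)
  midline <- all(d$hemisphere == "midline")
  df$value <- as.vector(scale(df$value))
  df$age <- as.vector(scale(df$age))

  rhs <- c()
  if ("age" %in% terms) rhs <- c(rhs, "age")
  if ("sex" %in% terms) rhs <- c(rhs, "sex")
  if ("age_sex" %in% terms && all(c("age", "sex") %in% terms))
    rhs <- c(rhs, "age:sex")
  if ("hemisphere" %in% terms && !midline) rhs <- c(rhs, "hemi")
  f_lin <- stats::reformulate(rhs, response = "value")
  f_quad <- stats::reformulate(c(rhs[1], "I(age^2)", rhs[-1]), response = "value")

  fit_lin <- stats::lm(f_lin, data = df)
  .check_rank(fit_lin)
  fit_quad <- if ("age" %in% terms) stats::lm(f_quad, data = df) else fit_lin
  form <- compare_linear_quadratic(fit_lin, fit_quad)
  chosen <- if (form == "quadratic") fit_quad else fit_lin
  sm <- summary(chosen)$coefficients
  coefs <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4],
                      significant = sm[, 4] < sig_threshold,
                      row.names = NULL)
  imp <- if (identical(fit_quad, fit_lin)) NULL else
    stats::anova(fit_lin, fit_quad)
  structure(list(
    tract = tract, measure = measure, coefficients = coefs,
    model_form = form,
    fit_stats = data.frame(
      form = c("linear", "quadratic"),
      r_squared = c(summary(fit_lin)$r.squared, summary(fit_quad)$r.squared),
      AIC = c(stats::AIC(fit_lin), stats::AIC(fit_quad))),
    improvement_p = if (!is.null(imp)) imp$`Pr(>F)`[2] else NA_real_,
    n = nrow(df), midline = midline,
    fits = list(linear = fit_lin, quadratic = fit_quad)
  ), class = "dediff_tract_reg")
}

.check_rank <- function(fit) {
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' Compare nested linear and quadratic age models
#'
#' Nested-model F test of the added age-squared term; returns
#' `"quadratic"` iff the improvement is significant at p < 0.05.
#'
#' @param fit_lin,fit_quad Nested `lm` fits on identical rows (`fit_quad`
#'   adds the age-squared term).
#' @return `"linear"` or `"quadratic"`.
#' @export
compare_linear_quadratic <- function(fit_lin, fit_quad) {
  if (identical(fit_lin, fit_quad)) return("linear")
  if (stats::nobs(fit_lin) != stats::nobs(fit_quad))
    stop("fits are not on identical rows; models are not nested")
  k_lin <- length(stats::coef(fit_lin))
  k_quad <- length(stats::coef(fit_quad))
  if (k_quad <= k_lin)
    stop("quadratic fit does not extend the linear fit; models are not nested")
  a <- stats::anova(fit_lin, fit_quad)
  p <- a$`Pr(>F)`[2]
  if (is.na(p)) return("linear")
  if (p < 0.05) "quadratic" else "linear"
}
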