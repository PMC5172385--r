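#' Generate a synthetic tract-metric cohort
#'
#' Samples a full synthetic cohort from a [generating_model()]: subject
#' covariates (age, sex, handedness), exclusion flags, tract-averaged values
#' for every measure and tract unit, and head-size-corrected volumetric
#' measures. The sampling process follows the generating equation documented
#' in [generating_model()]; all draws are governed by `seed`, so the same
#' call reproduces the same cohort exactly.
#'
#' @param gm A `dediff_genmodel`.
#' @param n_raw Number of raw subjects before exclusions (>= 50).
#' @param seed Integer seed.
#' @param age_dist `"groups"` draws ages from a mixture matching the six
#'   roughly 5-year age-group sizes of the study population; `"uniform"`
#'   draws uniformly over the supported range.
#' @param flag_mode `"disjoint"` assigns the (scaled) exclusion-flag counts
#'   to disjoint random subject sets so the cascade counts are exact;
#'   `"independent"` draws each flag as an independent Bernoulli with the
#'   corresponding rate.
#' @param planted_handedness_d Optional named list `list(measure=, tract=,
#'   d=)` planting a standardized right-minus-left-hander mean difference on
#'   one tract, for power checks of [handedness_check()].
#' @return A list of class `dediff_cohort` with elements `subjects`,
#'   `table` (long [data.table::data.table] with columns `subject_id`,
#'   `tract`, `hemisphere`, `measure`, `value`), `volumetrics`, `latents`
#'   (true factor scores and atrophy factor, for recovery tests), `genmodel`
#'   and `seed`.
#' @export
generate_cohort <- function(gm, n_raw = 5455L, seed = 1L,
                            age_dist = c("groups", "uniform"),
                            flag_mode = c("disjoint", "independent"),
                            planted_handedness_d = NULL) {
  stopifnot(inherits(gm, "dediff_genmodel"), n_raw >= 50)
  age_dist <- match.arg(age_dist)
  flag_mode <- match.arg(flag_mode)
  set.seed(as.integer(seed))

  n <- as.integer(n_raw)
  ids <- sprintf("S%05d", seq_len(n))

  ## ages
  if (age_dist == "groups") {
    gdef <- gm$age_groups
    grp <- sample.int(nrow(gdef), n, replace = TRUE, prob = gdef$n / sum(gdef$n))
    age <- stats::runif(n, gdef$lo[grp], gdef$hi[grp])
  } else {
    age <- stats::runif(n, gm$age_range[1], gm$age_range[2])
  }

  sex <- stats::rbinom(n, 1L, 0.47)            # 1 = male, 0 = female
  handedness <- sample(c("right", "left", "ambidextrous"), n, replace = TRUE,
                       prob = c(0.89, 0.10, 0.01))

  ## exclusion flags
  cnt <- round(gm$flag_counts * n / gm$n_ref)
  flags <- matrix(FALSE, n, 4L,
                  dimnames = list(NULL, c("early_phase_flag", "qc_fail_flag",
                                          "neuro_diagnosis_flag", "outlier_flag")))
  if (flag_mode == "disjoint") {
    if (sum(cnt) > n) stop("flag counts exceed n_raw")
    perm <- sample.int(n)
    at <- 0L
    for (j in seq_len(4L)) {
      if (cnt[j] > 0) flags[perm[(at + 1L):(at + cnt[j])], j] <- TRUE
      at <- at + cnt[j]
    }
  } else {
    for (j in seq_len(4L)) flags[, j] <- stats::runif(n) < gm$flag_counts[j] / gm$n_ref
  }

  subjects <- data.frame(subject_id = ids, age = age, sex = sex,
                         handedness = handedness, flags,
                         stringsAsFactors = FALSE)

  A <- (age - gm$age_center) / gm$age_scale     # standardized age
  a <- age - gm$age_center                      # centered years (moderation)

  ## measure-level latent factors
  meas_names <- names(gm$measures)
  nonfa <- setdiff(meas_names, if (isTRUE(gm$measures[["FA"]]$structural)) "FA" else character())
  k <- length(nonfa)
  zeta <- NULL
  if (k > 0) {
    C <- matrix(gm$zeta_corr, k, k); diag(C) <- 1
    zeta <- matrix(stats::rnorm(n * k), n, k) %*% chol(C)
    colnames(zeta) <- nonfa
  }
  g <- matrix(NA_real_, n, length(meas_names), dimnames = list(NULL, meas_names))
  for (m in nonfa) {
    gam <- gm$measures[[m]]$gamma
    g[, m] <- gam * A + sqrt(1 - gam^2) * zeta[, m]
  }
  if ("FA" %in% meas_names && isTRUE(gm$measures[["FA"]]$structural)) {
    st <- gm$fa_structure
    gI <- gm$measures[["ICVF"]]$gamma; gO <- gm$measures[["OD"]]$gamma
    covIO <- gI * gO + sqrt((1 - gI^2) * (1 - gO^2)) * gm$zeta_corr
    v_struct <- st$c_prime^2 + st$b[["ICVF"]]^2 + st$b[["OD"]]^2 +
      2 * st$c_prime * st$b[["ICVF"]] * gI +
      2 * st$c_prime * st$b[["OD"]] * gO +
      2 * st$b[["ICVF"]] * st$b[["OD"]] * covIO
    s_e <- sqrt(max(1 - v_struct, 1e-8))
    g[, "FA"] <- st$c_prime * A + st$b[["ICVF"]] * g[, "ICVF"] +
      st$b[["OD"]] * g[, "OD"] + s_e * stats::rnorm(n)
  }

  ## tract values per measure
  cat27 <- gm$catalog
  right_units <- cat27$name[cat27$laterality == "right"]
  tabs <- vector("list", length(meas_names))
  for (mi in seq_along(meas_names)) {
    m <- meas_names[mi]
    mm <- gm$measures[[m]]
    p <- mm$params
    w <- 1 + mm$lambda1p * a
    v <- 1 + mm$lambda2p * a
    U <- matrix(stats::rnorm(n * 27L), n, 27L)
    ## residual covariances: correlate the unique factors of listed pairs
    ## (covariance without extra variance, matching the fitted model's
    ## residual-covariance parameter)
    if (!is.null(gm$resid_pairs) && nrow(gm$resid_pairs)) {
      for (i in seq_len(nrow(gm$resid_pairs))) {
        j1 <- match(gm$resid_pairs$t1[i], p$name)
        j2 <- match(gm$resid_pairs$t2[i], p$name)
        rho <- gm$resid_pairs$value[i] / (p$lambda2[j1] * p$lambda2[j2])
        if (abs(rho) >= 1)
          stop("residual covariance implies |correlation| >= 1 for pair ",
               gm$resid_pairs$t1[i], "-", gm$resid_pairs$t2[i])
        U[, j2] <- rho * U[, j1] + sqrt(1 - rho^2) * U[, j2]
      }
    }
    Y <- tcrossprod(rep(1, n), p$nu) +
      tcrossprod(A, p$alpha1) + tcrossprod(A^2, p$alpha2) +
      tcrossprod(sex, p$alpha3) +
      tcrossprod(g[, m] * w, p$lambda1) +
      (U * v) %*% diag(p$lambda2)
    Y[, p$name %in% right_units] <- Y[, p$name %in% right_units] + mm$hemi_offset
    if (!is.null(planted_handedness_d) && planted_handedness_d$measure == m) {
      j <- match(planted_handedness_d$tract, p$name)
      Y[, j] <- Y[, j] + planted_handedness_d$d * (handedness == "right")
    }
    if (gm$missing_rate > 0)
      Y[stats::runif(n * 27L) < gm$missing_rate] <- NA_real_
    tabs[[mi]] <- data.table::data.table(
      subject_id = rep(ids, times = 27L),
      tract = rep(p$name, each = n),
      hemisphere = rep(cat27$laterality, each = n),
      measure = m,
      value = as.vector(Y))
  }
  table <- data.table::rbindlist(tabs)
  data.table::setkeyv(table, c("subject_id", "tract", "measure"))

  ## volumetrics: age trend plus a shared atrophy factor tied to the
  ## diffusion factors (healthier microstructure ~ larger volumes)
  sgn <- c(FA = 1, MD = -1, ICVF = 1, ISOVF = -1, OD = 0)
  use <- intersect(meas_names, names(sgn)[sgn != 0])
  healthy <- if (length(use)) {
    hraw <- g[, use, drop = FALSE] %*% sgn[use]
    as.vector(scale(hraw))
  } else stats::rnorm(n)
  atrophy <- 0.45 * healthy + sqrt(1 - 0.45^2) * stats::rnorm(n)
  vdef <- gm$volumetrics
  vols <- sapply(seq_len(nrow(vdef)), function(i) {
    av <- vdef$age_slope[i]; wv <- vdef$atrophy_loading[i]
    av * A + sqrt(1 - av^2) * (wv * atrophy + sqrt(1 - wv^2) * stats::rnorm(n))
  })
  colnames(vols) <- vdef$name
  volumetrics <- data.frame(subject_id = ids, vols, stringsAsFactors = FALSE)

  structure(list(subjects = subjects, table = table, volumetrics = volumetrics,
                 latents = list(g = g, atrophy = atrophy),
                 genmodel = gm, seed = as.integer(seed)),
            class = "dediff_cohort")
}

#' Apply the exclusion cascade
#'
#' Removes flagged subjects in the fixed order: early scanning phase,
#' diffusion QC failure, neurological diagnosis, extreme outlier. Counts are
#' order-dependent: a subject carrying several flags is counted only at the
#' first stage that removes them.
#'
#' @param subjects Data frame with the four logical flag columns.
#' @return List with `retained` (data frame) and `counts`, a named integer
#'   vector of per-stage removals plus `retained` (the final n).
#' @export
apply_exclusion_cascade <- function(subjects) {
  stages <- c("early_phase_flag", "qc_fail_flag",
              "neuro_diagnosis_flag", "outlier_flag")
  missing_cols <- setdiff(stages, names(subjects))
  if (length(missing_cols))
    stop("missing flag columns: ", paste(missing_cols, collapse = ", "))
  counts <- integer(length(stages))
  names(counts) <- sub("_flag$", "", stages)
  kept <- subjects
  for (i in seq_along(stages)) {
    drop <- kept[[stages[i]]]
    counts[i] <- sum(drop)
    kept <- kept[!drop, , drop = FALSE]
  }
  counts <- c(counts, retained = nrow(kept))
  list(retained = kept, counts = counts)
}

#' Restrict a cohort to retained subjects
#'
#' Applies [apply_exclusion_cascade()] and subsets the metric and
#' volumetric tables accordingly.
#' @param cohort A `dediff_cohort`.
#' @return The cohort with flagged subjects removed and `exclusion_counts`
#'   attached.
#' @export
exclude_cohort <- function(cohort) {
  casc <- apply_exclusion_cascade(cohort$subjects)
  ids <- casc$retained$subject_id
  keep_idx <- cohort$subjects$subject_id %in% ids
  cohort$subjects <- casc$retained
  cohort$table <- cohort$table[cohort$table$subject_id %in% ids, ]
  cohort$volumetrics <- cohort$volumetrics[cohort$volumetrics$subject_id %in% ids, ]
  cohort$latents$g <- cohort$latents$g[keep_idx, , drop = FALSE]
  cohort$latents$atrophy <- cohort$latents$atrophy[keep_idx]
  cohort$exclusion_counts <- casc$counts
  cohort
}
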