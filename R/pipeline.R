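#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()]: the seed, cohort size, measures, stage toggles and the
#' analysis thresholds.
#'
#' @param seed Master seed for cohort generation.
#' @param n_raw Raw cohort size before exclusions.
#' @param measures Measure labels to analyse.
#' @param stages Stages to run, in order, a subset of `"tract_effects"`,
#'   `"factors"`, `"pathways"`, `"mediation"`, `"prediction"`,
#'   `"dedifferentiation"`.
#' @param p_significance Per-coefficient significance threshold.
#' @param loading_cutoff Standardized-loading pruning threshold.
#' @param enet_frequency Elastic-net inclusion-frequency threshold.
#' @param n_boot Elastic-net bootstrap resamples.
#' @param max_resid_pairs Residual-covariance pairs to consider adding.
#' @param losem Run the LOSEM confirmation inside the de-differentiation
#'   stage.
#' @param losem_targets Number of LOSEM age targets.
#' @param losem_bandwidth LOSEM kernel bandwidth (years).
#' @param max_pathway_add Maximum tract-specific age paths to select.
#' @param weak_factor_threshold First-eigenvalue share below which a
#'   measure's factor score is not extracted.
#' @param out_dir Output directory (`NULL`: return results in memory only).
#' @return List of class `dediff_config`.
#' @export
pipeline_config <- function(seed = 7L, n_raw = 5455L,
                            measures = c("FA", "MD", "ICVF", "ISOVF", "OD"),
                            stages = c("tract_effects", "factors", "pathways",
                                       "mediation", "prediction",
                                       "dedifferentiation"),
                            p_significance = 0.001, loading_cutoff = 0.3,
                            enet_frequency = 0.60, n_boot = 1000L,
                            max_resid_pairs = 3L,
                            losem = FALSE, losem_targets = 300L,
                            losem_bandwidth = 2,
                            max_pathway_add = 5L,
                            weak_factor_threshold = 0.15,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(p_significance > 0, p_significance < 1,
            loading_cutoff >= 0, loading_cutoff < 1,
            enet_frequency > 0, enet_frequency < 1,
            !anyDuplicated(measures))
  class(cfg) <- "dediff_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file of configuration overrides.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic cohort (or takes a user-supplied metric table),
#' applies the exclusion cascade, then runs the enabled stages in order:
#' per-tract regressions, one-factor models with pruning, residual
#' covariances and factor scores, pathway-model comparison, the
#' age-gFA mediation, elastic-net age prediction, and the age-moderation
#' (de-differentiation) models. A stage failure is recorded and later
#' stages still run. When `out_dir` is set, tidy TSV/JSON artifacts and a
#' provenance manifest (with file checksums) are written.
#'
#' @param config A `dediff_config` from [pipeline_config()].
#' @param table,subjects,volumetrics Optional user-supplied data replacing
#'   the synthetic cohort; `table` must carry the standard columns and
#'   `subjects` must include `subject_id`, `age`, `sex`.
#' @return List of class `dediff_report`: `stages` (named results, each
#'   with `status`), `manifest`, `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config(), table = NULL,
                         subjects = NULL, volumetrics = NULL) {
  t_start <- Sys.time()
  warn_log <- character(0)
  note <- function(w) warn_log <<- c(warn_log, conditionMessage(w))

  gm <- generating_model(measures = config$measures)
  if (is.null(table)) {
    cohort <- exclude_cohort(generate_cohort(gm, config$n_raw,
                                             seed = config$seed))
    table <- cohort$table
    subjects <- cohort$subjects
    volumetrics <- cohort$volumetrics
    exclusion <- cohort$exclusion_counts
  } else {
    need <- c("subject_id", "age", "sex")
    if (is.null(subjects)) stop("user-supplied tables require `subjects`")
    miss <- setdiff(need, names(subjects))
    if (length(miss))
      stop("subjects table is missing column(s): ", paste(miss, collapse = ", "))
    req <- c("subject_id", "tract", "hemisphere", "measure", "value")
    miss <- setdiff(req, names(table))
    if (length(miss))
      stop("metric table is missing column(s): ", paste(miss, collapse = ", "))
    table <- data.table::as.data.table(table)
    table$tract <- normalize_tract_names(table$tract)
    if (any(c("early_phase_flag", "qc_fail_flag") %in% names(subjects))) {
      casc <- apply_exclusion_cascade(subjects)
      subjects <- casc$retained
      table <- table[table$subject_id %in% subjects$subject_id, ]
      exclusion <- casc$counts
    } else exclusion <- c(retained = nrow(subjects))
  }

  results <- list(exclusion = list(status = "ok", counts = exclusion))
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    res <- withCallingHandlers(
      tryCatch(list(status = "ok", value = expr),
               error = function(e) list(status = "failed",
                                        error = conditionMessage(e))),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    results[[name]] <<- res
    invisible(NULL)
  }

  run_stage("tract_effects", .stage_tract_effects(table, subjects, config))
  run_stage("factors", .stage_factors(table, subjects, config))
  fac <- results$factors
  run_stage("pathways", .stage_pathways(table, subjects, config))
  run_stage("mediation", .stage_mediation(fac, subjects, config))
  run_stage("prediction", .stage_prediction(fac, table, subjects,
                                            volumetrics, config))
  run_stage("dedifferentiation", .stage_dediff(table, subjects, fac, config))

  report <- structure(list(
    stages = results,
    config = unclass(config),
    warnings = warn_log,
    manifest = list(seed = config$seed,
                    started = format(t_start), finished = format(Sys.time()),
                    version = as.character(utils::packageVersion("dediffwm")))
  ), class = "dediff_report")
  if (!is.null(config$out_dir)) report <- .write_report(report, config$out_dir)
  report
}

.stage_tract_effects <- function(table, subjects, config) {
  base_tracts <- unique(tract_catalog()$tract)
  rows <- list()
  for (m in config$measures) for (tr in base_tracts) {
    fit <- fit_tract_regression(table, subjects, tr, m,
                                sig_threshold = config$p_significance)
    cf <- fit$coefficients
    cf$tract <- tr; cf$measure <- m; cf$model_form <- fit$model_form
    rows[[length(rows) + 1L]] <- cf
  }
  do.call(rbind, rows)
}

.stage_factors <- function(table, subjects, config) {
  out <- list()
  ## pruning is decided once, on the first measure's all-tract model
  first <- config$measures[1]
  all_fit <- fit_one_factor(table, subjects, first,
                            tracts = tract_catalog()$name, on_heywood = "warn")
  pruned <- prune_low_loadings(all_fit, config$loading_cutoff)
  keep <- setdiff(tract_catalog()$name, pruned)
  for (m in config$measures) {
    es <- eigen_spectrum(table, m, tracts = keep,
                         weak_threshold = config$weak_factor_threshold)
    entry <- list(eigen = es, weak = es$weak_first_factor)
    fit <- fit_one_factor(table, subjects, m, tracts = keep,
                          on_heywood = "warn")
    fit <- add_residual_covariances(table, subjects, fit,
                                    max_pairs = config$max_resid_pairs)
    entry$fit <- fit
    entry$variance_explained <- fit$variance_explained
    if (!es$weak_first_factor) {
      ## score-extraction model: sex-adjusted only, so scores retain age
      ## information for the downstream analyses
      sfit <- fit_one_factor(table, subjects, m, tracts = keep,
                             resid_pairs = fit$resid_pairs,
                             covariates = "sex", on_heywood = "warn")
      entry$scores <- factor_scores(sfit)
    }
    out[[m]] <- entry
  }
  out$pruned <- pruned
  out$tracts <- keep
  out
}

.stage_pathways <- function(table, subjects, config) {
  lapply(stats::setNames(nm = config$measures), function(m)
    fit_pathway_models(table, subjects, m, max_add = config$max_pathway_add))
}

.stage_mediation <- function(fac, subjects, config) {
  if (is.null(fac) || fac$status != "ok")
    stop("factor stage unavailable")
  v <- fac$value
  need <- c("FA", "ICVF", "OD")
  if (!all(vapply(need, function(m) !is.null(v[[m]]$scores), logical(1))))
    stop("mediation requires FA, ICVF and OD factor scores")
  ids <- Reduce(intersect, lapply(need, function(m) v[[m]]$scores$subject_id))
  sc <- function(m) v[[m]]$scores$score[match(ids, v[[m]]$scores$subject_id)]
  age <- subjects$age[match(ids, subjects$subject_id)]
  fit_multiple_mediator(age, cbind(gICVF = sc("ICVF"), gOD = sc("OD")),
                        sc("FA"), seed = config$seed)
}

.stage_prediction <- function(fac, table, subjects, volumetrics, config) {
  if (is.null(fac) || fac$status != "ok") stop("factor stage unavailable")
  v <- fac$value
  scored <- names(which(vapply(config$measures,
                               function(m) !is.null(v[[m]]$scores), logical(1))))
  if (!length(scored)) stop("no factor scores available")
  ids <- Reduce(intersect, c(lapply(scored, function(m) v[[m]]$scores$subject_id),
                             list(volumetrics$subject_id)))
  X <- do.call(cbind, lapply(scored, function(m)
    v[[m]]$scores$score[match(ids, v[[m]]$scores$subject_id)]))
  colnames(X) <- paste0("g", scored)
  vol <- as.matrix(volumetrics[match(ids, volumetrics$subject_id),
                               setdiff(names(volumetrics), "subject_id")])
  X <- cbind(X, vol)
  age <- subjects$age[match(ids, subjects$subject_id)]
  sel <- bootstrap_enet_select(X, age, n_boot = config$n_boot,
                               freq_threshold = config$enet_frequency,
                               split_seed = config$seed)
  confirm <- if (length(sel$selected))
    confirm_train_test(sel$selected, X, age, sel$train_idx, sel$test_idx)
  else NULL
  ## thalamus-specific increment, per measure
  thal <- lapply(stats::setNames(nm = scored), function(m) {
    g <- fit_gtr(table, m)
    common <- intersect(ids, g$scores$subject_id)
    thalamus_increment(
      volumetrics$thalamus[match(common, volumetrics$subject_id)],
      g$scores$score[match(common, g$scores$subject_id)],
      volumetrics$total_brain[match(common, volumetrics$subject_id)],
      subjects$age[match(common, subjects$subject_id)])
  })
  list(selection = sel, confirm = confirm, thalamus = thal)
}

.stage_dediff <- function(table, subjects, fac, config) {
  keep <- if (!is.null(fac) && fac$status == "ok") fac$value$tracts
          else core_tracts()
  out <- list()
  for (m in config$measures) {
    rp <- if (!is.null(fac) && fac$status == "ok")
      fac$value[[m]]$fit$resid_pairs else NULL
    mf <- fit_moderated_factor(table, subjects, m, mode = "invariant",
                               tracts = keep, resid_pairs = rp,
                               on_heywood = "warn")
    entry <- list(fit = mf,
                  curve = communality_curve(mf),
                  delta = communality_delta(mf),
                  tests = test_moderation_significance(mf))
    if (isTRUE(config$losem))
      entry$losem <- fit_losem(table, subjects, m, tracts = keep,
                               n_targets = config$losem_targets,
                               bandwidth = config$losem_bandwidth)
    out[[m]] <- entry
  }
  out
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  st <- report$stages
  if (!is.null(st$tract_effects) && st$tract_effects$status == "ok")
    emit_tsv(st$tract_effects$value, "tract_effects.tsv")
  if (!is.null(st$dedifferentiation) && st$dedifferentiation$status == "ok") {
    for (m in names(st$dedifferentiation$value)) {
      cv <- st$dedifferentiation$value[[m]]$curve
      emit_tsv(data.frame(age = cv$age, h_mean = cv$h_mean, se = cv$se,
                          lo = cv$lo, hi = cv$hi),
               paste0("communality_", m, ".tsv"))
    }
  }
  manifest <- report$manifest
  manifest$files <- if (length(files))
    data.frame(file = basename(files), md5 = unname(tools::md5sum(files)))
  else data.frame()
  report$manifest <- manifest
  jsonlite::write_json(
    list(manifest = manifest, warnings = report$warnings,
         stage_status = lapply(st, `[[`, "status"),
         config = report$config[!vapply(report$config, is.null, logical(1))]),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  report
}
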