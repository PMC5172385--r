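#!/usr/bin/env Rscript
# Mediation of the age-gFA association by gICVF and gOD, bootstrapped
# elastic-net selection of age predictors with train/test confirmation, and
# the thalamus-specific incremental-variance models.
source("analysis/00_common.R")

cohort <- make_cohort()
tab <- cohort$table; subj <- cohort$subjects

score_of <- function(m) {
  sfit <- fit_one_factor(tab, subj, m, covariates = "sex",
                         resid_pairs = default_resid_pairs()[, c("t1", "t2")],
                         on_heywood = "warn")
  factor_scores(sfit)
}
sc <- lapply(stats::setNames(nm = MEASURES), score_of)
ids <- Reduce(intersect, c(lapply(sc, `[[`, "subject_id"),
                           list(cohort$volumetrics$subject_id)))
pick <- function(m) sc[[m]]$score[match(ids, sc[[m]]$subject_id)]
age <- subj$age[match(ids, subj$subject_id)]

med <- fit_multiple_mediator(age, cbind(gICVF = pick("ICVF"), gOD = pick("OD")),
                             pick("FA"), n_boot = 2000, seed = SEED)
cat(sprintf("Age -> gFA: total beta %+0.3f, direct %+0.3f, mediated %.1f%%\n",
            med$c, med$c_prime, 100 * med$proportion_mediated))
cat(sprintf("  indirect via gICVF %+0.3f, via gOD %+0.3f\n",
            med$ab[1], med$ab[2]))
jsonlite::write_json(
  list(c = med$c, c_prime = med$c_prime, ab = med$ab,
       proportion_mediated = med$proportion_mediated,
       proportion_ci = unname(med$proportion_ci)),
  "results/mediation.json", auto_unbox = TRUE, digits = NA)

X <- do.call(cbind, lapply(MEASURES, pick))
colnames(X) <- paste0("g", MEASURES)
vol <- as.matrix(cohort$volumetrics[match(ids, cohort$volumetrics$subject_id),
                                    setdiff(names(cohort$volumetrics),
                                            "subject_id")])
X <- cbind(X, vol)
sel <- bootstrap_enet_select(X, age, n_boot = 1000, split_seed = SEED)
cat("\nElastic-net inclusion frequencies (1,000 bootstraps):\n")
print(round(sel$frequency, 2))
cat("Selected (>60%):", paste(sel$selected, collapse = ", "), "\n")
cf <- confirm_train_test(sel$selected, X, age, sel$train_idx, sel$test_idx)
cat(sprintf("Train R^2 = %.3f, Test R^2 = %.3f, max VIF = %.2f\n",
            cf$r_squared["train"], cf$r_squared["test"], max(cf$vif)))
utils::write.table(
  data.frame(predictor = names(sel$frequency),
             inclusion_frequency = unname(sel$frequency),
             selected = names(sel$frequency) %in% sel$selected),
  "results/enet_selection.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  rbind(cbind(half = "train", cf$train), cbind(half = "test", cf$test)),
  "results/enet_confirmation.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nThalamic volume + gTR vs age (R^2 without / with TBV):\n")
for (m in MEASURES) {
  g <- fit_gtr(tab, m)
  common <- intersect(ids, g$scores$subject_id)
  ti <- thalamus_increment(
    cohort$volumetrics$thalamus[match(common, cohort$volumetrics$subject_id)],
    g$scores$score[match(common, g$scores$subject_id)],
    cohort$volumetrics$total_brain[match(common, cohort$volumetrics$subject_id)],
    subj$age[match(common, subj$subject_id)])
  cat(sprintf("  gTR %-5s R^2 = %.3f -> %.3f\n", m,
              ti$r_squared["base"], ti$r_squared["with_tbv"]))
}
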