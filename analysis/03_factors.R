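#!/usr/bin/env Rscript
# General factors of white-matter microstructure: eigen spectra, pruning of
# weak-loading tracts, one-factor models with residual covariances, and
# factor-score reliabilities.
source("analysis/00_common.R")

cohort <- make_cohort()
tab <- cohort$table; subj <- cohort$subjects

all_fit <- fit_one_factor(tab, subj, "FA", tracts = tract_catalog()$name,
                          on_heywood = "warn")
pruned <- prune_low_loadings(all_fit)
cat("Tracts pruned for low (<0.3) FA loadings:",
    paste(pruned, collapse = ", "), "\n\n")

summary_rows <- list()
for (m in MEASURES) {
  es <- eigen_spectrum(tab, m)
  fit <- fit_one_factor(tab, subj, m, on_heywood = "warn")
  fit <- add_residual_covariances(tab, subj, fit, max_pairs = 3)
  sfit <- fit_one_factor(tab, subj, m, resid_pairs = fit$resid_pairs,
                         covariates = "sex", on_heywood = "warn")
  sc <- factor_scores(sfit)
  summary_rows[[m]] <- data.frame(
    measure = m,
    first_eigen_share = es$first_share,
    weak_first_factor = es$weak_first_factor,
    pct_variance = 100 * fit$variance_explained,
    n_resid_pairs = if (is.null(fit$resid_pairs)) 0L else nrow(fit$resid_pairs),
    score_reliability = attr(sc, "reliability"))
  cat(sprintf("%-5s first-factor share %.3f | variance explained %.1f%% | %d residual pair(s)\n",
              m, es$first_share, 100 * fit$variance_explained,
              if (is.null(fit$resid_pairs)) 0L else nrow(fit$resid_pairs)))
}
fs <- do.call(rbind, summary_rows)
utils::write.table(fs, "results/factor_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

g <- fit_gtr(tab, "MD")
cat("\ngTR (thalamic radiations, MD): first PC explains",
    sprintf("%.1f%%", 100 * g$var_share), "of the 6-tract variance\n")
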