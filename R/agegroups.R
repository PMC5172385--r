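#' Age-binned tract correlation matrices
#'
#' Splits subjects into age groups (default: six bins of roughly five
#' years) and computes, for each group and measure, the Pearson correlation
#' matrix across all tract units — the heatmap view of de-differentiation:
#' under increasing communality the mean off-diagonal correlation rises
#' from the youngest to the oldest bin.
#'
#' @param table Tidy metric table.
#' @param subjects Covariate data frame.
#' @param breaks Age bin boundaries (length = bins + 1). The default
#'   reproduces the six study age groups.
#' @param measures Measures to process (default: all present).
#' @param tracts Tract units (default: all present).
#' @return List of class `dediff_agegroups`: `bins` (data frame with
#'   edges, n, mean and sd of age) and `matrices[[measure]][[bin]]`
#'   (correlation matrix, or `NULL` when the bin holds fewer than 3
#'   subjects).
#' @export
age_group_correlations <- function(table, subjects,
                                   breaks = c(44.64, 50.05, 55.00, 60.01,
                                              65.00, 70.00, 77.13),
                                   measures = NULL, tracts = NULL) {
  tab <- data.table::as.data.table(table)
  if (is.null(measures)) measures <- unique(tab$measure)
  grp <- findInterval(subjects$age, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  if (any(grp < 1 | grp > nb, na.rm = TRUE))
    stop("bins do not partition the observed age range")
  bins <- data.frame(
    bin = seq_len(nb), lo = breaks[-length(breaks)], hi = breaks[-1],
    n = as.integer(tabulate(grp, nb)),
    age_mean = vapply(seq_len(nb), function(b)
      mean(subjects$age[grp == b]), numeric(1)),
    age_sd = vapply(seq_len(nb), function(b)
      stats::sd(subjects$age[grp == b]), numeric(1)))
  matrices <- list()
  for (m in measures) {
    W <- metric_wide(tab, m, tracts)
    sgrp <- grp[match(rownames(W), subjects$subject_id)]
    matrices[[m]] <- lapply(seq_len(nb), function(b) {
      Wb <- W[which(sgrp == b), , drop = FALSE]
      if (nrow(Wb) < 3) return(NULL)
      if (nrow(Wb) < 10)
        warning("age bin ", b, " has fewer than 10 subjects for ", m)
      stats::cor(Wb, use = "pairwise.complete.obs")
    })
  }
  structure(list(bins = bins, matrices = matrices),
            class = "dediff_agegroups")
}

#' Mean off-diagonal correlation per age bin
#'
#' Summary of [age_group_correlations()] output for one measure.
#' @param ag A `dediff_agegroups` object.
#' @param measure Measure label.
#' @return Numeric vector (one value per bin; `NA` for omitted bins).
#' @export
mean_offdiag_correlation <- function(ag, measure) {
  vapply(ag$matrices[[measure]], function(M) {
    if (is.null(M)) return(NA_real_)
    mean(M[upper.tri(M)], na.rm = TRUE)
  }, numeric(1))
}

#' Handedness comparison per tract and measure
#'
#' Welch two-sample t test and Cohen's d (pooled SD) comparing right- and
#' left-handed subjects on every tract unit and measure. Ambidextrous
#' subjects are excluded.
#'
#' @param table Tidy metric table.
#' @param subjects Covariate data frame with a `handedness` column.
#' @param measures Measures to test (default: all present).
#' @return Data frame: tract, measure, group ns, t, Welch df, p, cohen_d
#'   (right minus left).
#' @export
handedness_check <- function(table, subjects, measures = NULL) {
  tab <- data.table::as.data.table(table)
  if (is.null(measures)) measures <- unique(tab$measure)
  hand <- subjects$handedness[match(tab$subject_id, subjects$subject_id)]
  keep <- hand %in% c("right", "left")
  tab <- tab[keep, ]; hand <- hand[keep]
  if (!any(hand == "right") || !any(hand == "left"))
    stop("both handedness groups must be non-empty")
  out <- list()
  for (m in measures) {
    sel <- tab$measure == m
    d <- tab[sel, ]; h <- hand[sel]
    for (tr in unique(d$tract)) {
      i <- d$tract == tr
      xr <- d$value[i & h == "right"]; xl <- d$value[i & h == "left"]
      xr <- xr[!is.na(xr)]; xl <- xl[!is.na(xl)]
      tt <- stats::t.test(xr, xl)
      sp <- sqrt(((length(xr) - 1) * stats::var(xr) +
                  (length(xl) - 1) * stats::var(xl)) /
                 (length(xr) + length(xl) - 2))
      out[[length(out) + 1L]] <- data.frame(
        tract = tr, measure = m, n_right = length(xr), n_left = length(xl),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value,
        cohen_d = if (sp > 0) (mean(xr) - mean(xl)) / sp else 0)
    }
  }
  do.call(rbind, out)
}
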