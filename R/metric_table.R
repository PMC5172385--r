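#' Read / write a tidy tract-metric table
#'
#' The canonical interchange format is a tidy, tab-delimited table with
#' columns `subject_id`, `tract`, `hemisphere`, `measure`, `value` (UTF-8,
#' `.` decimal). Tract names are validated against [tract_catalog()] with a
#' documented alias map; duplicated (subject, tract, hemisphere, measure)
#' rows are an error.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @return `read_metric_table()`: a `data.table` keyed by subject, tract and
#'   measure. `write_metric_table()`: the path, invisibly.
#' @export
read_metric_table <- function(path, sep = "\t") {
  tab <- data.table::fread(path, sep = sep, colClasses = list(
    character = c("subject_id", "tract", "hemisphere", "measure")))
  required <- c("subject_id", "tract", "hemisphere", "measure", "value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("metric table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(tab$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$value))) & !is.na(tab$value))
    stop("malformed numeric value at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tab$tract <- normalize_tract_names(tab$tract)
  key <- paste(tab$subject_id, tab$tract, tab$hemisphere, tab$measure)
  if (anyDuplicated(key))
    stop("duplicate (subject, tract, hemisphere, measure) rows, e.g.: ",
         key[anyDuplicated(key)[1]][1])
  data.table::setkeyv(tab, c("subject_id", "tract", "measure"))
  tab[]
}

#' @rdname read_metric_table
#' @param table A tidy metric table.
#' @export
write_metric_table <- function(table, path, sep = "\t") {
  data.table::fwrite(data.table::as.data.table(table), path, sep = sep)
  invisible(path)
}

#' Wide subject-by-tract matrix for one measure
#'
#' @param table Tidy metric table.
#' @param measure Measure label.
#' @param tracts Tract unit names to keep (default: all present).
#' @return Numeric matrix, rownames = subject ids, colnames = tract units.
#' @export
metric_wide <- function(table, measure, tracts = NULL) {
  tab <- data.table::as.data.table(table)
  tab <- tab[tab$measure == measure, ]
  if (!nrow(tab)) stop("no rows for measure ", measure)
  if (!is.null(tracts)) tab <- tab[tab$tract %in% tracts, ]
  w <- data.table::dcast(tab, subject_id ~ tract, value.var = "value")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$subject_id
  if (!is.null(tracts)) m <- m[, tracts, drop = FALSE]
  m
}

# Covariate design matrix used throughout the factor models: standardized
# age, optionally its square, and 0/1 sex, aligned to the given subject ids.
.covariate_design <- function(subjects, ids, age_center = 60, age_scale = 7.5,
                              include_age2 = TRUE, include_age = TRUE) {
  i <- match(ids, subjects$subject_id)
  if (anyNA(i)) stop("subjects missing covariates: ",
                     paste(utils::head(ids[is.na(i)], 3), collapse = ", "))
  A <- (subjects$age[i] - age_center) / age_scale
  X <- cbind(intercept = 1, sex = subjects$sex[i])
  if (include_age) X <- cbind(X, age = A)
  if (include_age && include_age2) X <- cbind(X, age2 = A^2)
  X
}
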