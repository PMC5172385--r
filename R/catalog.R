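#' The 27-tract catalog
#'
#' Returns the fixed catalog of 27 tract-averaged white-matter units used
#' throughout the package: 12 bilateral pairs plus 3 midline structures.
#' Each bilateral tract contributes one left and one right unit, because the
#' factor models treat each hemisphere as a separate indicator. The 22 units
#' with `core_factor_member = TRUE` indicate the general factor; the middle
#' cerebellar peduncle, both medial lemnisci and both parahippocampal cingula
#' covary weakly with the rest and are excluded from the core set.
#'
#' @return A data.frame with one row per tract unit and columns `name`
#'   (e.g. `"ATR_L"`), `tract` (base name), `category` (one of
#'   `"association"`, `"thalamic_radiation"`, `"projection"`, `"callosal"`),
#'   `laterality` (`"left"`, `"right"`, `"midline"`) and `core_factor_member`.
#' @examples
#' cat27 <- tract_catalog()
#' nrow(cat27)                       # 27
#' sum(cat27$core_factor_member)     # 22
#' @export
tract_catalog <- function() {
  base <- data.frame(
    tract = c("MCP", "FMaj", "FMin",
              "ML", "CST", "AR", "ATR", "PTR", "STR",
              "SLF", "ILF", "IFOF", "Unc", "CingG", "CingPH"),
    category = c("projection", "callosal", "callosal",
                 "projection", "projection", "projection",
                 "thalamic_radiation", "thalamic_radiation", "thalamic_radiation",
                 "association", "association", "association", "association",
                 "association", "association"),
    bilateral = c(FALSE, FALSE, FALSE, rep(TRUE, 12)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    if (!b$bilateral) {
      data.frame(name = b$tract, tract = b$tract, category = b$category,
                 laterality = "midline", stringsAsFactors = FALSE)
    } else {
      data.frame(name = paste0(b$tract, c("_L", "_R")), tract = b$tract,
                 category = b$category, laterality = c("left", "right"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  weak <- c("MCP", "ML", "CingPH")
  out$core_factor_member <- !(out$tract %in% weak)
  rownames(out) <- NULL
  out
}

#' Core tract units
#'
#' Convenience accessor for the names of the 22 units indicating the general
#' factor.
#' @return Character vector of 22 unit names.
#' @export
core_tracts <- function() {
  cat27 <- tract_catalog()
  cat27$name[cat27$core_factor_member]
}

# Accepted aliases for tract base names (case-insensitive keys).
.tract_alias_map <- c(
  "forceps minor" = "FMin", "forceps major" = "FMaj",
  "middle cerebellar peduncle" = "MCP",
  "medial lemniscus" = "ML",
  "corticospinal tract" = "CST",
  "acoustic radiation" = "AR",
  "anterior thalamic radiation" = "ATR",
  "posterior thalamic radiation" = "PTR",
  "superior thalamic radiation" = "STR",
  "superior longitudinal fasciculus" = "SLF",
  "inferior longitudinal fasciculus" = "ILF",
  "inferior fronto-occipital fasciculus" = "IFOF",
  "uncinate" = "Unc", "uncinate fasciculus" = "Unc",
  "cingulum gyrus" = "CingG", "cingulate gyrus" = "CingG",
  "cingulum parahippocampal" = "CingPH",
  "parahippocampal cingulum" = "CingPH"
)

#' Normalize tract names against the catalog
#'
#' Maps common long-form tract names (e.g. `"Forceps minor"`) onto catalog
#' base names, preserving any `_L`/`_R` suffix, and errors on names that
#' match neither the catalog nor the alias map.
#'
#' @param x Character vector of tract names or unit names.
#' @return Character vector of catalog names, same length as `x`.
#' @export
normalize_tract_names <- function(x) {
  cat27 <- tract_catalog()
  known <- unique(c(cat27$name, cat27$tract))
  out <- as.character(x)
  for (i in seq_along(out)) {
    nm <- out[i]
    if (nm %in% known) next
    suffix <- ""
    stem <- nm
    if (grepl("_[LR]$", nm)) {
      suffix <- substring(nm, nchar(nm) - 1L)
      stem <- substring(nm, 1L, nchar(nm) - 2L)
    }
    hit <- .tract_alias_map[tolower(stem)]
    if (is.na(hit)) {
      stop("Unknown tract name '", nm, "'. Accepted names: ",
           paste(sort(known), collapse = ", "), call. = FALSE)
    }
    out[i] <- paste0(hit, suffix)
  }
  out
}
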