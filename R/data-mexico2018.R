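#' Published summaries of the 2018 Mexican market survey
#'
#' Two small tables summarizing a 2018 DNA-barcoding survey of fish sold in
#' Mazatlan, Mexico City and Cancun (376 samples under 48 commercial names,
#' 116 mislabeled), shipped as plain-text package data.
#'
#' `mexico2018_name_audits()` returns the per-name audit base counts for
#' the 18 focal commercial names (316 samples) — verbal sample number,
#' correctly labeled, mislabeling frequency/diversity, substitutability
#' frequency/diversity — with the derived framework cells recomputed by
#' [complete_audit_table()]. `mexico2018_strata()` returns the city-by-
#' vendor-type sample sizes and mislabeling percentages; per-cell mislabel
#' counts are recovered as `round(n * pct / 100)` (the recovery is exact:
#' rows and columns cross-check against the published margins).
#' `mexico2018_study_counts()` returns the study-wide tally.
#'
#' @return Tibbles (see Details); `mexico2018_study_counts()` a named list
#'   with `k = 116`, `n = 376`.
#' @name mexico2018
NULL

#' @rdname mexico2018
#' @export
mexico2018_name_audits <- function() {
  path <- system.file("extdata", "mexico2018_name_audits.tsv",
    package = "fishaudit", mustWork = TRUE
  )
  complete_audit_table(readr::read_tsv(path,
    show_col_types = FALSE,
    progress = FALSE
  ))
}

#' @rdname mexico2018
#' @export
mexico2018_strata <- function() {
  path <- system.file("extdata", "mexico2018_city_vendor_rates.tsv",
    package = "fishaudit", mustWork = TRUE
  )
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$k_mislabeled <- as.integer(round(tab$n * tab$pct_mislabeled / 100))
  tab
}

#' @rdname mexico2018
#' @export
mexico2018_study_counts <- function() {
  list(k = 116L, n = 376L)
}
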