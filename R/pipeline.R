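#' Run the full audit pipeline on a simulated survey
#'
#' Convenience wrapper tying the stages together:
#' simulate -> identify -> call -> audit -> stats. With all-default
#' arguments it reproduces the default study conditions (three cities,
#' three vendor types, 48 commercial names plus a generic one, ~100-species
#' pool) end to end from a single seed.
#'
#' @param seed Integer seed driving every random draw.
#' @param pool,design,catalogs Study conditions; defaults from
#'   [default_study_pool()], [default_study_design()],
#'   [default_study_catalogs()].
#' @param n_libraries,dropout_per_library Reference-library layout.
#' @param threshold,genus_floor Identification thresholds (percent).
#' @param min_verbal Focal-name cutoff for the regression layer.
#' @param out_dir Optional directory; when given, [write_report()] is
#'   called.
#' @return List with `samples`, `truth`, `identifications`, `calls`,
#'   `audits`, `focal_audits`, `network`, `category`, `strata`,
#'   `regressions`, `study_rate` (study-wide Wilson row).
#' @export
run_pipeline <- function(seed = 1L,
                         pool = default_study_pool(),
                         design = default_study_design(),
                         catalogs = default_study_catalogs(),
                         n_libraries = 2L, dropout_per_library = 0,
                         threshold = 98, genus_floor = 90,
                         min_verbal = 6L, out_dir = NULL) {
  local_seed(seed)
  libset <- generate_reference_library(
    pool,
    n_libraries = n_libraries,
    dropout_per_library = dropout_per_library
  )
  survey <- simulate_survey(pool, design, catalogs, libset)
  ids <- identify_samples(survey$samples, libset,
    threshold = threshold, genus_floor = genus_floor
  )
  calls <- call_samples(survey$samples, ids, catalogs,
    generic_names = design$generic_names
  )
  audits <- audit_names(calls, catalogs)
  focal <- filter_focal_names(audits, min_verbal = min_verbal)
  network <- build_network(calls)
  species_cat <- setNames(pool$category, pool$species)
  name_cat <- default_name_categories(catalogs, species_cat)
  category <- category_matrix(network$edges, species_cat, name_cat)
  strata <- list(
    city = stratified_rates(calls, "city"),
    vendor_type = stratified_rates(calls, "vendor_type"),
    name_source = stratified_rates(calls, "name_source")
  )
  regressions <- dplyr::bind_rows(
    ols_fit(focal$mislabeling_diversity,
      focal$mislabeling_percentage,
      predictor = "mislabeling_diversity"
    ),
    ols_fit(focal$confirmed_samples,
      focal$mislabeling_percentage,
      predictor = "confirmed_samples"
    ),
    ols_fit(focal$substitutability_frequency,
      focal$mislabeling_percentage,
      predictor = "substitutability_frequency"
    ),
    ols_fit(focal$substitutability_diversity,
      focal$mislabeling_percentage,
      predictor = "substitutability_diversity"
    ),
    ols_fit(focal$verbal_sample_number,
      focal$mislabeling_percentage,
      predictor = "verbal_sample_number"
    )
  )
  active <- calls[calls$status %in% c("correct", "mislabeled"), , drop = FALSE]
  study_rate <- wilson_ci(sum(active$status == "mislabeled"), nrow(active))
  out <- list(
    samples = survey$samples, truth = survey$truth, identifications = ids,
    calls = calls, audits = audits, focal_audits = focal, network = network,
    category = category, strata = strata, regressions = regressions,
    study_rate = study_rate
  )
  if (!is.null(out_dir)) {
    write_report(
      audits, network,
      list(strata = strata, regressions = regressions, category = category),
      out_dir,
      config = read_run_config(overrides = list(seed = seed))
    )
  }
  out
}

# commercial name -> category, derived as the modal category of the
# accepted species of each name (ties broken marine_bony first)
default_name_categories <- function(catalogs, species_category) {
  map <- catalog_union(catalogs)
  names_all <- unique(map$commercial_name)
  setNames(vapply(names_all, function(nm) {
    cats <- species_category[map$species[map$commercial_name == nm]]
    cats <- cats[!is.na(cats)]
    if (length(cats) == 0L) {
      return("marine_bony")
    }
    tab <- table(factor(cats, levels = SPECIES_CATEGORIES))
    names(tab)[which.max(tab)]
  }, character(1L)), names_all)
}
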