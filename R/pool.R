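#' Species pool for survey simulation
#'
#' Validates a table of species available to the simulated market: scientific
#' name, broad origin category, and a non-negative relative supply weight.
#' Supply weights drive both which accepted species is sold under a correct
#' label and which species is drawn as a substitute (availability-driven
#' substitution).
#'
#' @param species Data frame with columns `species` (`"Genus epithet"`),
#'   `category` (one of `"marine_bony"`, `"elasmobranch"`,
#'   `"aquaculture_freshwater"`) and `supply_weight` (non-negative, summing
#'   to > 0).
#' @return The validated tibble with class `species_pool`.
#' @export
species_pool <- function(species) {
  pool <- tibble::as_tibble(species)
  required <- c("species", "category", "supply_weight")
  if (!all(required %in% names(pool))) {
    stop("species pool needs columns: ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(pool$species)) {
    stop("species names must be unique", call. = FALSE)
  }
  if (!all(pool$category %in% SPECIES_CATEGORIES)) {
    stop("categories must be one of: ",
      paste(SPECIES_CATEGORIES, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(pool$supply_weight < 0) || sum(pool$supply_weight) <= 0) {
    stop("supply weights must be non-negative and sum > 0", call. = FALSE)
  }
  class(pool) <- c("species_pool", class(tibble::tibble()))
  pool
}

#' Survey design for the synthetic market survey
#'
#' @param name_counts Named integer vector: samples to purchase per
#'   commercial name.
#' @param mislabel_prob Named numeric vector in `[0, 1]`: per-name
#'   probability that a sample is a substitute species. Names absent default
#'   to 0.
#' @param cities,vendor_types,name_sources Stratum vocabularies; samples are
#'   assigned independently with `*_weights` probabilities.
#' @param city_weights,vendor_weights,source_weights Optional sampling
#'   weights (default uniform).
#' @param generic_names Commercial names excluded from mislabeling analysis
#'   (e.g. "pescado").
#' @param intra_divergence Maximum within-species barcode divergence; each
#'   query is mutated from its species anchor at a divergence drawn uniformly
#'   from `[0, intra_divergence]`.
#' @param unidentifiable_rate Probability that a sample yields an unrelated
#'   (non-fish) sequence that no library should identify.
#' @param substitution_weights Optional matrix (commercial name x species) of
#'   substitute preferences; defaults to pool supply weights for every name.
#' @param substitution_gamma Exponent tempering the supply weights when they
#'   are used as substitute preferences (`weight^gamma`): 1 is pure
#'   availability-driven substitution, values below 1 flatten the substitute
#'   spectrum so that rarer species also appear as substitutes.
#' @return A list of class `survey_design`.
#' @export
survey_design <- function(name_counts, mislabel_prob,
                          cities = "city1",
                          vendor_types = VENDOR_TYPES,
                          name_sources = NAME_SOURCES,
                          city_weights = NULL, vendor_weights = NULL,
                          source_weights = NULL,
                          generic_names = character(),
                          intra_divergence = 0.01,
                          unidentifiable_rate = 0,
                          substitution_weights = NULL,
                          substitution_gamma = 1) {
  stopifnot(
    length(name_counts) > 0L, !is.null(names(name_counts)),
    all(name_counts >= 0L)
  )
  if (is.null(names(mislabel_prob)) && length(mislabel_prob) > 0L) {
    stop("`mislabel_prob` must be a named vector", call. = FALSE)
  }
  if (any(mislabel_prob < 0 | mislabel_prob > 1)) {
    stop("mislabeling probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(vendor_types %in% VENDOR_TYPES)) {
    stop("vendor types must be a subset of: ",
      paste(VENDOR_TYPES, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(name_sources %in% NAME_SOURCES)) {
    stop("name sources must be a subset of: ",
      paste(NAME_SOURCES, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(
    intra_divergence >= 0, intra_divergence <= 0.25,
    unidentifiable_rate >= 0, unidentifiable_rate <= 1,
    substitution_gamma >= 0
  )
  norm_w <- function(w, values) {
    if (is.null(w)) {
      return(setNames(rep(1 / length(values), length(values)), values))
    }
    stopifnot(length(w) == length(values), all(w >= 0), sum(w) > 0)
    setNames(w / sum(w), values)
  }
  structure(
    list(
      name_counts = name_counts,
      mislabel_prob = mislabel_prob,
      cities = cities,
      vendor_types = vendor_types,
      name_sources = name_sources,
      city_weights = norm_w(city_weights, cities),
      vendor_weights = norm_w(vendor_weights, vendor_types),
      source_weights = norm_w(source_weights, name_sources),
      generic_names = normalize_name(generic_names),
      intra_divergence = intra_divergence,
      unidentifiable_rate = unidentifiable_rate,
      substitution_weights = substitution_weights,
      substitution_gamma = substitution_gamma
    ),
    class = "survey_design"
  )
}
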