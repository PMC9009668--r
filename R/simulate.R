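#' Simulate a market survey with ground truth
#'
#' Draws one purchased sample per design slot: the commercial name comes
#' from the design's per-name counts; with the name's mislabeling
#' probability the sample's true species is a substitute drawn from the
#' substitution weights re-normalized over species *not* accepted under the
#' name (union of catalogs), otherwise an accepted species drawn by supply
#' weight. The barcode sequence is the species anchor mutated at a
#' within-species divergence drawn uniformly from
#' `[0, design$intra_divergence]`. Everything is reproducible from `seed`.
#'
#' @param pool A [species_pool()].
#' @param design A [survey_design()].
#' @param catalogs List of [catalog()] objects (the generating truth).
#' @param library_set A `reference_library_set` from
#'   [generate_reference_library()] built on the same pool.
#' @param seed Optional integer seed.
#' @return A list with `samples` (tibble: `sample_id`, `city`,
#'   `vendor_type`, `name_source`, `commercial_name`, `price_mxn`,
#'   `sequence`) and `truth` (tibble: `sample_id`, `true_species`,
#'   `true_mislabel`), plus the per-name true probabilities as
#'   `attr(truth, "mislabel_prob")`.
#' @export
simulate_survey <- function(pool, design, catalogs, library_set, seed = NULL) {
  pool <- species_pool(pool)
  stopifnot(inherits(design, "survey_design"))
  local_seed(seed)
  anchors <- library_set$anchors
  if (!all(pool$species %in% anchors$species)) {
    stop("library set lacks anchors for some pool species", call. = FALSE)
  }
  map <- catalog_union(catalogs)
  unknown <- setdiff(
    setdiff(normalize_name(names(design$name_counts)), design$generic_names),
    map$commercial_name
  )
  if (length(unknown) > 0L) {
    stop("design names in no catalog and not generic: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  supply <- setNames(pool$supply_weight, pool$species)
  sub_weights_for <- function(name, accepted) {
    if (!is.null(design$substitution_weights) &&
      name %in% rownames(design$substitution_weights)) {
      w <- design$substitution_weights[name, ]
      w <- setNames(as.numeric(w), colnames(design$substitution_weights))
    } else {
      w <- supply^(design$substitution_gamma %||% 1)
    }
    w <- w[setdiff(names(w), accepted)]
    w[w > 0]
  }

  names_vec <- rep(names(design$name_counts), design$name_counts)
  n <- length(names_vec)
  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    raw_name <- names_vec[i]
    name <- normalize_name(raw_name)
    generic <- name %in% design$generic_names
    accepted <- if (generic) character() else map$species[map$commercial_name == name]
    p <- if (raw_name %in% names(design$mislabel_prob)) {
      unname(design$mislabel_prob[[raw_name]])
    } else {
      0
    }
    mislabel <- !generic && runif(1L) < p
    if (mislabel) {
      w <- sub_weights_for(name, accepted)
      if (length(w) == 0L) {
        stop("name '", name, "' has mislabel probability > 0 but no ",
          "substitute support",
          call. = FALSE
        )
      }
      true_species <- sample(names(w), 1L, prob = w)
    } else {
      choices <- if (generic) supply else supply[accepted]
      choices <- choices[choices > 0]
      if (length(choices) == 0L) {
        stop("name '", name, "' has no accepted species with supply",
          call. = FALSE
        )
      }
      true_species <- sample(names(choices), 1L, prob = choices)
    }
    unidentifiable <- runif(1L) < design$unidentifiable_rate
    sequence <- if (unidentifiable) {
      random_clean_sequence(nchar(anchors$sequence[1L]))
    } else {
      anchor <- anchors$sequence[anchors$species == true_species]
      mutate_sequence(anchor, runif(1L, 0, design$intra_divergence))
    }
    rows[[i]] <- tibble::tibble(
      sample_id = sprintf("S%04d", i),
      city = sample(design$cities, 1L, prob = design$city_weights),
      vendor_type = sample(design$vendor_types, 1L, prob = design$vendor_weights),
      name_source = sample(design$name_sources, 1L, prob = design$source_weights),
      commercial_name = name,
      price_mxn = round(exp(rnorm(1L, mean = 5, sd = 0.5)), 2),
      sequence = sequence
    )
    truth_rows[[i]] <- tibble::tibble(
      sample_id = sprintf("S%04d", i),
      true_species = true_species,
      true_mislabel = mislabel,
      unidentifiable = unidentifiable
    )
  }
  samples <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truth_rows)
  attr(truth, "mislabel_prob") <- design$mislabel_prob
  list(samples = samples, truth = truth)
}
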