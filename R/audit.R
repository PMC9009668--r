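#' Per-name mislabeling and substitutability audits
#'
#' Computes, for every commercial name in a set of label calls, the full
#' mislabeling/substitutability accounting framework: verbal sample number,
#' correctly labeled samples, mislabeling frequency/percentage/diversity,
#' substitutability frequency/diversity, confirmed samples, and over/sub-
#' representation. The framework identities hold exactly in integer
#' arithmetic:
#' `verbal = correct + mislabeling_frequency`,
#' `confirmed = correct + substitutability_frequency`,
#' `over_sub = verbal - confirmed`.
#'
#' Substitutability credits a mislabeled call to the focal name whose
#' accepted-species set (union of catalogs) contains the call's substitute
#' species. When a species is accepted under several names, the event is
#' credited once, to the accepting name with the most verbal samples
#' (alphabetical on ties); `credit = "all"` credits every accepting name.
#'
#' @param calls Label-call tibble from [call_samples()].
#' @param catalogs List of [catalog()] objects (for accepted-species sets).
#' @param credit `"most_samples"` (default) or `"all"`.
#' @return Tibble of audits ordered by verbal sample number (descending,
#'   then alphabetical), one row per commercial name with a non-excluded
#'   call.
#' @export
audit_names <- function(calls, catalogs, credit = c("most_samples", "all")) {
  credit <- match.arg(credit)
  calls <- tibble::as_tibble(calls)
  active <- calls[calls$status %in% c("correct", "mislabeled"), , drop = FALSE]
  names_all <- sort(unique(active$commercial_name))
  verbal <- vapply(names_all, function(nm) {
    sum(active$commercial_name == nm)
  }, integer(1L))
  correct <- vapply(names_all, function(nm) {
    sum(active$commercial_name == nm & active$status == "correct")
  }, integer(1L))
  mis <- active[active$status == "mislabeled", , drop = FALSE]
  mis_freq <- vapply(names_all, function(nm) {
    sum(mis$commercial_name == nm)
  }, integer(1L))
  mis_div <- vapply(names_all, function(nm) {
    length(unique(mis$substitute_species[mis$commercial_name == nm]))
  }, integer(1L))

  # credit each mislabeled call's substitute species to focal name(s)
  map <- catalog_union(catalogs)
  sub_freq <- setNames(integer(length(names_all)), names_all)
  sub_names <- setNames(vector("list", length(names_all)), names_all)
  if (nrow(mis) > 0L) {
    for (i in seq_len(nrow(mis))) {
      sp <- mis$substitute_species[i]
      accepting <- intersect(map$commercial_name[map$species == sp], names_all)
      if (length(accepting) == 0L) next
      if (credit == "most_samples" && length(accepting) > 1L) {
        ord <- order(-verbal[accepting], accepting)
        accepting <- accepting[ord][1L]
      }
      for (nm in accepting) {
        sub_freq[nm] <- sub_freq[nm] + 1L
        sub_names[[nm]] <- c(sub_names[[nm]], mis$commercial_name[i])
      }
    }
  }
  sub_div <- vapply(sub_names, function(x) length(unique(x)), integer(1L))
  confirmed <- unname(correct + sub_freq)
  over_sub <- unname(verbal - confirmed)
  audits <- tibble::tibble(
    commercial_name = names_all,
    verbal_sample_number = unname(verbal),
    correctly_labeled = unname(correct),
    mislabeling_frequency = unname(mis_freq),
    mislabeling_percentage = unname(round_half_up(100 * mis_freq / verbal, 2)),
    mislabeling_diversity = unname(mis_div),
    substitutability_frequency = unname(sub_freq),
    substitutability_diversity = unname(sub_div),
    confirmed_samples = confirmed,
    over_sub_representation = over_sub,
    over_sub_representation_percentage = ifelse(
      confirmed == 0L, NA_real_, round_half_up(100 * over_sub / confirmed, 2)
    )
  )
  audits[order(-audits$verbal_sample_number, audits$commercial_name), ]
}

#' @rdname audit_names
#' @param focal A single commercial name; a name absent from the calls
#'   yields an all-zero audit row, not an error.
#' @export
audit_name <- function(focal, calls, catalogs, credit = "most_samples") {
  focal <- normalize_name(focal)
  audits <- audit_names(calls, catalogs, credit = credit)
  row <- audits[audits$commercial_name == focal, , drop = FALSE]
  if (nrow(row) == 1L) {
    return(row)
  }
  tibble::tibble(
    commercial_name = focal, verbal_sample_number = 0L,
    correctly_labeled = 0L, mislabeling_frequency = 0L,
    mislabeling_percentage = NA_real_, mislabeling_diversity = 0L,
    substitutability_frequency = 0L, substitutability_diversity = 0L,
    confirmed_samples = 0L, over_sub_representation = 0L,
    over_sub_representation_percentage = NA_real_
  )
}

#' Derive the audit identities from base counts
#'
#' Completes a partially specified audit table: given
#' `verbal_sample_number`, one of `correctly_labeled` /
#' `mislabeling_frequency`, and `substitutability_frequency`, fills in the
#' other base count and the derived cells (`mislabeling_percentage`,
#' `confirmed_samples`, `over_sub_representation` and its percentage).
#' Useful for auditing published summary tables without sample-level data.
#'
#' @param audits Data frame with at least `verbal_sample_number`,
#'   `substitutability_frequency`, and `correctly_labeled` or
#'   `mislabeling_frequency`.
#' @return The completed tibble.
#' @export
complete_audit_table <- function(audits) {
  audits <- tibble::as_tibble(audits)
  if (!"verbal_sample_number" %in% names(audits) ||
    !"substitutability_frequency" %in% names(audits)) {
    stop("need `verbal_sample_number` and `substitutability_frequency`",
      call. = FALSE
    )
  }
  if (!"correctly_labeled" %in% names(audits)) {
    audits$correctly_labeled <-
      audits$verbal_sample_number - audits$mislabeling_frequency
  }
  if (!"mislabeling_frequency" %in% names(audits)) {
    audits$mislabeling_frequency <-
      audits$verbal_sample_number - audits$correctly_labeled
  }
  stopifnot(all(
    audits$verbal_sample_number ==
      audits$correctly_labeled + audits$mislabeling_frequency
  ))
  audits$mislabeling_percentage <- round_half_up(
    100 * audits$mislabeling_frequency / audits$verbal_sample_number, 2
  )
  audits$confirmed_samples <-
    audits$correctly_labeled + audits$substitutability_frequency
  audits$over_sub_representation <-
    audits$verbal_sample_number - audits$confirmed_samples
  audits$over_sub_representation_percentage <- ifelse(
    audits$confirmed_samples == 0L, NA_real_,
    round_half_up(
      100 * audits$over_sub_representation / audits$confirmed_samples, 2
    )
  )
  audits
}

#' Substitution network behind the mislabeling calls
#'
#' One edge per (substitute species, commercial name) pair with its count;
#' edge counts sum to the number of mislabeled calls. A name's in-degree is
#' its mislabeling diversity; a species' out-degree is the number of names
#' it substituted.
#'
#' @param calls Label-call tibble.
#' @return List: `edges` (tibble `species`, `commercial_name`, `count`),
#'   `n_substitute_species`, `n_substituted_names`, `n_unique_combinations`.
#' @export
build_network <- function(calls) {
  mis <- calls[calls$status == "mislabeled", , drop = FALSE]
  if (nrow(mis) == 0L) {
    edges <- tibble::tibble(
      species = character(), commercial_name = character(), count = integer()
    )
    return(list(
      edges = edges, n_substitute_species = 0L,
      n_substituted_names = 0L, n_unique_combinations = 0L
    ))
  }
  edges <- dplyr::count(mis, .data$substitute_species, .data$commercial_name,
    name = "count"
  )
  edges <- tibble::tibble(
    species = edges$substitute_species,
    commercial_name = edges$commercial_name,
    count = as.integer(edges$count)
  )
  edges <- edges[order(-edges$count, edges$species, edges$commercial_name), ]
  list(
    edges = edges,
    n_substitute_species = length(unique(edges$species)),
    n_substituted_names = length(unique(edges$commercial_name)),
    n_unique_combinations = nrow(edges)
  )
}

#' Category-level substitution matrix
#'
#' Aggregates substitution edges into a 3x3 matrix over the broad origin
#' groups (wild marine bony fish, wild elasmobranch, freshwater/anadromous
#' aquaculture fish), oriented (substitute category, labeled-name category).
#'
#' @param edges Edge tibble from [build_network()].
#' @param species_category Named character vector: species -> category.
#' @param name_category Named character vector: commercial name -> category.
#' @return List with integer matrix `counts` and numeric matrix
#'   `percentages` (summing to 100 when any edge exists).
#' @export
category_matrix <- function(edges, species_category, name_category) {
  cats <- SPECIES_CATEGORIES
  counts <- matrix(0L, 3L, 3L, dimnames = list(
    substitute = cats, labeled_name = cats
  ))
  missing_sp <- setdiff(unique(edges$species), names(species_category))
  missing_nm <- setdiff(unique(edges$commercial_name), names(name_category))
  if (length(missing_sp) || length(missing_nm)) {
    stop(
      "unmapped species/names: ",
      paste(c(missing_sp, missing_nm), collapse = ", "),
      call. = FALSE
    )
  }
  for (i in seq_len(nrow(edges))) {
    c1 <- species_category[[edges$species[i]]]
    c2 <- name_category[[edges$commercial_name[i]]]
    counts[c1, c2] <- counts[c1, c2] + edges$count[i]
  }
  total <- sum(counts)
  percentages <- if (total > 0) 100 * counts / total else counts * 0
  list(counts = counts, percentages = percentages)
}

#' Restrict audits to focal commercial names
#'
#' @param audits Audit tibble from [audit_names()].
#' @param min_verbal Minimum verbal sample number (default 6).
#' @return The audits with `verbal_sample_number >= min_verbal`, ordered by
#'   verbal sample number descending.
#' @export
filter_focal_names <- function(audits, min_verbal = 6L) {
  out <- audits[audits$verbal_sample_number >= min_verbal, , drop = FALSE]
  out[order(-out$verbal_sample_number, out$commercial_name), ]
}

#' Conservation-status tally of identified species
#'
#' Joins identified species (the representative, highest-identity candidate
#' of each non-excluded call) to a user-supplied status table and tallies
#' samples and mislabels per species and per status class. Species absent
#' from the table are reported as `"unclassified"`.
#'
#' @param calls Label-call tibble.
#' @param status_table Data frame: `species`, `iucn_category`,
#'   `cites_appendix` (`NA` when not listed).
#' @return List: `species` (per-species tibble with status, samples,
#'   mislabels), `by_iucn` and `by_cites` (per-class totals), and
#'   `listed_rate` (percent mislabeled among IUCN-classified samples;
#'   `NA` if none).
#' @export
conservation_report <- function(calls, status_table) {
  status_table <- tibble::as_tibble(status_table)
  active <- calls[calls$status %in% c("correct", "mislabeled"), , drop = FALSE]
  rep_species <- vapply(
    strsplit(active$candidates, ";", fixed = TRUE),
    function(x) if (length(x)) x[1L] else NA_character_, character(1L)
  )
  per <- dplyr::count(
    tibble::tibble(
      species = rep_species,
      mislabeled = active$status == "mislabeled"
    ),
    .data$species,
    name = "n_samples"
  )
  per$n_mislabeled <- vapply(per$species, function(sp) {
    sum(rep_species == sp & active$status == "mislabeled")
  }, integer(1L))
  idx <- match(per$species, status_table$species)
  per$iucn_category <- ifelse(is.na(idx), "unclassified",
    as.character(status_table$iucn_category[idx])
  )
  per$cites_appendix <- if ("cites_appendix" %in% names(status_table)) {
    ifelse(is.na(idx), NA_character_,
      as.character(status_table$cites_appendix[idx])
    )
  } else {
    NA_character_
  }
  by_iucn <- dplyr::summarise(
    dplyr::group_by(per, .data$iucn_category),
    n_species = dplyr::n(),
    n_samples = sum(.data$n_samples),
    n_mislabeled = sum(.data$n_mislabeled),
    .groups = "drop"
  )
  cited <- per[!is.na(per$cites_appendix), , drop = FALSE]
  by_cites <- dplyr::summarise(
    dplyr::group_by(cited, .data$cites_appendix),
    n_species = dplyr::n(),
    n_samples = sum(.data$n_samples),
    n_mislabeled = sum(.data$n_mislabeled),
    .groups = "drop"
  )
  listed <- per[per$iucn_category != "unclassified", , drop = FALSE]
  listed_rate <- if (sum(listed$n_samples) > 0L) {
    round_half_up(100 * sum(listed$n_mislabeled) / sum(listed$n_samples), 1)
  } else {
    NA_real_
  }
  list(
    species = per[order(-per$n_samples, per$species), ],
    by_iucn = by_iucn, by_cites = by_cites, listed_rate = listed_rate
  )
}
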