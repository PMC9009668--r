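#' Normalize a commercial name
#'
#' Case-folds, strips diacritics, and collapses surrounding/duplicate
#' whitespace, so that vendor spellings like `"Róbalo "` and `"robalo"`
#' compare equal. Vectorized and idempotent.
#'
#' @param raw Character vector of raw commercial names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_name(c("Róbalo ", "HUACHINANGO", "mero  "))
#' @export
normalize_name <- function(raw) {
  if (length(raw) == 0L) {
    return(character())
  }
  if (!is.character(raw) || any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("commercial names must be non-empty strings", call. = FALSE)
  }
  out <- stringi::stri_trans_general(raw, "Latin-ASCII")
  out <- tolower(trimws(out))
  gsub("[[:space:]]+", " ", out)
}

#' Commercial-name catalog
#'
#' A catalog maps normalized commercial names to the set of species accepted
#' under each name. Mislabeling is established against the union of several
#' catalogs: a sample is mislabeled only if its identified species is
#' accepted under its commercial name in none of them.
#'
#' @param tag Short catalog name.
#' @param mapping Data frame with columns `commercial_name` and `species`.
#' @return An object of class `name_catalog`.
#' @export
catalog <- function(tag, mapping) {
  mapping <- tibble::as_tibble(mapping)
  if (!all(c("commercial_name", "species") %in% names(mapping))) {
    stop("catalog mapping needs columns `commercial_name`, `species`",
      call. = FALSE
    )
  }
  mapping$commercial_name <- normalize_name(mapping$commercial_name)
  mapping <- dplyr::distinct(mapping[, c("commercial_name", "species")])
  structure(list(tag = tag, mapping = mapping), class = "name_catalog")
}

#' @export
print.name_catalog <- function(x, ...) {
  cat("<name_catalog '", x$tag, "': ", length(unique(x$mapping$commercial_name)),
    " names, ", nrow(x$mapping), " name-species pairs>\n",
    sep = ""
  )
  invisible(x)
}

# union of catalog mappings as one tibble (commercial_name, species)
catalog_union <- function(catalogs) {
  stopifnot(length(catalogs) >= 1L)
  maps <- lapply(catalogs, function(ct) {
    if (!inherits(ct, "name_catalog")) {
      stop("`catalogs` must be a list of catalog() objects", call. = FALSE)
    }
    ct$mapping
  })
  dplyr::distinct(dplyr::bind_rows(maps))
}

# species accepted under `name` in any catalog; character(0) if the name is
# listed but empty, NULL if the name is unknown to every catalog
accepted_species <- function(name, catalogs) {
  map <- catalog_union(catalogs)
  name <- normalize_name(name)
  if (!name %in% map$commercial_name) {
    return(NULL)
  }
  map$species[map$commercial_name == name]
}

#' Does any catalog accept a species under a commercial name?
#'
#' Union (logical OR) semantics across catalogs. An unknown commercial name
#' (present in no catalog) is a distinguished outcome, returned as `NA`
#' rather than `FALSE`, and is surfaced in label-call notes downstream.
#'
#' @param name Commercial name (normalized internally).
#' @param species Scientific name `"Genus epithet"`.
#' @param catalogs Non-empty list of [catalog()] objects.
#' @return `TRUE`, `FALSE`, or `NA` (unknown name).
#' @export
match_catalogs <- function(name, species, catalogs) {
  acc <- accepted_species(name, catalogs)
  if (is.null(acc)) {
    return(NA)
  }
  species %in% acc
}

#' Call one sample correct or mislabeled
#'
#' Applies the union-of-catalogs rule to one sample's identification:
#' generic names are excluded, unidentified samples are excluded, and a
#' multi-species (tied) identification counts as correct if *any* candidate
#' is accepted under the name. When mislabeled, the substitute species is
#' the highest-identity candidate (alphabetical on exact ties, which is the
#' candidate order produced by identification).
#'
#' @param sample_id Sample identifier.
#' @param commercial_name Raw commercial name as provided by the vendor.
#' @param identification One row of [identify_samples()] output (or a list
#'   with `candidates` `;`-joined, `best_identity`, `confidence`).
#' @param catalogs List of [catalog()] objects.
#' @param generic_names Character vector of generic names to exclude.
#' @return One-row tibble with fields `sample_id`, `commercial_name`,
#'   `status` (`correct` / `mislabeled` / `excluded_generic` /
#'   `excluded_unidentified`), `candidates`, `substitute_species`, `notes`.
#' @export
call_sample <- function(sample_id, commercial_name, identification, catalogs,
                        generic_names = character()) {
  name <- normalize_name(commercial_name)
  generic_names <- normalize_name(generic_names)
  candidates <- strsplit(identification$candidates %||% "", ";", fixed = TRUE)[[1L]]
  notes <- character()
  if (name %in% generic_names) {
    status <- "excluded_generic"
    substitute <- NA_character_
  } else if (identification$confidence == "unidentified") {
    status <- "excluded_unidentified"
    substitute <- NA_character_
  } else {
    if (identification$confidence == "genus") {
      notes <- c(notes, "genus-level identification")
    }
    matches <- vapply(candidates, match_catalogs,
      FUN.VALUE = NA, name = name, catalogs = catalogs
    )
    if (all(is.na(matches))) {
      notes <- c(notes, "unknown commercial name")
      status <- "unknown_name"
      substitute <- NA_character_
    } else if (any(matches, na.rm = TRUE)) {
      status <- "correct"
      substitute <- NA_character_
    } else {
      status <- "mislabeled"
      substitute <- candidates[1L] # ranked by identity, ties alphabetical
    }
  }
  tibble::tibble(
    sample_id = as.character(sample_id),
    commercial_name = name,
    status = status,
    candidates = paste(candidates, collapse = ";"),
    substitute_species = substitute,
    notes = paste(notes, collapse = "; ")
  )
}

#' Call every sample in a survey
#'
#' Joins a survey table to its identifications and applies [call_sample()]
#' row-wise, carrying the stratum columns (city, vendor type, name source)
#' through for downstream stratified rates.
#'
#' @param samples Survey table with `sample_id`, `commercial_name` and
#'   optionally `city`, `vendor_type`, `name_source`.
#' @param identifications Output of [identify_samples()].
#' @param catalogs List of [catalog()] objects.
#' @param generic_names Generic names to exclude.
#' @return Tibble of label calls, one row per sample.
#' @export
call_samples <- function(samples, identifications, catalogs,
                         generic_names = character()) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "commercial_name") %in% names(samples)))
  ids <- tibble::as_tibble(identifications)
  missing <- setdiff(samples$sample_id, ids$sample_id)
  if (length(missing) > 0L) {
    stop("no identification for samples: ",
      paste(head(missing, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(samples$sample_id, ids$sample_id)
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(samples)), function(i) {
    call_sample(
      samples$sample_id[i], samples$commercial_name[i],
      as.list(ids[idx[i], ]), catalogs, generic_names
    )
  }))
  for (col in intersect(c("city", "vendor_type", "name_source"), names(samples))) {
    calls[[col]] <- samples[[col]]
  }
  calls
}

`%||%` <- function(x, y) if (is.null(x)) y else x
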