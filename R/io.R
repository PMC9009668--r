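#' File readers and writers
#'
#' Tabular data uses tab-delimited UTF-8 with "." decimals as the canonical
#' dialect; CSV is accepted on input, auto-detected by extension. Sequences
#' use FASTA with `lib|accession|Genus_epithet` headers. Species are
#' serialized as `"Genus epithet"` and multi-candidate sets `;`-joined.
#'
#' @name fishaudit-io
NULL

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read and validate a survey sample table
#'
#' Required columns: `sample_id` (unique), `city`, `vendor_type` (one of
#' `fish_market` / `grocery_store` / `restaurant`), `name_source` (one of
#' `label` / `menu` / `verbal`), `commercial_name`. Violations are reported
#' together, with offending ids or row numbers.
#'
#' @param path TSV or CSV file with a header.
#' @return Validated tibble of survey samples.
#' @export
read_survey_table <- function(path) {
  tab <- read_delim_auto(path)
  problems <- character()
  required <- c(
    "sample_id", "city", "vendor_type", "name_source", "commercial_name"
  )
  absent <- setdiff(required, names(tab))
  if (length(absent) > 0L) {
    stop("missing required columns: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
  if (length(dup) > 0L) {
    problems <- c(problems, paste0(
      "duplicated sample ids: ", paste(dup, collapse = ", ")
    ))
  }
  bad_vendor <- which(!tab$vendor_type %in% VENDOR_TYPES)
  if (length(bad_vendor) > 0L) {
    problems <- c(problems, paste0(
      "unknown vendor_type in rows: ", paste(bad_vendor, collapse = ", ")
    ))
  }
  bad_source <- which(!tab$name_source %in% NAME_SOURCES)
  if (length(bad_source) > 0L) {
    problems <- c(problems, paste0(
      "unknown name_source in rows: ", paste(bad_source, collapse = ", ")
    ))
  }
  if (length(problems) > 0L) {
    stop("invalid survey table:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  tab
}

#' @rdname fishaudit-io
#' @param path Destination/ source path.
#' @param library A [reference_library()] to write.
#' @export
write_library_fasta <- function(library, path) {
  stopifnot(inherits(library, "reference_library"))
  seqs <- Biostrings::DNAStringSet(library$entries$sequence)
  names(seqs) <- sprintf(
    "%s|%s|%s", library$tag, library$entries$accession,
    gsub(" ", "_", library$entries$species, fixed = TRUE)
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname fishaudit-io
#' @export
read_library_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed FASTA headers (want lib|accession|Genus_epithet): ",
      paste(names(seqs)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  tags <- vapply(parts, `[[`, character(1L), 1L)
  if (length(unique(tags)) != 1L) {
    stop("one FASTA file must hold a single library tag", call. = FALSE)
  }
  reference_library(tags[1L], tibble::tibble(
    accession = vapply(parts, `[[`, character(1L), 2L),
    species = gsub("_", " ", vapply(parts, `[[`, character(1L), 3L), fixed = TRUE),
    sequence = unname(as.character(seqs))
  ))
}

#' @rdname fishaudit-io
#' @param queries Tibble with `sample_id`, `sequence`.
#' @export
write_query_fasta <- function(queries, path) {
  seqs <- Biostrings::DNAStringSet(queries$sequence)
  names(seqs) <- queries$sample_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname fishaudit-io
#' @export
read_query_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    sample_id = names(seqs),
    sequence = unname(as.character(seqs))
  )
}

#' Read catalogs from a three-column TSV
#'
#' Expected columns: `catalog_tag`, `commercial_name`, `species`; one
#' [catalog()] is built per tag.
#'
#' @param path TSV/CSV path.
#' @return List of [catalog()] objects.
#' @export
read_catalog_tsv <- function(path) {
  tab <- read_delim_auto(path)
  required <- c("catalog_tag", "commercial_name", "species")
  if (!all(required %in% names(tab))) {
    stop("catalog file needs columns: ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  lapply(split(tab, tab$catalog_tag), function(chunk) {
    catalog(chunk$catalog_tag[1L], chunk[, c("commercial_name", "species")])
  })
}

#' @rdname fishaudit-io
#' @param catalogs List of [catalog()] objects to serialize.
#' @export
write_catalog_tsv <- function(catalogs, path) {
  rows <- dplyr::bind_rows(lapply(catalogs, function(ct) {
    tibble::tibble(catalog_tag = ct$tag, ct$mapping)
  }))
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname fishaudit-io
#' @details `read_landings_table()` expects `commercial_name`, `tons` and
#'   optionally `year`; `read_status_table()` expects `species`,
#'   `iucn_category` and optionally `cites_appendix`.
#' @export
read_landings_table <- function(path) {
  tab <- read_delim_auto(path)
  if (!all(c("commercial_name", "tons") %in% names(tab))) {
    stop("landings file needs columns `commercial_name`, `tons`",
      call. = FALSE
    )
  }
  tab
}

#' @rdname fishaudit-io
#' @export
read_status_table <- function(path) {
  tab <- read_delim_auto(path)
  if (!all(c("species", "iucn_category") %in% names(tab))) {
    stop("status file needs columns `species`, `iucn_category`",
      call. = FALSE
    )
  }
  tab
}

#' Run configuration
#'
#' Reads a YAML configuration holding input paths, thresholds and the seed;
#' missing optional inputs (landings, status table) disable the
#' corresponding stage. Defaults mirror the argument defaults of the
#' underlying functions.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @param overrides Named list applied on top of the file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- list(
    queries = NULL, libraries = NULL, survey = NULL, catalogs = NULL,
    landings = NULL, status = NULL, out_dir = "fishaudit-report",
    threshold = 98, genus_floor = 90, min_verbal = 6L, alpha = 0.05,
    generic_names = "pescado", seed = 1L, verbosity = 1L
  )
  if (!is.null(path)) {
    from_file <- yaml::read_yaml(path)
    config[names(from_file)] <- from_file
  }
  config[names(overrides)] <- overrides
  with(config, {
    stopifnot(
      threshold > 0, threshold <= 100, genus_floor >= 0,
      genus_floor <= threshold, min_verbal >= 0, alpha > 0, alpha < 1
    )
  })
  structure(config, class = "run_config")
}

#' Write the report bundle of a completed run
#'
#' Emits the audit table, substitution edge list (TSV and JSON), category
#' matrix, per-stratum rates and tests, regression table, and a manifest
#' (configuration, seed, input checksums) for reproducibility. The output
#' directory is created first; an unwritable path fails before any file is
#' written.
#'
#' @param audits Audit tibble ([audit_names()]).
#' @param network Network list ([build_network()]).
#' @param stats_list Named list with optional elements `strata` (named list
#'   of [stratified_rates()] results), `regressions` (tibble of [ols_fit()]
#'   rows), `category` ([category_matrix()] result).
#' @param path Output directory.
#' @param config Optional `run_config` recorded in the manifest.
#' @param input_files Optional character vector of input paths to checksum.
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(audits, network, stats_list = list(), path,
                         config = NULL, input_files = character()) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, mode = 2L) != 0L) {
    stop("output path is not writable: ", path, call. = FALSE)
  }
  readr::write_tsv(audits, file.path(path, "audits.tsv"))
  readr::write_tsv(network$edges, file.path(path, "edges.tsv"))
  jsonlite::write_json(
    list(
      edges = network$edges,
      n_substitute_species = network$n_substitute_species,
      n_substituted_names = network$n_substituted_names,
      n_unique_combinations = network$n_unique_combinations
    ),
    file.path(path, "edges.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(stats_list$category)) {
    cm <- stats_list$category
    cm_tab <- tibble::tibble(
      substitute_category = rep(rownames(cm$counts), ncol(cm$counts)),
      labeled_name_category = rep(colnames(cm$counts), each = nrow(cm$counts)),
      count = as.vector(cm$counts),
      percentage = as.vector(cm$percentages)
    )
    readr::write_tsv(cm_tab, file.path(path, "category_matrix.tsv"))
  }
  if (!is.null(stats_list$strata)) {
    for (nm in names(stats_list$strata)) {
      readr::write_tsv(
        stats_list$strata[[nm]]$rates,
        file.path(path, sprintf("rates_%s.tsv", nm))
      )
      readr::write_tsv(
        stats_list$strata[[nm]]$tests,
        file.path(path, sprintf("tests_%s.tsv", nm))
      )
    }
  }
  if (!is.null(stats_list$regressions)) {
    readr::write_tsv(stats_list$regressions, file.path(path, "regressions.tsv"))
  }
  existing <- input_files[file.exists(input_files)]
  manifest <- list(
    package = "fishaudit",
    version = as.character(utils::packageVersion("fishaudit")),
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config)) unclass(config) else NULL,
    input_checksums = as.list(tools::md5sum(existing)),
    files = list.files(path)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}
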