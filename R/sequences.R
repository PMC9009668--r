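#' Simulated COI barcode sequences
#'
#' Helpers that build and perturb protein-coding mitochondrial sequences.
#' All generated sequences are kept free of in-frame stop codons under the
#' vertebrate mitochondrial genetic code in reading frame 1, emulating the
#' open-reading-frame structure of functional COI barcodes.
#'
#' @name coi-simulation
NULL

# split a DNA string into an uppercase character vector of bases
seq_chars <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
}

codon_of <- function(chars, pos) {
  start <- ((pos - 1L) %/% 3L) * 3L + 1L
  paste(chars[start:(start + 2L)], collapse = "")
}

# bases that can replace chars[pos] without creating a mito stop codon.
# For any non-stop codon at least one such base exists at every position
# (TAA/TAG leave TAT/TAC, AGA/AGG leave AGT/AGC, etc.).
safe_substitutions <- function(chars, pos) {
  current <- chars[pos]
  candidates <- setdiff(DNA_BASES, current)
  ok <- vapply(candidates, function(b) {
    tmp <- chars
    tmp[pos] <- b
    !(codon_of(tmp, pos) %in% MITO_STOP_CODONS)
  }, logical(1L))
  candidates[ok]
}

# random frame-clean sequence assembled codon by codon
random_clean_sequence <- function(length) {
  stopifnot(length %% 3L == 0L)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste,
    collapse = ""
  )
  codons <- setdiff(codons, MITO_STOP_CODONS)
  paste(sample(codons, length %/% 3L, replace = TRUE), collapse = "")
}

# substitute the bases at `positions` (all of them, exactly once), avoiding
# stop codons; used both by mutate_sequence() and the library generator
substitute_at <- function(chars, positions) {
  for (pos in positions) {
    choices <- safe_substitutions(chars, pos)
    chars[pos] <- if (length(choices) == 1L) choices else sample(choices, 1L)
  }
  chars
}

#' Mutate a barcode sequence to a controlled divergence
#'
#' Introduces exactly `round(divergence * nchar(reference))` base
#' substitutions (never indels) at positions drawn uniformly without
#' replacement. Replacement bases are drawn uniformly among the alternatives
#' that do not create a stop codon in frame 1 under the vertebrate
#' mitochondrial code, so the output stays frame-clean; at least one such
#' alternative always exists, so the requested substitution count is exact.
#'
#' @param reference A frame-clean DNA string (A/C/G/T, length divisible by 3).
#' @param divergence Proportion of positions to substitute, in `[0, 0.25]`.
#' @param seed Optional integer seed; the caller's RNG stream is restored on
#'   exit.
#' @return A DNA string of the same length as `reference`.
#' @examples
#' anchor <- fishaudit:::random_clean_sequence(300)
#' mutant <- mutate_sequence(anchor, 0.01, seed = 1)
#' sum(fishaudit:::seq_chars(anchor) != fishaudit:::seq_chars(mutant)) # 3
#' @export
mutate_sequence <- function(reference, divergence, seed = NULL) {
  local_seed(seed)
  chars <- seq_chars(reference)
  n <- length(chars)
  if (n %% 3L != 0L || !all(chars %in% DNA_BASES)) {
    stop("`reference` must be an A/C/G/T string with length divisible by 3",
      call. = FALSE
    )
  }
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.25) {
    stop("`divergence` must lie in [0, 0.25]", call. = FALSE)
  }
  if (check_reading_frame(reference)$frame != 1L) {
    stop("`reference` must be frame-clean in frame 1", call. = FALSE)
  }
  n_sub <- round(divergence * n)
  if (n_sub == 0L) {
    return(paste(chars, collapse = ""))
  }
  positions <- sample.int(n, n_sub)
  paste(substitute_at(chars, positions), collapse = "")
}

#' Reference barcode library
#'
#' A reference library is a tagged table of species-annotated barcode
#' records, emulating a "species-level barcode records" slice of a public
#' database such as GenBank or BOLD.
#'
#' @param tag Short library name (e.g. `"libA"`).
#' @param entries Data frame with columns `accession`, `species`
#'   (`"Genus epithet"`) and `sequence` (IUPAC DNA).
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(tag, entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("accession", "species", "sequence")
  if (!all(required %in% names(entries))) {
    stop("library entries need columns: ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(entries$accession)) {
    stop("accessions must be unique within a library", call. = FALSE)
  }
  if (any(!nzchar(entries$sequence))) {
    stop("library sequences must be non-empty", call. = FALSE)
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(entries$sequence))
  if (any(bad)) {
    stop("non-IUPAC characters in sequences of: ",
      paste(entries$accession[bad], collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(tag = tag, entries = entries), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("<reference_library '", x$tag, "': ", nrow(x$entries), " entries, ",
    length(unique(x$entries$species)), " species>\n",
    sep = ""
  )
  invisible(x)
}

genus_token <- function(species) {
  vapply(strsplit(species, " ", fixed = TRUE), `[[`, character(1L), 1L)
}

#' Generate species-anchored reference libraries
#'
#' Builds one frame-clean anchor sequence per species and replicates it into
#' `n_libraries` libraries (minus per-library dropouts). Species sharing a
#' genus token are derived from a common random genus ancestor, each mutated
#' on its own disjoint, interleaved set of positions, so congeners are more
#' similar to each other than to other genera while every inter-species pair
#' differs at at least `1.5 * min_interspecies_divergence * length`
#' scattered positions (which alignment gaps cannot bypass).
#'
#' @param pool A [species_pool()].
#' @param length Barcode length in bp; must be divisible by 3.
#' @param min_interspecies_divergence Minimum pairwise divergence between
#'   species anchors (> 0.02).
#' @param n_libraries Number of libraries to emit.
#' @param dropout_per_library Fraction of species absent from each library
#'   (`round(dropout * n_species)` species, drawn independently per library).
#' @param tags Optional library tags; defaults to `"libA"`, `"libB"`, ...
#' @param seed Optional integer seed.
#' @return A list of class `reference_library_set` with elements
#'   `libraries` (list of [reference_library()]) and `anchors` (tibble of
#'   `species`, `category`, `sequence`).
#' @export
generate_reference_library <- function(pool, length = 654L,
                                       min_interspecies_divergence = 0.05,
                                       n_libraries = 2L,
                                       dropout_per_library = 0,
                                       tags = NULL, seed = NULL) {
  pool <- species_pool(pool)
  local_seed(seed)
  if (length %% 3L != 0L) {
    stop("`length` must be divisible by 3", call. = FALSE)
  }
  if (min_interspecies_divergence <= 0.02) {
    stop("`min_interspecies_divergence` must exceed 0.02", call. = FALSE)
  }
  if (dropout_per_library < 0 || dropout_per_library >= 1) {
    stop("`dropout_per_library` must lie in [0, 1)", call. = FALSE)
  }
  block <- ceiling(0.75 * min_interspecies_divergence * length)
  genera <- split(pool$species, genus_token(pool$species))
  too_big <- vapply(genera, function(sp) length(sp) * block > length, logical(1L))
  if (any(too_big)) {
    stop(
      "divergence floor infeasible for genus size and sequence length: ",
      paste(names(genera)[too_big], collapse = ", "),
      call. = FALSE
    )
  }
  anchors <- character(nrow(pool))
  names(anchors) <- pool$species
  for (genus in names(genera)) {
    ancestor <- seq_chars(random_clean_sequence(length))
    members <- genera[[genus]]
    m <- length(members)
    stride <- length %/% block # >= m by the feasibility check
    for (i in seq_along(members)) {
      # disjoint position sets spread evenly over the whole sequence:
      # isolated single-base differences cannot be dodged by alignment
      # gaps or end clipping, so pairwise anchor identity stays at its
      # hamming value
      positions <- i + stride * (seq_len(block) - 1L)
      anchors[members[i]] <- paste(substitute_at(ancestor, positions),
        collapse = ""
      )
    }
  }
  if (is.null(tags)) {
    tags <- paste0("lib", LETTERS[seq_len(n_libraries)])
  }
  stopifnot(length(tags) == n_libraries)
  n_drop <- round(dropout_per_library * nrow(pool))
  libraries <- lapply(seq_len(n_libraries), function(i) {
    keep <- pool$species
    if (n_drop > 0L) {
      keep <- setdiff(keep, sample(pool$species, n_drop))
    }
    idx <- match(keep, pool$species)
    reference_library(
      tags[i],
      tibble::tibble(
        accession = sprintf("%s-%04d", tags[i], idx),
        species = keep,
        sequence = unname(anchors[keep])
      )
    )
  })
  names(libraries) <- tags
  structure(
    list(
      libraries = libraries,
      anchors = tibble::tibble(
        species = pool$species,
        category = pool$category,
        sequence = unname(anchors)
      )
    ),
    class = "reference_library_set"
  )
}
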