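#' Verify an uninterrupted reading frame
#'
#' A functional COI barcode should contain no stop codon in at least one
#' forward reading frame under the vertebrate mitochondrial genetic code.
#' Only complete codons are examined; codons containing ambiguity codes are
#' not counted as stops.
#'
#' @param sequence DNA string (IUPAC alphabet), length >= 100.
#' @return List with `pass` (logical) and `frame` (lowest passing frame
#'   1..3, or `NA` on failure).
#' @export
check_reading_frame <- function(sequence) {
  chars <- seq_chars(sequence)
  if (any(!chars %in% c(DNA_BASES, "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"))) {
    stop("non-IUPAC characters in sequence", call. = FALSE)
  }
  if (length(chars) < 100L) {
    stop("sequence too short for a reading-frame check (< 100 bp)",
      call. = FALSE
    )
  }
  for (frame in 1:3) {
    usable <- length(chars) - frame + 1L
    n_codons <- usable %/% 3L
    if (n_codons == 0L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L)
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    if (!any(codons %in% MITO_STOP_CODONS)) {
      return(list(pass = TRUE, frame = frame))
    }
  }
  list(pass = FALSE, frame = NA_integer_)
}

# scoring used throughout: match +1, mismatch -1, linear gap -2. Terminal
# gaps are free on the longer sequence only: the shorter sequence must be
# contained in the alignment. Fully ends-free alignment under this scoring
# degenerates to short perfect overlaps (rating unrelated sequences 100%),
# so containment is required for identity to rank relatives above
# strangers. Identity excludes the free terminal-gap columns and counts
# internal gap columns as non-matches (PID1).
the_matrix_cache <- new.env(parent = emptyenv())
identity_substitution_matrix <- function() {
  if (is.null(the_matrix_cache$m)) {
    the_matrix_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA"
    )
  }
  the_matrix_cache$m
}

# percent identity of one query (given orientation) against many references,
# aligning the full query into each reference ("local-global": reference
# ends free); falls back to the symmetric pairwise path when the query is
# longer than a reference
identity_one_strand <- function(query, references) {
  longer <- nchar(references) >= nchar(query)
  out <- numeric(length(references))
  if (any(longer)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(references[longer]),
      subject = Biostrings::DNAString(query),
      type = "local-global",
      substitutionMatrix = identity_substitution_matrix(),
      gapOpening = 0, gapExtension = 2
    )
    out[longer] <- Biostrings::pid(aln, type = "PID1")
  }
  if (any(!longer)) {
    out[!longer] <- vapply(references[!longer], function(ref) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(query),
        subject = Biostrings::DNAString(ref),
        type = "local-global",
        substitutionMatrix = identity_substitution_matrix(),
        gapOpening = 0, gapExtension = 2
      )
      Biostrings::pid(aln, type = "PID1")
    }, numeric(1L))
  }
  out
}

#' Percent identity between two barcode sequences
#'
#' Global alignment with free terminal gaps on the longer sequence (match
#' +1, mismatch -1, linear gap -2): the shorter sequence is aligned in full,
#' so a 550-bp barcode is compared against full-length references without
#' penalizing the length difference, while unrelated sequences cannot score
#' high via a short perfect overlap. Identity is
#' `100 * matches / aligned columns`, with the free terminal-gap columns
#' excluded from the denominator and internal gap columns counted as
#' non-matches; the function is symmetric in its arguments. Both the
#' forward query and its reverse complement are aligned and the better
#' strand is reported, so queries need not be oriented.
#'
#' @param query,reference Non-empty DNA strings.
#' @param with_strand If `TRUE`, return a list with `identity` and `strand`
#'   (`"forward"` or `"reverse-complement"`); otherwise the identity alone.
#' @return Percent identity in `[0, 100]` (or a list, see `with_strand`).
#' @export
pairwise_identity <- function(query, reference, with_strand = FALSE) {
  stopifnot(nzchar(query), nzchar(reference))
  fwd <- identity_one_strand(query, reference)
  rev <- identity_one_strand(revcomp(query), reference)
  if (!with_strand) {
    return(max(fwd, rev))
  }
  if (fwd >= rev) {
    list(identity = fwd, strand = "forward")
  } else {
    list(identity = rev, strand = "reverse-complement")
  }
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# k-mer index of a library: named list kmer -> integer entry rows
index_library <- function(library, kmer = 12L) {
  seqs <- toupper(library$entries$sequence)
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s) - kmer + 1L
    if (n < 1L) {
      return(character())
    }
    unique(substring(s, seq_len(n), seq_len(n) + kmer - 1L))
  })
  df <- data.frame(
    kmer = unlist(kmers),
    entry = rep(seq_along(seqs), lengths(kmers))
  )
  idx <- split(df$entry, df$kmer)
  structure(idx, kmer = kmer)
}

# candidate entry rows sharing at least one k-mer with the query (either
# strand); integer(0) when nothing is shared
prefilter_candidates <- function(query, index) {
  kmer <- attr(index, "kmer")
  hits <- integer()
  for (q in c(toupper(query), revcomp(query))) {
    n <- nchar(q) - kmer + 1L
    if (n < 1L) next
    qk <- unique(substring(q, seq_len(n), seq_len(n) + kmer - 1L))
    hits <- c(hits, unlist(index[intersect(qk, names(index))], use.names = FALSE))
  }
  sort(unique(hits))
}

#' Search a reference library for a query barcode
#'
#' Ranks library entries by [pairwise_identity()] (descending, stable tie
#' order by accession). A k-mer prefilter (default 12-mers, either strand)
#' prunes entries sharing no k-mer with the query; by construction any
#' pruned entry shares no 12-mer with the query on either strand, and on
#' barcode-like data this never changes the top hit relative to exhaustive
#' search (a tested invariant).
#'
#' @param query DNA string.
#' @param library A [reference_library()].
#' @param k Number of hits to return (>= 1).
#' @param kmer k-mer size of the prefilter.
#' @param prefilter Set `FALSE` to force exhaustive search.
#' @param index Optional precomputed [index_library()] result (internal
#'   speed-up for batch identification).
#' @return Tibble of hits: `accession`, `species`, `identity`, `library`,
#'   `strand`, at most `k` rows; zero rows when no entry shares a k-mer.
#' @export
search_library <- function(query, library, k = 5L, kmer = 12L,
                           prefilter = TRUE, index = NULL) {
  stopifnot(inherits(library, "reference_library"), k >= 1L)
  entries <- library$entries
  if (nrow(entries) == 0L) {
    stop("empty reference library: ", library$tag, call. = FALSE)
  }
  rows <- seq_len(nrow(entries))
  if (prefilter) {
    if (is.null(index)) {
      index <- index_library(library, kmer)
    }
    rows <- prefilter_candidates(query, index)
    if (length(rows) == 0L) {
      return(tibble::tibble(
        accession = character(), species = character(),
        identity = numeric(), library = character(), strand = character()
      ))
    }
  }
  fwd <- identity_one_strand(query, entries$sequence[rows])
  rev <- identity_one_strand(revcomp(query), entries$sequence[rows])
  identity <- pmax(fwd, rev)
  strand <- ifelse(fwd >= rev, "forward", "reverse-complement")
  hits <- tibble::tibble(
    accession = entries$accession[rows],
    species = entries$species[rows],
    identity = identity,
    library = library$tag,
    strand = strand
  )
  hits <- hits[order(-hits$identity, hits$accession), ]
  head(hits, k)
}

#' Consensus species assignment across reference libraries
#'
#' Implements the threshold-consensus rule used for COI identifications:
#' a species-level call requires best identity of at least `threshold`
#' percent; libraries that agree on the species confirm it; libraries that
#' agree only at the genus level yield the single species with the highest
#' identity overall (noted); an exact within-library tie (identities equal
#' after rounding to 0.01%) yields a multi-species candidate set; a
#' cross-library conflict at different genera keeps both species (noted);
#' and below the threshold the call degrades to genus-level confidence
#' (best identity >= `genus_floor`) or `unidentified`. Libraries whose best
#' hit falls below `threshold` abstain when another library meets it.
#'
#' @param per_library_hits Named list (library tag -> ranked hit tibble from
#'   [search_library()]).
#' @param threshold Species-level identity threshold, percent (default 98).
#' @param genus_floor Genus-level identity floor, percent (default 90).
#' @param sample_id Optional sample identifier carried into the result.
#' @return One-row tibble: `sample_id`, `candidates` (`;`-joined, ranked by
#'   identity then alphabetical), `best_identity`, `confidence`
#'   (`species` / `genus` / `unidentified`), one `best_<tag>` column per
#'   library (`accession@identity`), and `notes`.
#' @export
consensus_assign <- function(per_library_hits, threshold = 98,
                             genus_floor = 90, sample_id = NA_character_) {
  stopifnot(length(per_library_hits) >= 1L)
  tags <- names(per_library_hits)
  if (is.null(tags)) {
    tags <- paste0("lib", seq_along(per_library_hits))
    names(per_library_hits) <- tags
  }
  best <- lapply(per_library_hits, function(h) {
    if (is.null(h) || nrow(h) == 0L) {
      return(NULL)
    }
    top <- round(h$identity[1L], 2)
    tied <- h[round(h$identity, 2) == top, , drop = FALSE]
    list(
      species = h$species[1L], identity = h$identity[1L],
      accession = h$accession[1L],
      tied_species = sort(unique(tied$species))
    )
  })
  lib_cols <- setNames(
    lapply(tags, function(tg) {
      b <- best[[tg]]
      if (is.null(b)) NA_character_ else sprintf("%s@%.2f", b$accession, b$identity)
    }),
    paste0("best_", tags)
  )
  result <- function(candidates, confidence, best_identity, notes) {
    tibble::tibble(
      sample_id = as.character(sample_id),
      candidates = paste(candidates, collapse = ";"),
      best_identity = best_identity,
      confidence = confidence,
      !!!lib_cols,
      notes = paste(notes, collapse = "; ")
    )
  }
  nonempty <- best[!vapply(best, is.null, logical(1L))]
  if (length(nonempty) == 0L) {
    return(result(character(), "unidentified", NA_real_, "no hits in any library"))
  }
  overall_best <- max(vapply(nonempty, `[[`, numeric(1L), "identity"))
  qualifying <- nonempty[vapply(nonempty, function(b) b$identity >= threshold, logical(1L))]
  notes <- character()
  if (length(qualifying) > 0L) {
    if (length(qualifying) < length(per_library_hits)) {
      notes <- c(notes, sprintf(
        "%d librar%s below threshold or empty",
        length(per_library_hits) - length(qualifying),
        if (length(per_library_hits) - length(qualifying) == 1L) "y" else "ies"
      ))
    }
    tie_sets <- lapply(qualifying, `[[`, "tied_species")
    has_tie <- any(lengths(tie_sets) >= 2L)
    if (has_tie) {
      candidates <- sort(unique(unlist(tie_sets)))
      # order by best identity across libraries, ties alphabetical
      cand_identity <- vapply(candidates, function(sp) {
        max(vapply(qualifying, function(b) {
          if (sp %in% b$tied_species) b$identity else -Inf
        }, numeric(1L)))
      }, numeric(1L))
      candidates <- candidates[order(-cand_identity, candidates)]
      return(result(
        candidates, "species", overall_best,
        c(notes, "identical top identity to multiple species")
      ))
    }
    species <- vapply(qualifying, `[[`, character(1L), "species")
    if (length(unique(species)) == 1L) {
      return(result(unique(species), "species", overall_best, notes))
    }
    genera <- genus_token(species)
    identities <- vapply(qualifying, `[[`, numeric(1L), "identity")
    if (length(unique(genera)) == 1L) {
      pick <- species[which.max(identities)]
      return(result(
        pick, "species", overall_best,
        c(notes, "libraries agree at genus level; highest identity kept")
      ))
    }
    candidates <- unique(species[order(-identities, species)])
    return(result(
      candidates, "species", overall_best,
      c(notes, "library conflict: best species in different genera")
    ))
  }
  # no library reaches the threshold
  if (overall_best >= genus_floor) {
    all_best <- nonempty[[which.max(vapply(nonempty, `[[`, numeric(1L), "identity"))]]
    return(result(
      all_best$species, "genus", overall_best,
      "best identity below species threshold; genus-level only"
    ))
  }
  result(character(), "unidentified", overall_best, "best identity below genus floor")
}

#' Identify a batch of query barcodes
#'
#' Runs [search_library()] against every library and combines the ranked
#' hits with [consensus_assign()], one row per query.
#'
#' @param samples Tibble with `sample_id` and `sequence` columns (e.g. the
#'   `samples` element of [simulate_survey()]).
#' @param libraries List of [reference_library()] objects (or a
#'   `reference_library_set`, whose libraries are used).
#' @param threshold,genus_floor Passed to [consensus_assign()].
#' @param k,kmer,prefilter Passed to [search_library()].
#' @return Tibble of identification results, one row per sample.
#' @export
identify_samples <- function(samples, libraries, threshold = 98,
                             genus_floor = 90, k = 5L, kmer = 12L,
                             prefilter = TRUE) {
  if (inherits(libraries, "reference_library_set")) {
    libraries <- libraries$libraries
  }
  if (inherits(libraries, "reference_library")) {
    libraries <- list(libraries)
  }
  tags <- vapply(libraries, `[[`, character(1L), "tag")
  names(libraries) <- tags
  indexes <- lapply(libraries, index_library, kmer = kmer)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "sequence") %in% names(samples)))
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    hits <- lapply(tags, function(tg) {
      search_library(samples$sequence[i], libraries[[tg]],
        k = k, kmer = kmer,
        prefilter = prefilter, index = indexes[[tg]]
      )
    })
    names(hits) <- tags
    consensus_assign(hits,
      threshold = threshold, genus_floor = genus_floor,
      sample_id = samples$sample_id[i]
    )
  })
  dplyr::bind_rows(rows)
}
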