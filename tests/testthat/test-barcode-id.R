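test_that("reading-frame checks find stops in all three frames", {
  anchor <- withr::with_seed(1, fishaudit:::random_clean_sequence(300L))
  res <- check_reading_frame(anchor)
  expect_true(res$pass)
  expect_equal(res$frame, 1L)
  # splice stops into every forward frame at codon 10
  chars <- strsplit(anchor, "")[[1]]
  chars[28:30] <- c("T", "A", "A")
  chars[32:34] <- c("T", "A", "G")
  chars[36:38] <- c("A", "G", "A")
  broken <- paste(chars, collapse = "")
  res2 <- check_reading_frame(broken)
  expect_false(res2$pass)
  expect_true(is.na(res2$frame))
  expect_error(check_reading_frame("ACGTXACGT"), "IUPAC")
})

test_that("pairwise identity matches its defining formula", {
  a <- withr::with_seed(2, fishaudit:::random_clean_sequence(600L))
  expect_equal(pairwise_identity(a, a), 100.0)
  b <- mutate_sequence(a, 0.01, seed = 3) # exactly 6 substitutions
  expect_equal(pairwise_identity(a, b), 99.0, tolerance = 1e-9)
  # symmetric, and strand-insensitive
  expect_equal(pairwise_identity(b, a), pairwise_identity(a, b))
  rc <- fishaudit:::revcomp(b)
  res <- pairwise_identity(rc, a, with_strand = TRUE)
  expect_equal(res$identity, 99.0, tolerance = 1e-9)
  expect_equal(res$strand, "reverse-complement")
})

test_that("pairwise identity agrees with the independent DP oracle", {
  withr::with_seed(4, {
    for (len in c(150L, 300L)) {
      for (div in c(0.02, 0.10)) {
        a <- fishaudit:::random_clean_sequence(len)
        b <- mutate_sequence(a, div)
        expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
          tolerance = 1e-6
        )
      }
    }
    # a truncated query against a full-length reference (length-tolerant)
    a <- fishaudit:::random_clean_sequence(654L)
    b <- mutate_sequence(a, 0.05)
    trimmed <- substr(b, 51, 600)
    expect_equal(
      pairwise_identity(trimmed, a), oracle_identity(trimmed, a),
      tolerance = 1e-6
    )
  })
})

test_that("library search ranks the query's own record first", {
  libset <- generate_reference_library(tiny_pool(), seed = 5)
  lib <- libset$libraries[[1]]
  hits <- search_library(lib$entries$sequence[3], lib, k = 3)
  expect_equal(hits$identity[1], 100.0)
  expect_equal(hits$accession[1], lib$entries$accession[3])
  expect_true(all(diff(hits$identity) <= 0))
  expect_error(
    search_library("ACGT", reference_library("x", tibble::tibble(
      accession = character(), species = character(), sequence = character()
    ))),
    "empty"
  )
})

test_that("a query sharing no k-mer with the library is flagged empty", {
  libset <- generate_reference_library(tiny_pool(), seed = 6)
  lib <- libset$libraries[[1]]
  alien <- paste(rep("ACGT", 40), collapse = "") # periodic, shares no 12-mer
  hits <- search_library(alien, lib)
  expect_equal(nrow(hits), 0L)
})

test_that("the k-mer prefilter never changes the top species", {
  corpus <- make_corpus(n_species = 50L, n_queries = 20L, seed = 77)
  lib <- corpus$libset$libraries[[1]]
  for (i in seq_len(nrow(corpus$queries))) {
    fast <- search_library(corpus$queries$sequence[i], lib, k = 3)
    slow <- search_library(corpus$queries$sequence[i], lib,
      k = 3,
      prefilter = FALSE
    )
    expect_equal(fast$species[1], slow$species[1])
    expect_equal(fast$identity[1], slow$identity[1], tolerance = 1e-9)
  }
})

test_that("self-identification recovers the true species on clean libraries", {
  corpus <- make_corpus(n_species = 50L, n_queries = 20L, seed = 99)
  ids <- identify_samples(corpus$queries, corpus$libset)
  top1 <- vapply(
    strsplit(ids$candidates, ";", fixed = TRUE),
    function(x) x[1], character(1)
  )
  expect_gte(mean(top1 == corpus$queries$true_species), 0.99)
  expect_true(all(ids$confidence == "species"))
})

hit_row <- function(species, identity, accession = "X-1", lib = "libA") {
  tibble::tibble(
    accession = accession, species = species, identity = identity,
    library = lib, strand = "forward"
  )
}

test_that("consensus assignment follows the threshold rules", {
  # both libraries agree above threshold
  r <- consensus_assign(list(
    libA = hit_row("Salmo salar", 99.4),
    libB = hit_row("Salmo salar", 99.7, lib = "libB")
  ))
  expect_equal(r$confidence, "species")
  expect_equal(r$candidates, "Salmo salar")
  expect_equal(r$best_identity, 99.7)

  # genus-level agreement: single best species kept, noted
  r2 <- consensus_assign(list(
    libA = hit_row("Lutjanus peru", 99.1),
    libB = hit_row("Lutjanus campechanus", 98.4, lib = "libB")
  ))
  expect_equal(r2$confidence, "species")
  expect_equal(r2$candidates, "Lutjanus peru")
  expect_match(r2$notes, "genus")

  # a single sub-threshold best hit degrades to genus-level confidence
  r3 <- consensus_assign(list(libA = hit_row("Cynoscion parvipinnis", 92.6)))
  expect_equal(r3$confidence, "genus")
  expect_equal(r3$candidates, "Cynoscion parvipinnis")

  # below the genus floor: unidentified
  r4 <- consensus_assign(list(libA = hit_row("Mugil cephalus", 71)))
  expect_equal(r4$confidence, "unidentified")
  r5 <- consensus_assign(list(libA = hit_row("x", 95)[0, ]))
  expect_equal(r5$confidence, "unidentified")
  expect_match(r5$notes, "no hits")
})

test_that("exact top-identity ties yield multi-species candidate sets", {
  tied <- dplyr::bind_rows(
    hit_row("Thunnus albacares", 99.54, accession = "A-1"),
    hit_row("Thunnus obesus", 99.54, accession = "A-2")
  )
  r <- consensus_assign(list(libA = tied, libB = hit_row("Thunnus albacares", 99.54, lib = "libB")))
  expect_equal(r$confidence, "species")
  expect_setequal(
    strsplit(r$candidates, ";")[[1]],
    c("Thunnus albacares", "Thunnus obesus")
  )
  # cross-library conflict at different genera keeps both, noted
  r2 <- consensus_assign(list(
    libA = hit_row("Thunnus albacares", 99.1),
    libB = hit_row("Katsuwonus pelamis", 98.6, lib = "libB")
  ))
  expect_setequal(
    strsplit(r2$candidates, ";")[[1]],
    c("Thunnus albacares", "Katsuwonus pelamis")
  )
  expect_match(r2$notes, "conflict")
})

test_that("raising the threshold never upgrades confidence", {
  rank_conf <- c(unidentified = 0, genus = 1, species = 2)
  cases <- list(
    list(libA = hit_row("A b", 98.5), libB = hit_row("A b", 97.9, lib = "libB")),
    list(libA = hit_row("A b", 96.2)),
    list(libA = hit_row("A b", 91.0)),
    list(libA = hit_row("A b", 99.9), libB = hit_row("C d", 98.2, lib = "libB"))
  )
  for (case in cases) {
    prev <- NULL
    for (thr in c(90, 95, 98, 99.5)) {
      conf <- rank_conf[[consensus_assign(case, threshold = thr)$confidence]]
      if (!is.null(prev)) expect_lte(conf, prev)
      prev <- conf
    }
  }
})
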