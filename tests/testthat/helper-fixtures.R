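# Small in-code fixtures shared across test files.

tiny_pool <- function() {
  species_pool(tibble::tibble(
    species = c(
      "Thunnus albacares", "Thunnus obesus", "Coryphaena hippurus",
      "Centropomus viridis", "Oreochromis niloticus",
      "Carcharhinus falciformis"
    ),
    category = c(
      "marine_bony", "marine_bony", "marine_bony", "marine_bony",
      "aquaculture_freshwater", "elasmobranch"
    ),
    supply_weight = c(10, 3, 5, 1, 6, 2)
  ))
}

tiny_catalogs <- function() {
  list(
    catalog("alpha", tibble::tibble(
      commercial_name = c("atun", "atun", "dorado", "robalo"),
      species = c(
        "Thunnus albacares", "Thunnus obesus", "Coryphaena hippurus",
        "Centropomus viridis"
      )
    )),
    catalog("beta", tibble::tibble(
      commercial_name = c("atun", "tilapia", "cazon"),
      species = c(
        "Thunnus albacares", "Oreochromis niloticus",
        "Carcharhinus falciformis"
      )
    ))
  )
}

tiny_design <- function(name_counts = c(atun = 8, dorado = 4, tilapia = 4),
                        mislabel_prob = c(atun = 0, dorado = 0.5, tilapia = 0),
                        ...) {
  survey_design(
    name_counts = name_counts, mislabel_prob = mislabel_prob,
    cities = c("A", "B"), ...
  )
}

# identification rows taken straight from ground truth (perfect assignment);
# used to exercise calling/audit/stats without paying for alignment
truth_identifications <- function(truth) {
  tibble::tibble(
    sample_id = truth$sample_id,
    candidates = truth$true_species,
    best_identity = 100,
    confidence = "species",
    notes = ""
  )
}

# a reusable mid-size corpus: 50 species, 2 libraries, 20 mutated queries
make_corpus <- function(n_species = 50L, n_queries = 20L, seed = 77L,
                        divergence = 0.012, dropout = 0) {
  pool <- species_pool(default_study_pool()[seq_len(n_species), ])
  libset <- generate_reference_library(pool,
    n_libraries = 2L,
    dropout_per_library = dropout, seed = seed
  )
  withr::with_seed(seed + 1L, {
    idx <- sample(nrow(pool), n_queries, replace = TRUE)
    queries <- tibble::tibble(
      sample_id = sprintf("Q%03d", seq_len(n_queries)),
      true_species = pool$species[idx],
      sequence = vapply(idx, function(i) {
        mutate_sequence(
          libset$anchors$sequence[i],
          stats::runif(1, 0, divergence)
        )
      }, character(1L))
    )
  })
  list(pool = pool, libset = libset, queries = queries)
}
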