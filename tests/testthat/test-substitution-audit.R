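# helper: assemble a label-call tibble from compact arguments
mk_calls <- function(name, status, substitute = NA_character_,
                     candidates = substitute) {
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(name)),
    commercial_name = name, status = status,
    candidates = ifelse(is.na(candidates), "Genus sp", candidates),
    substitute_species = substitute, notes = ""
  )
}

test_that("the audit identities hold on published summary counts", {
  audits <- mexico2018_name_audits()
  atun <- audits[audits$commercial_name == "atun", ]
  expect_equal(atun$confirmed_samples, 67)
  expect_equal(atun$over_sub_representation, -9)
  expect_equal(atun$over_sub_representation_percentage, -13.43)
  marlin <- audits[audits$commercial_name == "marlin", ]
  expect_equal(marlin$confirmed_samples, 1)
  expect_equal(marlin$over_sub_representation_percentage, 1700)
  mero <- audits[audits$commercial_name == "mero", ]
  expect_equal(mero$over_sub_representation_percentage, 275)
  # framework identities across all 18 rows
  expect_true(all(audits$verbal_sample_number ==
    audits$correctly_labeled + audits$mislabeling_frequency))
  expect_true(all(audits$confirmed_samples ==
    audits$correctly_labeled + audits$substitutability_frequency))
  expect_true(all(audits$over_sub_representation ==
    audits$verbal_sample_number - audits$confirmed_samples))
  expect_equal(sum(audits$verbal_sample_number), 316)
})

test_that("audit identities hold on arbitrary random count tables", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      verbal <- sample(1:60, n, replace = TRUE)
      misfreq <- vapply(verbal, function(v) sample(0:v, 1), integer(1))
      tab <- tibble::tibble(
        commercial_name = sprintf("name%02d", seq_len(n)),
        verbal_sample_number = verbal,
        mislabeling_frequency = misfreq,
        substitutability_frequency = sample(0:20, n, replace = TRUE)
      )
      out <- complete_audit_table(tab)
      expect_identical(
        out$correctly_labeled + out$mislabeling_frequency,
        out$verbal_sample_number
      )
      expect_identical(
        out$confirmed_samples,
        out$correctly_labeled + out$substitutability_frequency
      )
      expect_identical(
        out$over_sub_representation,
        out$verbal_sample_number - out$confirmed_samples
      )
      zero <- out$confirmed_samples == 0
      expect_true(all(is.na(out$over_sub_representation_percentage[zero])))
      expect_true(all(!is.na(out$over_sub_representation_percentage[!zero])))
    }
  })
})

test_that("audits computed from calls follow the framework and catalogs", {
  cats <- tiny_catalogs()
  calls <- mk_calls(
    name = c(
      rep("atun", 5), # 4 correct + 1 mislabeled (dorado sold as atun)
      rep("dorado", 4), # 1 correct + 3 mislabeled (2x tuna, 1x tilapia)
      rep("tilapia", 2) # correct
    ),
    status = c(
      "correct", "correct", "correct", "correct", "mislabeled",
      "correct", "mislabeled", "mislabeled", "mislabeled",
      "correct", "correct"
    ),
    substitute = c(
      NA, NA, NA, NA, "Coryphaena hippurus",
      NA, "Thunnus albacares", "Thunnus albacares", "Oreochromis niloticus",
      NA, NA
    )
  )
  audits <- audit_names(calls, cats)
  atun <- audits[audits$commercial_name == "atun", ]
  expect_equal(atun$verbal_sample_number, 5L)
  expect_equal(atun$mislabeling_frequency, 1L)
  expect_equal(atun$mislabeling_percentage, 20)
  expect_equal(atun$mislabeling_diversity, 1L)
  expect_equal(atun$substitutability_frequency, 2L) # tuna stood in for dorado twice
  expect_equal(atun$substitutability_diversity, 1L)
  expect_equal(atun$confirmed_samples, 6L)
  expect_equal(atun$over_sub_representation, -1L)
  dorado <- audits[audits$commercial_name == "dorado", ]
  expect_equal(dorado$mislabeling_diversity, 2L)
  expect_equal(dorado$substitutability_frequency, 1L)
  tilapia <- audits[audits$commercial_name == "tilapia", ]
  expect_equal(tilapia$substitutability_frequency, 1L)
  # a name absent from the calls audits to zeros, not an error
  zero <- audit_name("huachinango", calls, cats)
  expect_equal(zero$verbal_sample_number, 0L)
  # total substitutability never exceeds total mislabeling
  expect_lte(
    sum(audits$substitutability_frequency),
    sum(audits$mislabeling_frequency)
  )
})

test_that("shared substitute species are credited once, to the busiest name", {
  # Thunnus albacares is accepted under both "atun" and "listado"
  cats <- list(catalog("c1", tibble::tibble(
    commercial_name = c("atun", "listado", "dorado"),
    species = c("Thunnus albacares", "Thunnus albacares", "Coryphaena hippurus")
  )))
  calls <- mk_calls(
    name = c(rep("atun", 3), "listado", rep("dorado", 2)),
    status = c(rep("correct", 4), "mislabeled", "mislabeled"),
    substitute = c(NA, NA, NA, NA, "Thunnus albacares", "Thunnus albacares")
  )
  once <- audit_names(calls, cats)
  expect_equal(
    once$substitutability_frequency[once$commercial_name == "atun"], 2L
  )
  expect_equal(
    once$substitutability_frequency[once$commercial_name == "listado"], 0L
  )
  all_credit <- audit_names(calls, cats, credit = "all")
  expect_equal(
    all_credit$substitutability_frequency[all_credit$commercial_name == "listado"],
    2L
  )
})

test_that("the substitution network mirrors the mislabeled calls", {
  empty <- build_network(mk_calls("atun", "correct"))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$n_unique_combinations, 0L)

  calls <- mk_calls(
    name = c(rep("marlin", 3), "mero", "mero"),
    status = rep("mislabeled", 5),
    substitute = c(
      rep("Thunnus albacares", 3),
      "Pangasianodon hypophthalmus", "Thunnus albacares"
    )
  )
  net <- build_network(calls)
  expect_equal(net$n_unique_combinations, 3L)
  expect_equal(net$n_substitute_species, 2L)
  expect_equal(net$n_substituted_names, 2L)
  expect_equal(sum(net$edges$count), 5L)
  first <- net$edges[1, ]
  expect_equal(first$count, 3L) # the marlin <- tuna edge dominates
  # degree consistency with the audits
  cats <- list(catalog("c", tibble::tibble(
    commercial_name = c("marlin", "mero"),
    species = c("Makaira nigricans", "Epinephelus morio")
  )))
  audits <- audit_names(calls, cats)
  for (nm in audits$commercial_name) {
    expect_equal(
      audits$mislabeling_diversity[audits$commercial_name == nm],
      length(unique(net$edges$species[net$edges$commercial_name == nm]))
    )
  }
})

test_that("category matrices aggregate edges by origin group", {
  edges <- tibble::tibble(
    species = c("Pangasianodon hypophthalmus", "Oreochromis niloticus"),
    commercial_name = c("mero", "mojarra"),
    count = c(4L, 1L)
  )
  spc <- c(
    "Pangasianodon hypophthalmus" = "aquaculture_freshwater",
    "Oreochromis niloticus" = "aquaculture_freshwater"
  )
  nmc <- c(mero = "marine_bony", mojarra = "marine_bony")
  cm <- category_matrix(edges, spc, nmc)
  expect_equal(cm$counts["aquaculture_freshwater", "marine_bony"], 5L)
  expect_equal(sum(cm$counts), 5L)
  expect_equal(cm$percentages["aquaculture_freshwater", "marine_bony"], 100)
  expect_equal(sum(cm$percentages), 100)
  expect_error(
    category_matrix(edges, spc[1], nmc),
    "unmapped.*Oreochromis"
  )
})

test_that("focal-name filtering keeps names at the verbal threshold", {
  audits <- mexico2018_name_audits()
  expect_equal(nrow(filter_focal_names(audits, 6L)), 18L)
  expect_equal(nrow(filter_focal_names(audits, 1L)), 18L)
  expect_equal(nrow(filter_focal_names(audits, 100L)), 0L)
  expect_equal(nrow(filter_focal_names(audits, 12L)), 11L)
  f <- filter_focal_names(audits)
  expect_true(all(diff(f$verbal_sample_number) <= 0))
})

test_that("conservation reports tally status classes and rates", {
  calls <- mk_calls(
    name = rep("cazon", 46),
    status = c(rep("mislabeled", 6), rep("correct", 40)),
    substitute = c(rep("Sphyrna lewini", 6), rep(NA, 40)),
    candidates = c(rep("Sphyrna lewini", 6), rep("Prionace glauca", 40))
  )
  status <- tibble::tibble(
    species = c("Sphyrna lewini", "Prionace glauca"),
    iucn_category = c("Critically endangered", "Near threatened"),
    cites_appendix = c("II", NA)
  )
  rep_ <- conservation_report(calls, status)
  expect_equal(rep_$listed_rate, 13.0)
  expect_equal(sum(rep_$by_iucn$n_samples), 46L)
  cites <- rep_$by_cites
  expect_equal(cites$n_samples[cites$cites_appendix == "II"], 6L)
  # empty status table: everything unclassified
  rep0 <- conservation_report(calls, status[0, ])
  expect_true(all(rep0$species$iucn_category == "unclassified"))
  expect_true(is.na(rep0$listed_rate))
})
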