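test_that("Wilson intervals match the study-wide rate and its bounds", {
  ci <- wilson_ci(116, 376)
  expect_equal(ci$rate, 30.85106, tolerance = 1e-6)
  expect_equal(round(ci$ci_low, 1), 26.4)
  expect_lt(abs(ci$ci_high - 35.7), 0.05)
  # boundaries
  expect_equal(wilson_ci(0, 10)$ci_low, 0)
  expect_equal(wilson_ci(10, 10)$ci_high, 100)
  ci2 <- wilson_ci(3, 7)
  expect_lte(ci2$ci_low, ci2$rate)
  expect_gte(ci2$ci_high, ci2$rate)
  expect_error(wilson_ci(5, 0), "at least 1")
  expect_error(wilson_ci(8, 5), "0, n")
})

test_that("Wilson intervals always contain k/n and achieve ~95% coverage", {
  withr::with_seed(42, {
    for (p in c(0.1, 0.3, 0.5)) {
      for (n in c(50L, 376L)) {
        k <- rbinom(2000L, n, p)
        cis <- vapply(k, function(ki) {
          ci <- wilson_ci(ki, n)
          c(ci$ci_low, ci$rate, ci$ci_high)
        }, numeric(3))
        expect_true(all(cis[1, ] <= cis[2, ] & cis[2, ] <= cis[3, ]))
        covered <- cis[1, ] <= 100 * p & 100 * p <= cis[3, ]
        expect_gte(mean(covered), 0.93)
        expect_lte(mean(covered), 0.97)
      }
    }
  })
})

test_that("2x2 chi-square equals the direct textbook computation", {
  tabs <- list(
    matrix(c(13, 65, 64, 127), 2, byrow = TRUE),
    matrix(c(39, 68, 13, 65), 2, byrow = TRUE),
    matrix(c(10, 10, 10, 10), 2, byrow = TRUE),
    matrix(c(3, 17, 9, 4), 2, byrow = TRUE)
  )
  for (tab in tabs) {
    res <- chi2_2x2(tab)
    expect_equal(res$statistic, oracle_chi2(tab), tolerance = 1e-9)
    expect_equal(res$df, 1L)
  }
  flat <- chi2_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margins")
})

test_that("chi-square type-I error is near its nominal 5% level", {
  withr::with_seed(7, {
    hits <- vapply(1:200, function(i) {
      k <- rbinom(2L, 80L, 0.3)
      tab <- matrix(c(k[1], 80 - k[1], k[2], 80 - k[2]), 2, byrow = TRUE)
      chi2_2x2(tab)$p_value < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.01)
    expect_lte(mean(hits), 0.11)
  })
})

test_that("OLS reproduces exact fits and is affine-invariant", {
  x <- c(1, 2, 3, 4, 5)
  fit <- ols_fit(x, 2 * x + 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(fit$p_value, 1e-10)
  withr::with_seed(3, {
    xr <- rnorm(20)
    yr <- 1.5 * xr + rnorm(20)
    base <- ols_fit(xr, yr)
    scaled <- ols_fit(3 * xr - 7, -2 * yr + 11)
    expect_equal(base$r_squared, scaled$r_squared, tolerance = 1e-12)
    expect_equal(base$p_value, scaled$p_value, tolerance = 1e-12)
  })
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(ols_fit(c(1, 2), c(1, 2)), "at least 3")
  expect_error(ols_fit(c(-1, 2, 3), c(1, 2, 3), transform = "log10_x"), "x > 0")
})

test_that("stratified rates reproduce a city-by-vendor rate table", {
  strata <- mexico2018_strata()
  # recovered counts cross-check against the published margins
  expect_equal(sum(strata$k_mislabeled), 116L)
  expect_equal(sum(strata$n), 376L)
  vendor_k <- tapply(strata$k_mislabeled, strata$vendor_type, sum)
  expect_equal(
    as.vector(vendor_k[c("fish_market", "grocery_store", "restaurant")]),
    c(39L, 13L, 64L)
  )
  # cell-level rates recomputed from counts match the published percentages
  for (i in seq_len(nrow(strata))) {
    ci <- wilson_ci(strata$k_mislabeled[i], strata$n[i])
    expect_lt(abs(ci$rate - strata$pct_mislabeled[i]), 0.1)
  }
  # build a call table with those counts and recover rates per vendor type
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), function(i) {
    n <- strata$n[i]
    k <- strata$k_mislabeled[i]
    tibble::tibble(
      sample_id = sprintf("%d-%d", i, seq_len(n)),
      commercial_name = "x",
      status = c(rep("mislabeled", k), rep("correct", n - k)),
      city = strata$city[i], vendor_type = strata$vendor_type[i]
    )
  }))
  by_vendor <- stratified_rates(calls, "vendor_type")
  expect_equal(nrow(by_vendor$rates), 3L)
  gro <- by_vendor$rates[by_vendor$rates$stratum == "grocery_store", ]
  expect_equal(gro$k, 13L)
  expect_equal(gro$n, 78L)
  t1 <- by_vendor$tests
  gr <- t1[t1$group1 == "grocery_store" & t1$group2 == "restaurant", ]
  expect_equal(round(gr$statistic, 3), 7.688)
  fg <- t1[t1$group1 == "fish_market" & t1$group2 == "grocery_store", ]
  expect_equal(round(fg$statistic, 3), 8.736)
  # single stratum: a rate but no tests
  single <- stratified_rates(calls[calls$vendor_type == "restaurant", ], "vendor_type")
  expect_equal(nrow(single$rates), 1L)
  expect_equal(nrow(single$tests), 0L)
  # Holm column only on request
  expect_false("p_holm" %in% names(by_vendor$tests))
  expect_true("p_holm" %in% names(stratified_rates(calls, "vendor_type", adjust = TRUE)$tests))
})

test_that("landings regressions use log10 tonnage and join by name", {
  audits <- mexico2018_name_audits()
  # exact collinearity on the log scale gives R^2 = 1
  sub <- audits[1:6, ]
  landings <- tibble::tibble(
    commercial_name = sub$commercial_name,
    tons = 10^(5 - sub$mislabeling_percentage / 10)
  )
  fit <- availability_regression(landings, sub)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$transform, "log10_x")
  expect_error(
    availability_regression(landings[1:2, ], sub),
    "at least 3"
  )
  bad <- landings
  bad$tons[1] <- -1
  expect_error(availability_regression(bad, sub), "positive")
})

test_that("a strong simulated landings effect beats shuffled pairings", {
  audits <- mexico2018_name_audits()
  withr::with_seed(19, {
    tons <- 10^(4 - audits$mislabeling_percentage / 25 +
      rnorm(nrow(audits), 0, 0.15))
    landings <- tibble::tibble(
      commercial_name = audits$commercial_name, tons = tons
    )
    observed <- availability_regression(landings, audits)$r_squared
    shuffled <- vapply(1:200, function(i) {
      sh <- landings
      sh$tons <- sample(sh$tons)
      availability_regression(sh, audits)$r_squared
    }, numeric(1))
    expect_gte(mean(observed > shuffled), 0.9)
  })
})

test_that("audit rates recover the generating mislabel probability", {
  pool <- tiny_pool()
  cats <- tiny_catalogs()
  libset <- generate_reference_library(pool, seed = 91)
  design <- tiny_design(
    name_counts = c(dorado = 60),
    mislabel_prob = c(dorado = 0.4),
    intra_divergence = 0
  )
  p_true <- 40
  covered <- vapply(1:200, function(r) {
    sv <- simulate_survey(pool, design, cats, libset, seed = r)
    calls <- call_samples(sv$samples, truth_identifications(sv$truth), cats)
    audit <- audit_name("dorado", calls, cats)
    ci <- wilson_ci(audit$mislabeling_frequency, audit$verbal_sample_number)
    ci$ci_low <= p_true && p_true <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.89)
})
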