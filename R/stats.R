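#' Wilson score confidence interval for a binomial rate
#'
#' The interval used for all mislabeling rates: good small-sample coverage,
#' never escapes `[0, 100]`, and always contains the point estimate `k/n`.
#' The normal quantile is computed from `alpha`, not hard-coded.
#'
#' @param k Number of successes (mislabeled samples), `0 <= k <= n`.
#' @param n Number of trials (samples), `n >= 1`.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return One-row tibble: `k`, `n`, `rate`, `ci_low`, `ci_high` (all rates
#'   in percent), `alpha`.
#' @examples
#' wilson_ci(116, 376) # rate 30.9%, lower bound 26.4%
#' @export
wilson_ci <- function(k, n, alpha = 0.05) {
  if (n < 1L) {
    stop("`n` must be at least 1", call. = FALSE)
  }
  if (k < 0L || k > n) {
    stop("`k` must lie in [0, n]", call. = FALSE)
  }
  z <- qnorm(1 - alpha / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble::tibble(
    k = as.integer(k), n = as.integer(n),
    rate = 100 * p,
    ci_low = 100 * max(0, (centre - half) / denom),
    ci_high = 100 * min(1, (centre + half) / denom),
    alpha = alpha
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction is applied: this is fixed behavior, chosen to
#' match the conventional reporting of vendor-type comparisons in market
#' surveys (and verified against published statistics in the test suite).
#'
#' @param table 2x2 matrix of counts with all margins positive; rows are
#'   groups, columns are outcomes (e.g. mislabeled / correct).
#' @return List of class `chi2_result`: `statistic`, `df` (= 1), `p_value`,
#'   `observed`, `expected`.
#' @examples
#' chi2_2x2(matrix(c(13, 65, 64, 127), 2, byrow = TRUE)) # 7.688
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be 2x2", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(
    list(
      statistic = unname(ht$statistic),
      df = 1L,
      p_value = unname(ht$p.value),
      observed = table,
      expected = ht$expected
    ),
    class = "chi2_result"
  )
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square (df = 1, no continuity correction): X2 = %.3f, P = %.3g\n",
    x$statistic, x$p_value
  ))
  invisible(x)
}

#' Simple linear regression with an optional log10 predictor transform
#'
#' Ordinary least squares of `y` on `x` (optionally `log10(x)`), reporting
#' the squared Pearson correlation and the two-sided p-value from the
#' F(1, n-2) statistic.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param transform `"none"` or `"log10_x"` (requires all `x > 0`).
#' @param predictor Optional label carried into the result.
#' @return One-row tibble: `predictor`, `n`, `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`, `transform`.
#' @export
ols_fit <- function(x, y, transform = c("none", "log10_x"),
                    predictor = NA_character_) {
  transform <- match.arg(transform)
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) {
    stop("need at least 3 complete observations", call. = FALSE)
  }
  if (transform == "log10_x") {
    if (any(x <= 0)) {
      stop("log10 transform requires all x > 0", call. = FALSE)
    }
    x <- log10(x)
  }
  if (stats::var(x) == 0) {
    stop("zero variance in the predictor", call. = FALSE)
  }
  fit <- lm(y ~ x)
  # summary.lm warns on exact fits; a perfect fit is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  f <- unname(sm$fstatistic)
  tibble::tibble(
    predictor = predictor,
    n = length(x),
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = sm$r.squared,
    f_statistic = f[1L],
    p_value = pf(f[1L], f[2L], f[3L], lower.tail = FALSE),
    transform = transform
  )
}

#' Mislabeling rates and pairwise tests by stratum
#'
#' Computes a Wilson rate estimate per stratum level (city, vendor type,
#' name source, or commercial name) plus all pairwise 2x2 chi-square
#' comparisons. Excluded calls (generic names, unidentified samples,
#' unknown names) never enter the denominators. Pairwise p-values are
#' reported unadjusted; `adjust = TRUE` adds a Holm-adjusted column.
#'
#' @param calls Label-call tibble carrying the stratum column.
#' @param stratum One of `"city"`, `"vendor_type"`, `"name_source"`,
#'   `"commercial_name"`.
#' @param alpha Significance level for the Wilson intervals.
#' @param adjust Add a `p_holm` column to the pairwise tests.
#' @return List: `rates` (one Wilson row per stratum level) and `tests`
#'   (pairwise tibble: `group1`, `group2`, `statistic`, `p_value`, and
#'   optionally `p_holm`); `tests` has zero rows with a single stratum.
#' @export
stratified_rates <- function(calls,
                             stratum = c(
                               "city", "vendor_type", "name_source",
                               "commercial_name"
                             ),
                             alpha = 0.05, adjust = FALSE) {
  stratum <- match.arg(stratum)
  if (!stratum %in% names(calls)) {
    stop("calls carry no `", stratum, "` column", call. = FALSE)
  }
  active <- calls[calls$status %in% c("correct", "mislabeled"), , drop = FALSE]
  levels_ <- sort(unique(active[[stratum]]))
  rates <- dplyr::bind_rows(lapply(levels_, function(lv) {
    sub <- active[active[[stratum]] == lv, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("stratum level with no callable samples omitted: ", lv)
      return(NULL)
    }
    ci <- wilson_ci(sum(sub$status == "mislabeled"), nrow(sub), alpha)
    tibble::tibble(stratum = lv, ci)
  }))
  tests <- tibble::tibble(
    group1 = character(), group2 = character(),
    statistic = numeric(), p_value = numeric()
  )
  if (nrow(rates) >= 2L) {
    pairs <- utils::combn(rates$stratum, 2L, simplify = FALSE)
    tests <- dplyr::bind_rows(lapply(pairs, function(pr) {
      r1 <- rates[rates$stratum == pr[1L], ]
      r2 <- rates[rates$stratum == pr[2L], ]
      tab <- matrix(
        c(r1$k, r1$n - r1$k, r2$k, r2$n - r2$k),
        nrow = 2L, byrow = TRUE
      )
      res <- chi2_2x2(tab)
      tibble::tibble(
        group1 = pr[1L], group2 = pr[2L],
        statistic = res$statistic, p_value = res$p_value
      )
    }))
    if (adjust) {
      tests$p_holm <- stats::p.adjust(tests$p_value, method = "holm")
    }
  }
  list(rates = rates, tests = tests)
}

#' Regression of mislabeling on availability from landings
#'
#' Joins a landings/imports table (tons per year per commercial name) to
#' per-name audits and regresses mislabeling percentage on log10(tons).
#' Landings span orders of magnitude across species, hence the fixed log
#' transform; the log base does not affect R-squared.
#'
#' @param landings Data frame: `commercial_name`, `tons` (positive).
#' @param audits Audit tibble from [audit_names()].
#' @return One-row tibble from [ols_fit()] with
#'   `predictor = "log10_landings_tons"`.
#' @export
availability_regression <- function(landings, audits) {
  landings <- tibble::as_tibble(landings)
  stopifnot(all(c("commercial_name", "tons") %in% names(landings)))
  landings$commercial_name <- normalize_name(landings$commercial_name)
  shared <- intersect(landings$commercial_name, audits$commercial_name)
  if (length(shared) < 3L) {
    stop("need at least 3 commercial names shared between landings and audits",
      call. = FALSE
    )
  }
  if (any(landings$tons[landings$commercial_name %in% shared] <= 0)) {
    stop("landings must be positive for the log transform", call. = FALSE)
  }
  x <- landings$tons[match(shared, landings$commercial_name)]
  y <- audits$mislabeling_percentage[match(shared, audits$commercial_name)]
  ols_fit(x, y, transform = "log10_x", predictor = "log10_landings_tons")
}
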