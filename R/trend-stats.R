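## Time-trend analytics on national index series: relative increments over a
## base year, trapezoidal AUC of increments, the Mann-Kendall trend test
## (exact null for short tie-free series, tie-corrected normal approximation
## otherwise), Pearson correlation of increments, and period-mean comparison.

one_country <- function(series) {
  if ("country" %in% names(series) && length(unique(series$country)) > 1L) {
    stop_ctaccess("expected a single country's series; split by country first",
                  "ctaccess_validation_error")
  }
  series[order(series$year), , drop = FALSE]
}

#' Relative increments over a base year
#'
#' Percent change of each year's value over the base-year value,
#' per country.
#'
#' @param series A `national_series` data.frame (`country, year, value`;
#'   the `country` column is optional for a single series).
#' @param base_year Year whose value defines 0% (must be > 0 for every
#'   country).
#' @return data.frame `country, year, increment_pct` with
#'   `attr(, "base_year")` set; the base-year increment is exactly 0.
#' @export
relative_increments <- function(series, base_year) {
  if (!"country" %in% names(series)) series$country <- "all"
  rows <- lapply(split(series, series$country), function(s) {
    s <- s[order(s$year), , drop = FALSE]
    base <- s$value[s$year == base_year]
    if (length(base) != 1L) {
      stop_ctaccess(sprintf("base year %d absent for '%s'", base_year,
                            s$country[1L]), "ctaccess_validation_error")
    }
    if (base <= 0) {
      stop_ctaccess(sprintf("base-year value is 0 for '%s': increments undefined",
                            s$country[1L]), "ctaccess_zero_base")
    }
    data.frame(country = s$country, year = s$year,
               increment_pct = 100 * (s$value - base) / base,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "base_year") <- base_year
  out
}

#' Area under the increment curve
#'
#' Trapezoidal integral of percent increment against the year axis (unit
#' spacing between consecutive years). Only ratios of AUCs are interpreted,
#' which makes the result invariant to the abscissa origin.
#'
#' @param inc A single country's increment series (`year, increment_pct`).
#' @return Scalar area.
#' @export
auc_increments <- function(inc) {
  inc <- one_country(inc)
  if (nrow(inc) < 2L) {
    stop_ctaccess("need at least two years for an AUC", "ctaccess_validation_error")
  }
  y <- inc$increment_pct
  dx <- diff(inc$year)
  sum(dx * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Accessibility-vs-trials decoupling ratio
#'
#' Ratio of the accessibility-increment AUC to the trial-count-increment
#' AUC over the same years; values below 1 mean trial numbers grew faster
#' than accessibility (growth concentrated at existing sites).
#'
#' @param access_inc,trials_inc Increment series (`year, increment_pct`)
#'   for the index and for the trial counts.
#' @return Scalar ratio.
#' @export
decoupling_ratio <- function(access_inc, trials_inc) {
  auc_increments(access_inc) / auc_increments(trials_inc)
}

## ---- Mann-Kendall ----------------------------------------------------------

# number of permutations of 1..n with d inversions, d = 0..n(n-1)/2;
# generating polynomial prod_{i=1}^{n} (1 + q + ... + q^{i-1})
inversion_counts <- function(n) {
  counts <- 1
  for (i in 2:n) {
    counts <- convolve_poly(counts, rep(1, i))
  }
  counts
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# exact two-sided p of |S| >= |s_obs| under the tie-free permutation null
mk_exact_p <- function(s_obs, n) {
  counts <- inversion_counts(n)
  N <- n * (n - 1) / 2
  svals <- N - 2 * (0:N)             # S corresponding to each inversion count
  sum(counts[abs(svals) >= abs(s_obs)]) / sum(counts)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test on an ordered series via the sign-sum
#' statistic `S = sum_{k<l} sign(x_l - x_k)`, with Kendall's tau-b
#' (tie-corrected) as the normalized statistic. For short tie-free series
#' the exact permutation null of S is used; otherwise a tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x Ordered numeric values (a national index series), length >= 3.
#' @param method `"auto"` (exact when `n <= 10` and tie-free), `"exact"`,
#'   or `"normal"`.
#' @return list `S, tau, p_value, n, method`.
#' @export
mann_kendall <- function(x, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3L) stop_ctaccess("need n >= 3 for a trend test",
                            "ctaccess_validation_error")
  if (any(!is.finite(x))) stop_ctaccess("non-finite values in series",
                                        "ctaccess_validation_error")
  dif <- outer(x, x, "-")
  S <- as.integer(sum(sign(dif[lower.tri(dif)])))  # lower.tri: x_l - x_k, l > k
  ties <- table(x)
  ties <- ties[ties > 1L]
  has_ties <- length(ties) > 0L

  D0 <- n * (n - 1) / 2
  Tx <- sum(ties * (ties - 1) / 2)
  tau <- if (D0 - Tx > 0) S / sqrt((D0 - Tx) * D0) else 0

  if (method == "auto") {
    method <- if (!has_ties && n <= 10L) "exact" else "normal"
  }
  if (method == "exact") {
    if (has_ties) {
      stop_ctaccess("exact null requires a tie-free series",
                    "ctaccess_config_error")
    }
    p <- mk_exact_p(S, n)
  } else {
    varS <- (n * (n - 1) * (2 * n + 5) -
               sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (S == 0 || varS <= 0) 0 else (S - sign(S)) / sqrt(varS)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(S = S, tau = tau, p_value = p, n = n, method = method)
}

#' Trend report over a panel of national series
#'
#' Runs [mann_kendall()] per country and flags significance at the given
#' two-sided level. No multiple-testing correction is applied by default;
#' `adjust = "BH"` switches on Benjamini-Hochberg.
#'
#' @param series A `national_series` data.frame.
#' @param alpha Two-sided significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `country, n, S, tau, p_value, significant`.
#' @export
trend_report <- function(series, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(split(series, series$country), function(s) {
    s <- s[order(s$year), , drop = FALSE]
    mk <- mann_kendall(s$value)
    data.frame(country = s$country[1L], n = mk$n, S = mk$S, tau = mk$tau,
               p_value = mk$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p <= alpha
  out
}

#' Pearson correlation with a t-test p value
#'
#' Product-moment correlation of two equal-length series (e.g. the yearly
#' increments of accessibility and of trial counts) with the usual
#' two-sided t test on n - 2 degrees of freedom.
#'
#' @param a,b Numeric vectors, equal length >= 3, each with nonzero
#'   variance.
#' @return list `r, p_value, n`.
#' @export
pearson_corr <- function(a, b) {
  if (length(a) != length(b)) {
    stop_ctaccess("'a' and 'b' must have equal length", "ctaccess_validation_error")
  }
  if (length(a) < 3L) {
    stop_ctaccess("need n >= 3", "ctaccess_validation_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_ctaccess("zero variance: correlation undefined", "ctaccess_validation_error")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}

#' Period-mean comparison
#'
#' Mean and SD of the series over two year windows, and the difference of
#' means. Countries where either period mean is 0 are flagged (a display
#' convention), never dropped.
#'
#' @param series A `national_series` data.frame.
#' @param period1,period2 Integer year vectors (closed intervals).
#' @return data.frame `country, mean1, sd1, mean2, sd2, delta, flagged`.
#' @export
period_comparison <- function(series, period1, period2) {
  rows <- lapply(split(series, series$country), function(s) {
    v1 <- s$value[s$year %in% period1]
    v2 <- s$value[s$year %in% period2]
    if (!length(v1) || !length(v2)) {
      stop_ctaccess(sprintf("empty period for '%s'", s$country[1L]),
                    "ctaccess_validation_error")
    }
    data.frame(country = s$country[1L],
               mean1 = mean(v1), sd1 = if (length(v1) > 1L) sd(v1) else NA_real_,
               mean2 = mean(v2), sd2 = if (length(v2) > 1L) sd(v2) else NA_real_,
               delta = mean(v2) - mean(v1),
               flagged = mean(v1) == 0 || mean(v2) == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
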