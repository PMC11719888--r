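#' Yearly research-article counts for a corpus selection
#'
#' @param records Corpus tibble (optionally pre-filtered to a corpus lineage).
#' @param years Closed integer year range, e.g. `2011:2022`.
#' @return A tibble `year`, `count` covering every year in the range (zeros
#'   where no article was published).
#' @export
yearly_counts <- function(records, years = 2011:2022) {
  arts <- records %>% filter(.data$doc_type == "article", .data$year %in% years)
  tibble(year = as.integer(years)) %>%
    left_join(count(arts, .data$year, name = "count"), by = "year") %>%
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)))
}

#' Fit the log-linear publication-growth regression
#'
#' Ordinary least squares of `ln(count)` on calendar year:
#' `ln(y) = a + b * x`. The year enters raw (not centered), matching the
#' large-magnitude intercepts conventional for this model; centering is
#' available and reports back-transformed coefficients. Fit statistics are
#' `r2`, `r2_adj = 1 - (1 - r2) (n-1)/(n-2)`, `F = (n-2) r2 / (1 - r2)` and
#' the upper-tail F(1, n-2) p-value.
#'
#' @param series Tibble `year`, `count`; all counts must be positive over at
#'   least 4 years (years with zero counts abort the fit rather than being
#'   dropped silently: restrict the range instead).
#' @param center Center the year covariate for numerical conditioning;
#'   reported coefficients are back-transformed to the raw-year scale.
#' @return A `growth_fit` object (list with `a`, `b`, `n`, `r2`, `r2_adj`,
#'   `F`, `p`).
#' @export
fit_loglinear <- function(series, center = FALSE) {
  if (any(series$count <= 0)) {
    abort("zero or negative count in range; restrict the year range to positive counts")
  }
  if (nrow(series) < 4) abort("need at least 4 years to fit")
  x <- series$year
  y <- log(series$count)
  xm <- if (center) mean(x) else 0
  fit <- lm(y ~ I(x - xm))
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1]) - b * xm
  n <- length(y)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  Fstat <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  structure(
    list(
      a = a, b = b, n = n, r2 = r2,
      r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
      F = Fstat,
      p = pf(Fstat, 1, n - 2, lower.tail = FALSE),
      series = series
    ),
    class = "growth_fit"
  )
}

#' Build a growth fit from printed regression coefficients
#'
#' Wraps an `(a, b)` pair reported by an earlier analysis into a
#' `growth_fit` so it can be used in share projections without the original
#' yearly series.
#'
#' @param a Intercept on the natural-log scale.
#' @param b Slope per calendar year.
#' @param n Optional number of fitted years.
#' @return A `growth_fit` object (fit statistics `NA` unless supplied).
#' @export
growth_fit_from_coefficients <- function(a, b, n = NA_integer_) {
  structure(
    list(a = a, b = b, n = n, r2 = NA_real_, r2_adj = NA_real_,
      F = NA_real_, p = NA_real_, series = NULL),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "log-linear growth fit: ln(y) = %.5f + %.5f * year\n", x$a, x$b
  ))
  if (!is.na(x$r2)) {
    cat(sprintf(
      "  n = %d, r2 = %.4f, adj r2 = %.4f, F = %.1f, p = %.3g\n",
      x$n, x$r2, x$r2_adj, x$F, x$p
    ))
  }
  invisible(x)
}

#' @rdname fit_loglinear
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "year"),
    estimate = c(x$a, x$b)
  )
}

#' @rdname fit_loglinear
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2, adj.r.squared = x$r2_adj, statistic = x$F,
    p.value = x$p, nobs = x$n
  )
}

#' Adjusted r-squared implied by a printed F statistic
#'
#' Inverts `F = (n-2) r2 / (1 - r2)` to `r2 = F / (F + n - 2)` and applies
#' the single-predictor adjustment. Used for consistency checks against
#' printed regression statistics.
#'
#' @param F F statistic (1 and n-2 degrees of freedom).
#' @param n Number of fitted observations (years), at least 4.
#' @return The implied adjusted r-squared.
#' @export
implied_adjusted_r2 <- function(F, n) {
  stopifnot(F >= 0, n >= 4)
  r2 <- F / (F + n - 2)
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' Projected share of a numerator corpus within a denominator corpus
#'
#' With two log-linear fits, the share at year `x` is
#' `exp((a_num - a_den) + (b_num - b_den) * x)`. The share is monotone in
#' the year iff the slopes differ.
#'
#' @param fit_num,fit_den `growth_fit` objects (fitted or from printed
#'   coefficients).
#' @param years Integer year(s).
#' @return A tibble `year`, `share` (fraction; multiply by 100 for percent).
#' @export
project_share <- function(fit_num, fit_den, years) {
  tibble(
    year = as.integer(years),
    share = exp((fit_num$a - fit_den$a) + (fit_num$b - fit_den$b) * years)
  )
}

#' First year a projected share reaches a threshold
#'
#' @param fit_num,fit_den `growth_fit` objects; the numerator slope must
#'   exceed the denominator slope (share increasing).
#' @param threshold Share threshold as a fraction (0.01 for 1%).
#' @param years Integer search range (default 2011:2050).
#' @return The smallest year in range with share >= threshold; an error if
#'   the threshold is never reached in range.
#' @export
threshold_year <- function(fit_num, fit_den, threshold, years = 2011:2050) {
  if (fit_num$b <= fit_den$b) abort("share is not increasing (b_num <= b_den)")
  sh <- project_share(fit_num, fit_den, years)
  hit <- sh$year[sh$share >= threshold]
  if (length(hit) == 0) {
    abort(sprintf("share never reaches %g within %d-%d", threshold, min(years), max(years)))
  }
  min(hit)
}
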