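#' Configuration for Bayes-factor trend scoring
#'
#' @param r prior scale on the standardized slope of the
#'   Jeffreys-Zellner-Siow mixture-of-g prior; the default
#'   \code{sqrt(2)/4} is the conventional "medium" scale for regression.
#' @param min_timepoints minimum number of nonzero-denominator bins a
#'   phrase needs before its Bayes factor is evaluated (default 5).
#' @param report_threshold Bayes factors below this are suppressed in the
#'   report variant of the trend table (default 2).
#' @param rel_tol relative tolerance of the quadrature (default 1e-8).
#' @return an object of class \code{bf_config}.
#' @export
bf_config <- function(r = sqrt(2) / 4, min_timepoints = 5L,
                      report_threshold = 2, rel_tol = 1e-8) {
  stopifnot(r > 0, min_timepoints >= 3L, rel_tol > 0)
  structure(list(r = r, min_timepoints = as.integer(min_timepoints),
                 report_threshold = report_threshold, rel_tol = rel_tol),
            class = "bf_config")
}

#' @export
print.bf_config <- function(x, ...) {
  cat("<bf_config> r =", format(x$r), " min_timepoints =",
      x$min_timepoints, " report_threshold =", x$report_threshold,
      " rel_tol =", format(x$rel_tol), "\n")
  invisible(x)
}

#' Ordinary least-squares line fit for display
#'
#' Simple linear regression of a prevalence series on time, with the
#' pointwise 95 per cent band of the mean response. When the response is
#' constant the total sum of squares is zero and R-squared is defined as 0.
#'
#' @param y response (per-bin prevalence).
#' @param x predictor (bin midpoint years), at least 3 distinct values.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{fitted}, \code{band_low}, \code{band_high}, \code{n}.
#' @export
fit_linear <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (any(!is.finite(y)) || any(!is.finite(x))) {
    stop("non-finite values in the series")
  }
  n <- length(y)
  if (n < 3L) stop("need at least 3 points")
  if (length(unique(x)) < 2L) stop("x is constant")
  fit <- stats::lm(y ~ x)
  pr <- stats::predict(fit, se.fit = TRUE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = max(0, min(1, r2)),
       fitted = unname(pr$fit),
       band_low = unname(pr$fit - 1.959964 * pr$se.fit),
       band_high = unname(pr$fit + 1.959964 * pr$se.fit),
       n = n)
}

# log integrand of the JZS Bayes factor in g
jzs_log_integrand_g <- function(g, n, r2, s) {
  (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
    0.5 * log(s) - lgamma(0.5) - 1.5 * log(g) - s / g
}

# after the scale-adapted substitution v = g/(c + g): the constant c is
# matched to where the integrand mass sits (prior scale s plus the
# likelihood peak ~ n R^2/(1-R^2)), so the transformed peak stays interior
# even as R^2 approaches 1; includes the Jacobian dg = c dv/(1-v)^2
jzs_log_integrand <- function(v, n, r2, s, c) {
  g <- c * v / (1 - v)
  jzs_log_integrand_g(g, n, r2, s) + log(c) - 2 * log1p(-v)
}

#' JZS Bayes factor for a linear trend from n and R-squared
#'
#' Evaluates the Jeffreys-Zellner-Siow Bayes factor of a one-covariate
#' linear regression against the intercept-only model,
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(n-2)/2}\,
#'   (1 + g(1-R^2))^{-(n-1)/2}\, \pi(g)\, dg,}
#' where \eqn{\pi(g)} is the inverse-gamma(1/2, n r^2/2) mixing density of
#' the Zellner-Siow (Cauchy) prior on the standardized slope. The data
#' enter only through \code{n} and \code{r_squared}. The integral is
#' computed on the log scale after mapping g to (0, 1) via
#' \code{u = g/(1+g)}, with max-subtraction before exponentiating, so it is
#' stable for large n and R-squared near 1.
#'
#' @param n number of data points (at least 3).
#' @param r_squared coefficient of determination of the OLS fit, in
#'   \[0, 1\].
#' @param r prior scale (default \code{sqrt(2)/4}).
#' @param rel_tol relative tolerance of the quadrature.
#' @return the Bayes factor BF10 (positive; \code{Inf} as R-squared
#'   reaches 1).
#' @export
bf10_from_r2 <- function(n, r_squared, r = sqrt(2) / 4, rel_tol = 1e-8) {
  stopifnot(n >= 3L, r_squared >= 0, r_squared <= 1, r > 0)
  if (r_squared >= 1 - 1e-15) return(Inf)
  s <- n * r^2 / 2
  cc <- s + n * r_squared / (1 - r_squared) + 1
  v_grid <- seq(1e-8, 1 - 1e-8, length.out = 4001L)
  M <- max(jzs_log_integrand(v_grid, n, r_squared, s, cc))
  val <- stats::integrate(
    function(v) exp(jzs_log_integrand(v, n, r_squared, s, cc) - M),
    lower = 0, upper = 1, rel.tol = rel_tol, subdivisions = 1000L)
  exp(M) * val$value
}

#' JZS Bayes factor for a linear trend in a series
#'
#' Fits the OLS regression of \code{y} on \code{x} and evaluates
#' [bf10_from_r2()] on its R-squared. The result depends on the data only
#' through the number of points and R-squared, so it is invariant to affine
#' rescaling of \code{x} and to adding a constant to \code{y}.
#'
#' @param y response series (per-bin prevalence).
#' @param x time covariate (bin midpoint years).
#' @param cfg a [bf_config()].
#' @return BF10 as a single number.
#' @export
jzs_bf10 <- function(y, x, cfg = bf_config()) {
  if (length(y) < cfg$min_timepoints) {
    stop("series has fewer than min_timepoints = ", cfg$min_timepoints,
         " points")
  }
  fit <- fit_linear(y, x)
  bf10_from_r2(fit$n, fit$r_squared, r = cfg$r, rel_tol = cfg$rel_tol)
}

#' Evidence band for a Bayes factor
#'
#' The conventional four-way taxonomy: up to 3.2 "not worth more than a
#' bare mention", 3.2--10 "substantial", 10--100 "strong", above 100
#' "decisive". Each band is closed at its upper bound.
#'
#' @param bf10 positive numeric vector.
#' @return character vector of \code{"mention"}, \code{"substantial"},
#'   \code{"strong"}, \code{"decisive"}.
#' @export
classify_evidence <- function(bf10) {
  if (any(!is.na(bf10) & bf10 <= 0)) stop("BF10 must be positive")
  ifelse(bf10 <= 3.2, "mention",
         ifelse(bf10 <= 10, "substantial",
                ifelse(bf10 <= 100, "strong", "decisive")))
}

#' Per-phrase temporal trend table
#'
#' For every phrase in a per-phrase binned prevalence table, fits the OLS
#' line on (bin midpoint year, prevalence) and scores the evidence for a
#' temporal trend with the JZS Bayes factor. Bins with no documents were
#' already dropped upstream; the terminal partial bin (start year 2020) is
#' excluded by default because the final collection year is incomplete.
#' Phrases with fewer than \code{cfg$min_timepoints} usable bins are
#' retained with \code{evaluated = FALSE} and a reason.
#'
#' @param prev per-phrase rows of a [prevalence_table()] (scope
#'   \code{"phrase"}).
#' @param cfg a [bf_config()].
#' @param include_partial_bin include the 2020 partial bin in the series.
#' @return data.frame \code{phrase}, \code{n_timepoints}, \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{bf10},
#'   \code{evidence_band}, \code{evaluated}, \code{reason}; sorted by
#'   \code{bf10} decreasing (unevaluated rows last). The report variant —
#'   evaluated rows with \code{bf10 >= cfg$report_threshold} — is attached
#'   as attribute \code{report}.
#' @export
trend_table <- function(prev, cfg = bf_config(),
                        include_partial_bin = FALSE) {
  if ("scope" %in% names(prev)) {
    prev <- prev[prev$scope == "phrase", , drop = FALSE]
  }
  if (!include_partial_bin) {
    prev <- prev[prev$bin_start < 2020L, , drop = FALSE]
  }
  phrases <- unique(prev$phrase)
  rows <- lapply(phrases, function(ph) {
    d <- prev[prev$phrase == ph & prev$n_total > 0L, , drop = FALSE]
    x <- d$bin_start + (d$bin_width - 1) / 2
    base <- data.frame(phrase = ph, n_timepoints = nrow(d),
                       slope = NA_real_, intercept = NA_real_,
                       r_squared = NA_real_, bf10 = NA_real_,
                       evidence_band = NA_character_, evaluated = FALSE,
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (nrow(d) < cfg$min_timepoints) {
      base$reason <- sprintf("only %d of the required %d time points",
                             nrow(d), cfg$min_timepoints)
      return(base)
    }
    fit <- fit_linear(d$prevalence, x)
    bf <- bf10_from_r2(fit$n, fit$r_squared, r = cfg$r,
                       rel_tol = cfg$rel_tol)
    base$slope <- fit$slope
    base$intercept <- fit$intercept
    base$r_squared <- fit$r_squared
    base$bf10 <- bf
    base$evidence_band <- classify_evidence(bf)
    base$evaluated <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$evaluated, -ifelse(is.na(out$bf10), -Inf, out$bf10),
                   out$phrase), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <-
    out[out$evaluated & out$bf10 >= cfg$report_threshold, , drop = FALSE]
  out
}
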