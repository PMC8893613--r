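#' Assign publication years to time bins
#'
#' Bins are anchored at 1990. With \code{width = 1} each year 1990--2020 is
#' its own bin (31 bins); with \code{width = 3} the bins are 1990--1992,
#' 1993--1995, ..., 2017--2019 plus a terminal partial bin holding 2020
#' alone.
#'
#' @param year integer vector of publication years within 1990--2020.
#' @param width bin width in years, 1 or 3.
#' @return integer vector of bin start years.
#' @export
bin_start_year <- function(year, width = 3L) {
  width <- as.integer(width)
  if (!width %in% c(1L, 3L)) stop("bin width must be 1 or 3")
  if (any(year < 1990L | year > 2020L)) {
    stop("year(s) outside the 1990-2020 window; filter the corpus first")
  }
  1990L + width * ((as.integer(year) - 1990L) %/% width)
}

#' Count documents and phrase-positive documents per time bin
#'
#' Produces one row per bin over the full 1990--2020 range (empty bins get
#' zero counts), partitioning the input: the bin totals sum to the number
#' of summary rows.
#'
#' @param summary per-document summary from [scan_corpus()] (columns
#'   \code{year} and \code{phrase_positive}), or any data.frame with a
#'   \code{year} column plus a logical \code{positive} given via
#'   \code{positive}.
#' @param width bin width in years, 1 or 3.
#' @param positive optional logical vector overriding
#'   \code{summary$phrase_positive}.
#' @return data.frame \code{bin_start}, \code{bin_width}, \code{n_total},
#'   \code{n_positive}.
#' @export
bin_by_period <- function(summary, width = 3L, positive = NULL) {
  width <- as.integer(width)
  positive <- positive %||% summary$phrase_positive
  stopifnot(length(positive) == nrow(summary))
  starts <- seq(1990L, 2020L, by = width)
  bins <- bin_start_year(summary$year, width)
  f <- factor(bins, levels = starts)
  data.frame(
    bin_start = starts,
    bin_width = pmin(width, 2021L - starts),
    n_total = as.integer(table(f)),
    n_positive = as.integer(tapply(as.logical(positive), f, sum,
                                   default = 0L)),
    stringsAsFactors = FALSE)
}

#' Continuity-corrected confidence interval for a proportion
#'
#' Point estimate \code{x/n} with the continuity-corrected Wilson score
#' interval (Newcombe's formulation of the Yates-corrected interval):
#' \deqn{L = \frac{2np + z^2 - 1 - z\sqrt{z^2 - 2 - 1/n + 4p(n(1-p)+1)}}{2(n+z^2)}}
#' \deqn{U = \frac{2np + z^2 + 1 + z\sqrt{z^2 + 2 - 1/n + 4p(n(1-p)-1)}}{2(n+z^2)}}
#' with \code{p = x/n}, clipped to \[0, 1\]; \code{L = 0} when \code{x = 0}
#' and \code{U = 1} when \code{x = n}. For the default 95 per cent level
#' the critical value is pinned at \code{z = 1.959964}.
#'
#' @param x number of successes (vectorized).
#' @param n number of trials, \code{n >= 1}.
#' @param level confidence level (default 0.95).
#' @return data.frame \code{estimate}, \code{ci_low}, \code{ci_high}.
#' @examples
#' proportion_ci(49134, 567758)  # 0.0865 (0.0858-0.0873)
#' @export
proportion_ci <- function(x, n, level = 0.95) {
  if (any(n < 1L)) stop("n must be at least 1")
  if (any(x < 0L | x > n)) stop("need 0 <= x <= n")
  z <- if (identical(level, 0.95)) 1.959964 else
    stats::qnorm((1 + level) / 2)
  p <- x / n
  lo <- (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  lo[x == 0] <- 0
  hi[x == n] <- 1
  data.frame(estimate = p,
             ci_low = pmin(pmax(lo, 0), 1),
             ci_high = pmin(pmax(hi, 0), 1))
}

#' Phrase-positive prevalence per time bin, overall and per phrase
#'
#' The overall series uses yearly bins by default; per-phrase series use
#' 3-year bins (a phrase counts as present in a document when it occurs at
#' least once). Bins without any documents are omitted and counted in the
#' \code{n_empty_bins} attribute.
#'
#' @param summary per-document summary from [scan_corpus()].
#' @param hits hit table from [scan_corpus()]; required for per-phrase
#'   rows.
#' @param dict phrases to tabulate (default: phrases present in
#'   \code{hits}).
#' @param width_overall,width_phrase bin widths for the two scopes.
#' @param nested \code{"all"} counts every hit; \code{"longest-only"}
#'   ignores hits subsumed by a longer overlapping phrase.
#' @param level confidence level.
#' @return data.frame \code{scope} ("overall"/"phrase"), \code{phrase}
#'   (\code{NA} for overall rows), \code{bin_start}, \code{bin_width},
#'   \code{n_total}, \code{n_positive}, \code{prevalence}, \code{ci_low},
#'   \code{ci_high}.
#' @export
prevalence_table <- function(summary, hits = NULL, dict = NULL,
                             width_overall = 1L, width_phrase = 3L,
                             nested = c("all", "longest-only"),
                             level = 0.95) {
  nested <- match.arg(nested)
  overall <- bin_by_period(summary, width_overall)
  overall <- data.frame(scope = "overall", phrase = NA_character_, overall,
                        stringsAsFactors = FALSE)
  out <- overall
  if (!is.null(hits)) {
    h <- hits
    if (nested == "longest-only") h <- h[is.na(h$subsumed_by), , drop = FALSE]
    phrases <- if (is.null(dict)) sort(unique(h$phrase)) else
      as.character(dict)
    per <- lapply(phrases, function(ph) {
      pos_ids <- unique(h$article_id[h$phrase == ph])
      b <- bin_by_period(summary, width_phrase,
                         positive = summary$article_id %in% pos_ids)
      data.frame(scope = "phrase", phrase = ph, b, stringsAsFactors = FALSE)
    })
    out <- rbind(overall, do.call(rbind, per))
  }
  n_empty <- sum(out$n_total == 0L)
  out <- out[out$n_total > 0L, , drop = FALSE]
  ci <- proportion_ci(out$n_positive, out$n_total, level = level)
  out$prevalence <- ci$estimate
  out$ci_low <- ci$ci_low
  out$ci_high <- ci$ci_high
  rownames(out) <- NULL
  attr(out, "n_empty_bins") <- n_empty
  out
}
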