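#' Context window following a phrase hit
#'
#' Returns the stretch of normalized text directly following a phrase
#' occurrence, truncated at the document end: the region in which a
#' directly referred P value is searched for.
#'
#' @param text_norm normalized document text.
#' @param end 1-based inclusive end offset of the phrase hit.
#' @param width window width in characters (default 100).
#' @return a string of length \code{min(width, nchar(text_norm) - end)}.
#' @export
extract_window <- function(text_norm, end, width = 100L) {
  stopifnot(width >= 0L, end >= 0L)
  substr(text_norm, end + 1L, end + width)
}

# token grammar over normalized (lowercase) text:
#   optional "("; "p" (not preceded by an alphanumeric) optionally followed
#   by "value"/"values"; comparator; number as d.ddd, .ddd or
#   mantissa x 10^k / e-notation.  U+00D7 is the multiplication sign kept
#   by normalize_text(); U+2264/2265 are <= / >=.
pvalue_token_regex <- function() {
  num <- "(?:\\d+(?:\\.\\d+)?|\\.\\d+)(?:\\s*(?:[x\u00d7]\\s*10\\s*\\^?\\s*|e)[+-]?\\d+)?"
  paste0("\\(?\\s*(?<![a-z0-9])p(?:[ -]?values?)?\\s*",
         "(<=|>=|[<>=]|\u2264|\u2265)\\s*(", num, ")")
}

# numeric value of a matched number literal
parse_pnumber <- function(s) {
  s <- gsub("\\s+", "", s)
  if (grepl("[x\u00d7]", s)) {
    parts <- stringi::stri_split_regex(s, "[x\u00d7]10\\^?")[[1]]
    as.numeric(parts[1]) * 10^as.numeric(parts[2])
  } else {
    as.numeric(s)  # plain decimal or e-notation
  }
}

normalize_comparator <- function(cmp) {
  cmp[cmp == "\u2264"] <- "<="
  cmp[cmp == "\u2265"] <- ">="
  cmp
}

#' Parse the first P-value token in a context window
#'
#' Scans the window left to right for tokens of the P-value grammar and
#' returns the first whose numeric literal lies in \[0, 1\]; tokens with a
#' value above 1 (percentages, ratios) are rejected and the scan continues.
#' The numeric literal is returned even for inequality comparators
#' ("p < 0.06" yields 0.06); the comparator is retained for auditing.
#'
#' @param window string, normally from [extract_window()].
#' @return \code{NULL} when no token parses, otherwise a list with
#'   \code{value}, \code{comparator} (one of \code{=}, \code{<}, \code{>},
#'   \code{<=}, \code{>=}), \code{raw_token} and \code{distance} (0-based
#'   characters from the phrase end to the token start).
#' @examples
#' parse_pvalue("lower in group b (p = 0.052)")
#' parse_pvalue("risk ratio 1.3, p = 1.2 x 10-3")
#' @export
parse_pvalue <- function(window) {
  stopifnot(length(window) == 1L)
  re <- pvalue_token_regex()
  m <- stringi::stri_match_all_regex(window, re)[[1]]
  if (is.na(m[1, 1])) return(NULL)
  loc <- stringi::stri_locate_all_regex(window, re)[[1]]
  for (i in seq_len(nrow(m))) {
    value <- parse_pnumber(m[i, 3])
    if (is.na(value) || value > 1) next
    return(list(value = value,
                comparator = normalize_comparator(m[i, 2]),
                raw_token = stringi::stri_trim_both(m[i, 1]),
                distance = as.integer(loc[i, 1]) - 1L))
  }
  NULL
}

#' Categorize a P value relative to the significance threshold
#'
#' Bands: \code{below} when value < 0.05, \code{mid} when
#' 0.05 <= value <= 0.15 (both boundaries belong to the mid band),
#' \code{above} when value > 0.15.
#'
#' @param value numeric vector in \[0, 1\].
#' @return character vector of \code{"below"}, \code{"mid"},
#'   \code{"above"}.
#' @export
categorize_pvalue <- function(value) {
  if (anyNA(value) || any(value < 0 | value > 1)) {
    stop("P values must lie in [0, 1]")
  }
  ifelse(value < 0.05, "below", ifelse(value <= 0.15, "mid", "above"))
}

#' Extract P-value mentions for every phrase hit in a corpus
#'
#' Automates direct-referral extraction: for each hit the window of
#' \code{width} characters after the phrase is parsed with [parse_pvalue()]
#' and the first valid token (if any) becomes one mention row.
#'
#' @param corpus corpus data.frame (needs \code{id}, \code{text_norm}).
#' @param hits hit table from [scan_corpus()].
#' @param width window width in characters (default 100).
#' @return data.frame with one row per extracted mention:
#'   \code{article_id}, \code{phrase}, \code{raw_token}, \code{comparator},
#'   \code{value}, \code{distance}, \code{category}; attribute
#'   \code{n_windows} records how many hits were searched.
#' @export
extract_pvalues <- function(corpus, hits, width = 100L) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    out <- data.frame(article_id = character(0), phrase = character(0),
                      raw_token = character(0), comparator = character(0),
                      value = numeric(0), distance = integer(0),
                      category = character(0), stringsAsFactors = FALSE)
    attr(out, "n_windows") <- 0L
    return(out)
  }
  text <- corpus$text_norm[match(hits$article_id, corpus$id)]
  if (anyNA(text)) stop("hit table refers to unknown article id(s)")
  windows <- substr(text, hits$end + 1L, hits$end + width)
  re <- pvalue_token_regex()
  ms <- stringi::stri_match_all_regex(windows, re)
  ls <- stringi::stri_locate_all_regex(windows, re)
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    m <- ms[[i]]
    if (is.na(m[1, 1])) next
    for (j in seq_len(nrow(m))) {
      value <- parse_pnumber(m[j, 3])
      if (is.na(value) || value > 1) next
      rows[[i]] <- data.frame(
        article_id = hits$article_id[i], phrase = hits$phrase[i],
        raw_token = stringi::stri_trim_both(m[j, 1]),
        comparator = normalize_comparator(m[j, 2]),
        value = value, distance = as.integer(ls[[i]][j, 1]) - 1L,
        stringsAsFactors = FALSE)
      break
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(article_id = character(0), phrase = character(0),
                      raw_token = character(0), comparator = character(0),
                      value = numeric(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  }
  out$category <- if (nrow(out)) categorize_pvalue(out$value) else character(0)
  rownames(out) <- NULL
  attr(out, "n_windows") <- nrow(hits)
  out
}

#' Canonical printer for P-value tokens
#'
#' The inverse of [parse_pvalue()] to printed precision: values of at least
#' 0.001 are printed as plain decimals with \code{digits} significant
#' digits; smaller values are printed in mantissa-times-power-of-ten form.
#'
#' @param value numeric vector in \[0, 1\].
#' @param comparator comparator string(s), recycled.
#' @param digits significant digits (default 3).
#' @return character vector of tokens such as \code{"p = 0.052"} or
#'   \code{"p = 1.2 x 10-4"}.
#' @export
format_pvalue <- function(value, comparator = "=", digits = 3L) {
  stopifnot(all(value >= 0 & value <= 1))
  comparator <- rep_len(comparator, length(value))
  vapply(seq_along(value), function(i) {
    v <- signif(value[i], digits)
    if (v >= 0.001 || v == 0) {
      sprintf("p %s %s", comparator[i],
              formatC(v, format = "fg", digits = digits))
    } else {
      e <- floor(log10(v))
      m <- signif(v / 10^e, digits)
      sprintf("p %s %s x 10%d", comparator[i],
              formatC(m, format = "fg", digits = digits), as.integer(e))
    }
  }, character(1))
}

#' Summary statistics for extracted P-value mentions
#'
#' @param mentions mention table from [extract_pvalues()].
#' @param n_windows number of searched windows (defaults to the
#'   \code{n_windows} attribute of \code{mentions}); used for the
#'   extraction rate.
#' @param level confidence level for category-proportion intervals.
#' @return list with \code{n}, \code{n_windows}, \code{extraction_rate},
#'   \code{median}, \code{quantiles} (5, 25, 50, 75, 95 per cent, linear
#'   interpolation between order statistics), and \code{categories}
#'   (data.frame \code{category}, \code{n}, \code{proportion},
#'   \code{ci_low}, \code{ci_high}). With no mentions, statistics are
#'   \code{NA}.
#' @export
summarize_pvalues <- function(mentions, n_windows = NULL, level = 0.95) {
  n_windows <- n_windows %||% attr(mentions, "n_windows")
  n <- nrow(mentions)
  cats <- c("below", "mid", "above")
  if (n == 0L) {
    return(list(n = 0L, n_windows = n_windows,
                extraction_rate = if (is.null(n_windows)) NA_real_ else
                  if (n_windows > 0) 0 else NA_real_,
                median = NA_real_,
                quantiles = stats::setNames(rep(NA_real_, 5),
                                            c("5%", "25%", "50%", "75%", "95%")),
                categories = data.frame(category = cats, n = 0L,
                                        proportion = NA_real_,
                                        ci_low = NA_real_,
                                        ci_high = NA_real_)))
  }
  q <- stats::quantile(mentions$value, c(.05, .25, .5, .75, .95), type = 7)
  counts <- as.integer(table(factor(mentions$category, levels = cats)))
  ci <- proportion_ci(counts, n, level = level)
  list(n = n,
       n_windows = n_windows,
       extraction_rate = if (is.null(n_windows)) NA_real_ else n / n_windows,
       median = unname(q[["50%"]]),
       quantiles = q,
       categories = data.frame(category = cats, n = counts,
                               proportion = counts / n,
                               ci_low = ci$ci_low, ci_high = ci$ci_high,
                               stringsAsFactors = FALSE))
}
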