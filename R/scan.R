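#' Scan one document for exact dictionary matches
#'
#' Finds every occurrence of every dictionary phrase in the normalized text
#' by exact substring matching (no word-boundary requirement, mirroring a
#' plain \code{grep} over cleaned text; set \code{word_boundary = TRUE} for
#' a boundary-anchored sensitivity variant). Overlapping occurrences of
#' different phrases and repeated occurrences of the same phrase are all
#' reported. A hit whose span is strictly contained in the span of a hit of
#' a longer phrase is annotated with that phrase in \code{subsumed_by}.
#'
#' Offsets are 1-based and inclusive, so
#' \code{substr(text_norm, start, end) == phrase} for every row.
#'
#' @param text_norm normalized document text (see [normalize_text()]).
#' @param dict a \code{phrase_dictionary} or character vector of normalized
#'   phrases.
#' @param id article identifier recorded in the hit table.
#' @param word_boundary require word boundaries around matches.
#' @return data.frame with columns \code{article_id}, \code{phrase},
#'   \code{start}, \code{end}, \code{subsumed_by}, ordered by
#'   (\code{start}, \code{phrase}).
#' @export
scan_document <- function(text_norm, dict, id = "doc",
                          word_boundary = FALSE) {
  hits <- locate_phrases(text_norm, dict, word_boundary)
  if (nrow(hits) == 0L) {
    return(empty_hits())
  }
  hits <- data.frame(article_id = id, hits, stringsAsFactors = FALSE)
  annotate_subsumption(hits)
}

empty_hits <- function() {
  data.frame(article_id = character(0), phrase = character(0),
             start = integer(0), end = integer(0),
             subsumed_by = character(0), stringsAsFactors = FALSE)
}

# all matches of all phrases in a single text; no subsumption yet
locate_phrases <- function(text, dict, word_boundary = FALSE) {
  res <- vector("list", length(dict))
  for (k in seq_along(dict)) {
    phrase <- dict[[k]]
    loc <- if (word_boundary) {
      stringi::stri_locate_all_regex(
        text, paste0("\\b\\Q", phrase, "\\E\\b"))[[1]]
    } else {
      # overlap = TRUE: every occurrence, including self-overlapping ones
      stringi::stri_locate_all_fixed(
        text, phrase,
        opts_fixed = stringi::stri_opts_fixed(overlap = TRUE))[[1]]
    }
    if (!is.na(loc[1, 1])) {
      res[[k]] <- data.frame(phrase = phrase, start = loc[, 1],
                             end = loc[, 2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(phrase = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$phrase), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# subsumed_by: the longest strictly containing hit, if any (per document)
annotate_subsumption <- function(hits) {
  hits$subsumed_by <- rep(NA_character_, nrow(hits))
  if (nrow(hits) <= 1L) return(hits)
  for (doc in unique(hits$article_id)) {
    i <- which(hits$article_id == doc)
    if (length(i) < 2L) next
    s <- hits$start[i]; e <- hits$end[i]
    len <- e - s + 1L
    for (a in seq_along(i)) {
      container <- which(s <= s[a] & e >= e[a] & len > len[a])
      if (length(container)) {
        best <- container[which.max(len[container])]
        hits$subsumed_by[i[a]] <- hits$phrase[i[best]]
      }
    }
  }
  hits
}

#' Scan a whole corpus for dictionary phrases
#'
#' Applies [scan_document()] to every record and aggregates a per-document
#' summary. Document ids must be unique. For speed, each phrase is screened
#' over all documents with a vectorized fixed-pattern detector before exact
#' locations are extracted, which is equivalent to scanning document by
#' document.
#'
#' @param corpus data.frame from [read_corpus()] (needs columns \code{id},
#'   \code{year}, \code{text_norm}).
#' @param dict a \code{phrase_dictionary} or character vector.
#' @param word_boundary require word boundaries around matches.
#' @return a list with elements \code{hits} (one row per occurrence, as in
#'   [scan_document()]) and \code{summary} (one row per document:
#'   \code{article_id}, \code{year}, \code{n_hits},
#'   \code{phrase_positive}).
#' @export
scan_corpus <- function(corpus, dict, word_boundary = FALSE) {
  stopifnot(is.data.frame(corpus),
            all(c("id", "year", "text_norm") %in% names(corpus)))
  if (anyDuplicated(corpus$id)) {
    stop("duplicate article id(s): ",
         paste(unique(corpus$id[duplicated(corpus$id)]), collapse = ", "))
  }
  texts <- corpus$text_norm
  pieces <- vector("list", length(dict))
  for (k in seq_along(dict)) {
    phrase <- dict[[k]]
    cand <- if (word_boundary) {
      which(stringi::stri_detect_regex(
        texts, paste0("\\b\\Q", phrase, "\\E\\b")))
    } else {
      which(stringi::stri_detect_fixed(texts, phrase))
    }
    if (length(cand) == 0L) next
    locs <- if (word_boundary) {
      stringi::stri_locate_all_regex(
        texts[cand], paste0("\\b\\Q", phrase, "\\E\\b"))
    } else {
      stringi::stri_locate_all_fixed(
        texts[cand], phrase,
        opts_fixed = stringi::stri_opts_fixed(overlap = TRUE))
    }
    nper <- vapply(locs, nrow, integer(1))
    loc <- do.call(rbind, locs)
    pieces[[k]] <- data.frame(
      article_id = rep(corpus$id[cand], nper),
      phrase = phrase,
      start = loc[, 1], end = loc[, 2],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- empty_hits()
    hits$subsumed_by <- NULL
  }
  hits <- hits[order(match(hits$article_id, corpus$id), hits$start,
                     hits$phrase), , drop = FALSE]
  rownames(hits) <- NULL
  hits <- annotate_subsumption(hits)

  n_hits <- integer(nrow(corpus))
  if (nrow(hits)) {
    tab <- table(factor(hits$article_id, levels = corpus$id))
    n_hits <- as.integer(tab)
  }
  summary <- data.frame(
    article_id = corpus$id,
    year = corpus$year,
    n_hits = n_hits,
    phrase_positive = n_hits > 0L,
    stringsAsFactors = FALSE)
  list(hits = hits, summary = summary)
}

#' Per-phrase document counts
#'
#' Counts, for every phrase, the number of documents containing it at least
#' once, in two nesting variants: counting every hit
#' (\code{docs_all}) and counting only hits not subsumed by a longer
#' overlapping phrase (\code{docs_unsubsumed}). A frequency-table analogue
#' of a "phrases per document" tally.
#'
#' @param hits hit table from [scan_corpus()].
#' @param dict optional dictionary; when given, phrases with zero documents
#'   are included and rows follow dictionary order before sorting.
#' @return data.frame \code{phrase}, \code{docs_all},
#'   \code{docs_unsubsumed}, \code{hits_all}, sorted by \code{docs_all}
#'   decreasing then phrase.
#' @export
phrase_counts <- function(hits, dict = NULL) {
  phrases <- if (is.null(dict)) sort(unique(hits$phrase)) else as.character(dict)
  f_all <- factor(hits$phrase, levels = phrases)
  docs_all <- vapply(split(hits$article_id, f_all),
                     function(x) length(unique(x)), integer(1))
  keep <- is.na(hits$subsumed_by)
  f_uns <- factor(hits$phrase[keep], levels = phrases)
  docs_uns <- vapply(split(hits$article_id[keep], f_uns),
                     function(x) length(unique(x)), integer(1))
  out <- data.frame(phrase = phrases,
                    docs_all = as.integer(docs_all),
                    docs_unsubsumed = as.integer(docs_uns),
                    hits_all = as.integer(table(f_all)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$docs_all, out$phrase), , drop = FALSE]
  rownames(out) <- NULL
  out
}
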