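#' Default filler vocabulary for synthetic corpora
#'
#' Clinical-sounding words vetted so that no word of four or more
#' characters from any shipped dictionary phrase occurs as a substring of
#' any filler word; since every dictionary phrase contains at least one
#' such word and phrases span word boundaries only through literal spaces,
#' filler-only text can never contain a dictionary phrase.
#'
#' @return character vector of filler words.
#' @export
default_filler_vocab <- function() {
  c("patients", "randomized", "cohort", "placebo", "dosage", "enrolled",
    "visits", "weeks", "months", "therapy", "infusion", "serum", "plasma",
    "biopsy", "assay", "tumor", "lesion", "cardiac", "renal", "hepatic",
    "glucose", "lipid", "enzyme", "receptor", "protocol", "criteria",
    "centers", "blinded", "washout", "titration", "events", "mortality",
    "morbidity", "relapse", "remission", "symptom", "syndrome",
    "diagnosis", "prognosis", "imaging", "scan", "ultrasound", "vaccine",
    "antibody", "antigen", "pathogen", "microbe", "culture", "sample",
    "aliquot", "vials", "syringe", "catheter", "stent", "graft", "suture",
    "anesthesia", "sedation", "ward", "clinic", "hospital", "nurse",
    "physician", "surgeon", "pharmacy", "compliance", "adherence",
    "dropout", "screening", "telemetry", "spirometry", "biomarker",
    "genotype", "phenotype", "allele", "mutation", "kinase", "cytokine",
    "platelet", "neutrophil", "lymphocyte", "hemoglobin", "creatinine",
    "bilirubin", "albumin", "sodium", "potassium", "calcium", "fasting",
    "baseline", "outcome", "endpoint", "followup", "subgroup",
    "stratified", "allocation", "concealment", "masking", "tablet",
    "capsule", "syrup", "ointment", "topical", "systemic", "infection",
    "fever", "cough", "nausea", "fatigue", "headache", "dizziness",
    "rash", "edema")
}

#' Configuration for the synthetic corpus generator
#'
#' Defines the statistical structure the generated corpus emulates:
#' documents spread uniformly over the study years; each phrase inserted
#' per document with a logit-linear occurrence probability
#' \eqn{\pi(t) = \mathrm{logistic}(\mathrm{logit}(\pi_0) + \beta (t - t_{mid}))}
#' anchored at the midpoint year; a direct-referral P-value token appended
#' immediately after an inserted phrase with probability \code{referral_prob}
#' (default 0.41); P values drawn from a three-component mixture over the
#' bands below 0.05 / 0.05--0.15 / above 0.15 with default weights
#' 0.25 / 0.68 / 0.07. The within-band distributions are calibrated so the
#' overall draw has median about 0.06, quartiles about \[0.05, 0.08\] and a
#' 5--95 per cent interval of about \[0.006, 0.15\].
#'
#' @param years integer vector of publication years (default 1990:2019).
#' @param docs_per_year documents generated per year.
#' @param phrase_specs data.frame with columns \code{phrase} (normalized),
#'   \code{pi0} (occurrence probability at the midpoint year) and
#'   \code{beta} (per-year log-odds slope). May have zero rows.
#' @param referral_prob probability that an inserted phrase is directly
#'   followed by a parseable P-value token.
#' @param p_weights mixture weights for the below/mid/above P bands;
#'   must sum to 1.
#' @param filler_vocab filler word list; screened against the phrases and
#'   the shipped dictionary at generation time.
#' @param words_per_doc filler words per document.
#' @param seed integer seed; the same seed yields a byte-identical corpus.
#' @return an object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(years = 1990:2019, docs_per_year = 500L,
                             phrase_specs = data.frame(
                               phrase = character(0), pi0 = numeric(0),
                               beta = numeric(0)),
                             referral_prob = 0.41,
                             p_weights = c(below = 0.25, mid = 0.68,
                                           above = 0.07),
                             filler_vocab = default_filler_vocab(),
                             words_per_doc = 40L, seed = 1L) {
  stopifnot(is.data.frame(phrase_specs),
            all(c("phrase", "pi0", "beta") %in% names(phrase_specs)),
            all(phrase_specs$pi0 > 0 & phrase_specs$pi0 < 1),
            referral_prob >= 0, referral_prob <= 1,
            length(p_weights) == 3L, abs(sum(p_weights) - 1) < 1e-12,
            all(p_weights >= 0), docs_per_year >= 1L, words_per_doc >= 3L,
            all(years >= 1990L & years <= 2020L))
  if (anyDuplicated(phrase_specs$phrase)) stop("duplicate phrase specs")
  if (any(phrase_specs$phrase != normalize_text(phrase_specs$phrase))) {
    stop("phrase specs must be normalization fixed points")
  }
  structure(list(years = as.integer(years),
                 docs_per_year = as.integer(docs_per_year),
                 phrase_specs = phrase_specs,
                 referral_prob = referral_prob,
                 p_weights = p_weights,
                 filler_vocab = filler_vocab,
                 words_per_doc = as.integer(words_per_doc),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", length(x$years), " years x ", x$docs_per_year,
      " docs, ", nrow(x$phrase_specs), " phrase spec(s), referral_prob = ",
      x$referral_prob, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# screen: no dictionary-phrase word of >= 4 characters may be a substring
# of any filler word, and every screened phrase must contain such a word
screen_filler <- function(filler, phrases) {
  words <- unique(unlist(strsplit(phrases, " ", fixed = TRUE)))
  blocked <- words[nchar(words) >= 4L]
  has_block <- vapply(strsplit(phrases, " ", fixed = TRUE),
                      function(w) any(nchar(w) >= 4L), logical(1))
  if (any(!has_block)) {
    stop("cannot guarantee filler specificity for phrase(s): ",
         paste(phrases[!has_block], collapse = ", "))
  }
  for (b in blocked) {
    bad <- stringi::stri_detect_fixed(filler, b)
    if (any(bad)) {
      stop("filler word(s) collide with dictionary vocabulary: ",
           paste(filler[bad], collapse = ", "), " (contains '", b, "')")
    }
  }
  invisible(TRUE)
}

# P-value mixture calibrated to the target quantile structure:
# below: 0.001 + 0.049 * Beta(0.7, 1); mid: 0.05 + 0.1 * Beta(0.806, 3.07)
# (median 0.06, 75th percentile 0.08 at default weights);
# above: 0.15 + 0.35 * Beta(0.5, 3).
draw_pvalues <- function(n, weights) {
  band <- sample.int(3L, n, replace = TRUE, prob = weights)
  v <- numeric(n)
  nb <- sum(band == 1L); nm <- sum(band == 2L); na_ <- sum(band == 3L)
  v[band == 1L] <- 0.001 + 0.049 * stats::rbeta(nb, 0.7, 1)
  v[band == 2L] <- 0.05 + 0.1 * stats::rbeta(nm, 0.806, 3.07)
  v[band == 3L] <- 0.15 + 0.35 * stats::rbeta(na_, 0.5, 3)
  v
}

#' Generate a seeded synthetic corpus with ground truth
#'
#' Builds one document per (year, replicate) slot: filler text from the
#' screened vocabulary, with each configured phrase inserted at a random
#' word gap with its year-specific probability, and a formatted P-value
#' token (drawn from the configured band mixture) appended directly after
#' the phrase with probability \code{referral_prob}. The recorded
#' ground-truth P value is the parsed value of the printed token, so
#' bookkeeping is exact to printed precision.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{corpus} (data.frame \code{id}, \code{year},
#'   \code{month}, \code{text_raw}, \code{text_norm}) and
#'   \code{ground_truth}: a list of \code{occurrence} (phrase, year,
#'   true_prob, beta), \code{insertions} (id, phrase, p_value, category —
#'   \code{NA} when no token was appended) and the \code{config}.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  specs <- config$phrase_specs
  screen_targets <- unique(c(specs$phrase, default_dictionary()))
  screen_filler(config$filler_vocab, screen_targets)

  years <- rep(config$years, each = config$docs_per_year)
  ndoc <- length(years)
  ids <- sprintf("syn%06d", seq_len(ndoc))
  mid <- mean(range(config$years))

  set.seed(config$seed)
  # filler: words_per_doc draws per document, pasted column-wise
  w <- matrix(sample(config$filler_vocab, ndoc * config$words_per_doc,
                     replace = TRUE),
              nrow = ndoc)
  text <- do.call(paste, as.data.frame(w, stringsAsFactors = FALSE))

  occ <- NULL
  ins_rows <- list()
  if (nrow(specs) > 0L) {
    occ <- do.call(rbind, lapply(seq_len(nrow(specs)), function(k) {
      data.frame(phrase = specs$phrase[k], year = config$years,
                 true_prob = stats::plogis(
                   stats::qlogis(specs$pi0[k]) +
                     specs$beta[k] * (config$years - mid)),
                 beta = specs$beta[k], stringsAsFactors = FALSE)
    }))
    for (k in seq_len(nrow(specs))) {
      p_doc <- stats::plogis(stats::qlogis(specs$pi0[k]) +
                               specs$beta[k] * (years - mid))
      inserted <- stats::runif(ndoc) < p_doc
      idx <- which(inserted)
      if (length(idx) == 0L) next
      referral <- stats::runif(length(idx)) < config$referral_prob
      pv <- rep(NA_real_, length(idx))
      tok <- rep(NA_character_, length(idx))
      if (any(referral)) {
        raw <- draw_pvalues(sum(referral), config$p_weights)
        tok[referral] <- format_pvalue(raw)
        # truth is the printed value: re-parse the token
        pv[referral] <- vapply(tok[referral],
                               function(t) parse_pvalue(t)$value,
                               numeric(1), USE.NAMES = FALSE)
      }
      gap_u <- stats::runif(length(idx))
      # splice the phrase (plus optional token) at a random word gap; only
      # the inserted documents are split, so large corpora stay cheap
      parts <- stringi::stri_split_fixed(text[idx], " ")
      text[idx] <- vapply(seq_along(idx), function(j) {
        ws <- parts[[j]]
        g <- 1L + floor(gap_u[j] * (length(ws) - 1L))
        piece <- if (is.na(tok[j])) specs$phrase[k] else
          paste0(specs$phrase[k], " (", tok[j], ")")
        paste(c(ws[seq_len(g)], piece, ws[(g + 1L):length(ws)]),
              collapse = " ")
      }, character(1))
      ins_rows[[k]] <- data.frame(
        id = ids[idx], phrase = specs$phrase[k], p_value = pv,
        category = ifelse(is.na(pv), NA_character_, categorize_pvalue(
          ifelse(is.na(pv), 0.5, pv))),
        stringsAsFactors = FALSE)
    }
  }
  corpus <- data.frame(id = ids, year = years, month = NA_integer_,
                       text_raw = text, stringsAsFactors = FALSE)
  corpus$text_norm <- normalize_text(corpus$text_raw)
  attr(corpus, "corpus_counts") <- c(read = ndoc, kept = ndoc, dropped = 0L)
  insertions <- do.call(rbind,
                        ins_rows[!vapply(ins_rows, is.null, logical(1))])
  if (is.null(insertions)) {
    insertions <- data.frame(id = character(0), phrase = character(0),
                             p_value = numeric(0), category = character(0),
                             stringsAsFactors = FALSE)
  }
  list(corpus = corpus,
       ground_truth = list(occurrence = occ %||% data.frame(
         phrase = character(0), year = integer(0), true_prob = numeric(0),
         beta = numeric(0), stringsAsFactors = FALSE),
         insertions = insertions, config = config))
}

#' True per-phrase trend table of a synthetic corpus
#'
#' Reformats the ground truth into one row per phrase with the true
#' occurrence-probability series and log-odds slope, for direct comparison
#' with [trend_table()] output.
#'
#' @param ground_truth the \code{ground_truth} element of
#'   [generate_corpus()] output.
#' @return data.frame \code{phrase}, \code{beta}, \code{prob_first},
#'   \code{prob_last}, \code{increasing}, plus the full series in the
#'   \code{series} attribute.
#' @export
ground_truth_report <- function(ground_truth) {
  occ <- ground_truth$occurrence
  phrases <- unique(occ$phrase)
  out <- do.call(rbind, lapply(phrases, function(ph) {
    d <- occ[occ$phrase == ph, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    data.frame(phrase = ph, beta = d$beta[1],
               prob_first = d$true_prob[1],
               prob_last = d$true_prob[nrow(d)],
               increasing = d$beta[1] > 0,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(phrase = character(0), beta = numeric(0),
                      prob_first = numeric(0), prob_last = numeric(0),
                      increasing = logical(0), stringsAsFactors = FALSE)
  }
  attr(out, "series") <- occ
  out
}

#' Write a corpus in the JSONL dialect read by [read_corpus()]
#'
#' @param corpus corpus data.frame (\code{id}, \code{year}, optional
#'   \code{month}, \code{text_raw}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(id = corpus$id[i], year = corpus$year[i],
                text = corpus$text_raw[i])
    if (!is.null(corpus$month) && !is.na(corpus$month[i])) {
      rec$month <- corpus$month[i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
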