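test_that("the shipped dictionary loads with exactly 505 normalized phrases", {
  d <- default_dictionary()
  expect_s3_class(d, "phrase_dictionary")
  expect_length(d, 505L)
  expect_identical(as.character(d), normalize_text(as.character(d)))
  expect_false(anyDuplicated(d) > 0)
  expect_true("marginally significant" %in% d)
})

test_that("dictionary loading normalizes, deduplicates and rejects degenerate files", {
  f <- tempfile()
  writeLines(c("# comment", "Marginally Significant", "",
               "marginally significant", "a strong trend"), f)
  expect_warning(d <- load_dictionary(f), "1 duplicate")
  expect_identical(as.character(d),
                   c("marginally significant", "a strong trend"))
  expect_identical(attr(d, "n_blank"), 1L)

  blank <- tempfile(); writeLines(c("", "   ", ""), blank)
  expect_error(load_dictionary(blank), "no phrases")
  expect_error(load_dictionary(tempfile()), "does not exist")
})

test_that("single-document scanning finds all occurrences with offsets into the text", {
  text <- normalize_text("The effect was marginally significant (p = 0.052)")
  hits <- scan_document(text, c("marginally significant"), id = "doc1")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 16L)  # 0-based offset 15
  expect_identical(substr(text, hits$start, hits$end), hits$phrase)

  expect_identical(nrow(scan_document("no phrases here",
                                      c("marginally significant"))), 0L)

  # nested phrases: both reported, the shorter annotated as subsumed
  text2 <- "was only marginally significant"
  d2 <- c("marginally significant", "only marginally significant")
  hits2 <- scan_document(text2, d2)
  expect_identical(nrow(hits2), 2L)
  expect_identical(hits2$subsumed_by[hits2$phrase == "marginally significant"],
                   "only marginally significant")
  expect_true(is.na(
    hits2$subsumed_by[hits2$phrase == "only marginally significant"]))
  o <- oracle_scan(text2, d2)
  expect_identical(hits2$start, o$start)
  expect_identical(hits2$phrase, o$phrase)
})

test_that("corpus scanning separates hit counts from phrase-positive documents", {
  corp <- data.frame(
    id = c("d1", "d2", "d3"),
    year = c(1995L, 2000L, 2005L),
    text_norm = c("a strong trend and a clear trend were seen",
                  "nothing of note",
                  "almost significant result"),
    stringsAsFactors = FALSE)
  res <- scan_corpus(corp, c("a strong trend", "a clear trend",
                             "almost significant"))
  expect_identical(sum(res$summary$phrase_positive), 2L)
  expect_identical(nrow(res$hits), 3L)
  expect_identical(res$summary$n_hits, c(2L, 0L, 1L))
  # a document with two phrases counts once as positive but twice in hits
  expect_true(nrow(res$hits) >= sum(res$summary$phrase_positive))
  expect_error(scan_corpus(corp[c(1, 1), ], "a strong trend"), "duplicate")
})

test_that("corpus scanning agrees with the brute-force substring oracle", {
  set.seed(402)
  for (case in 1:20) {
    rc <- random_scan_case(40L)
    res <- scan_corpus(rc$corpus, rc$dict)
    for (i in seq_len(nrow(rc$corpus))) {
      o <- oracle_scan(rc$corpus$text_norm[i], rc$dict)
      h <- res$hits[res$hits$article_id == rc$corpus$id[i], , drop = FALSE]
      expect_identical(h$start, o$start)
      expect_identical(h$end, o$end)
      expect_identical(h$phrase, o$phrase)
    }
  }
})

test_that("adding a phrase to the dictionary never decreases any document's hit count", {
  set.seed(403)
  for (case in 1:10) {
    rc <- random_scan_case(25L)
    base <- scan_corpus(rc$corpus, rc$dict)
    extra <- paste(sample(c("a", "b", "c"), 3, TRUE), collapse = "")
    more <- scan_corpus(rc$corpus, unique(c(rc$dict, extra)))
    expect_true(all(more$summary$n_hits >= base$summary$n_hits))
  }
})

test_that("word-boundary mode is stricter than substring mode", {
  corp <- data.frame(id = "d1", year = 2000L,
                     text_norm = "the subtrend was a trend indeed",
                     stringsAsFactors = FALSE)
  sub <- scan_corpus(corp, "trend")
  bounded <- scan_corpus(corp, "trend", word_boundary = TRUE)
  expect_identical(nrow(sub$hits), 2L)
  expect_identical(nrow(bounded$hits), 1L)
})

test_that("per-phrase document counts respect the nesting variants", {
  corp <- data.frame(
    id = c("d1", "d2"),
    year = c(2000L, 2001L),
    text_norm = c("was only marginally significant here",
                  "marginally significant alone"),
    stringsAsFactors = FALSE)
  res <- scan_corpus(corp, c("marginally significant",
                             "only marginally significant"))
  pc <- phrase_counts(res$hits)
  expect_identical(pc$docs_all[pc$phrase == "marginally significant"], 2L)
  expect_identical(
    pc$docs_unsubsumed[pc$phrase == "marginally significant"], 1L)
  expect_identical(
    pc$docs_all[pc$phrase == "only marginally significant"], 1L)
  # document counts never exceed hit counts
  expect_true(all(pc$docs_all <= pc$hits_all))
})
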