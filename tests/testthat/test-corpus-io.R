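test_that("normalization lowercases, strips diacritics, maps quotes and dashes", {
  expect_identical(normalize_text("Marginally Significant"),
                   "marginally significant")
  expect_identical(normalize_text("“almost significant”"),
                   "\"almost significant\"")
  expect_identical(normalize_text("café trend"), "cafe trend")
  expect_identical(normalize_text("a – b — c − d"),
                   "a - b - c - d")
  expect_identical(normalize_text("it’s"), "it's")
  # multiplication sign survives (the P-value grammar needs it)
  expect_identical(normalize_text("1.2 × 10-3"), "1.2 × 10-3")
  expect_identical(normalize_text("a\n\n  b\tc"), "a b c")
})

test_that("normalization is idempotent and leaves no marked characters on fuzzed input", {
  set.seed(401)
  pieces <- c("é", "Å", "‘", "”", "—", " ",
              "\n", "\t", "  ", "P", "q", "0.05", "<", "×", "x",
              "significant", "TREND", "Å")
  for (i in 1:200) {
    s <- paste(sample(pieces, sample(1:12, 1), replace = TRUE),
               collapse = "")
    n1 <- normalize_text(s)
    expect_identical(normalize_text(n1), n1)
    expect_false(stringi::stri_detect_regex(n1, "[A-Z\\p{Mn}‘’“”–— ]"),
                 info = s)
    expect_false(stringi::stri_detect_regex(n1, "  "), info = s)
  }
})

test_that("time-frame filter keeps Jan 1990 - Sep 2020 and reports counts", {
  rows <- list(
    list(id = "a", year = 1991, text = "alpha"),
    list(id = "b", year = 2005, text = "beta"),
    list(id = "c", year = 2019, text = "gamma"),
    list(id = "d", year = 1989, text = "too early"),
    list(id = "e", year = 2020, month = 10, text = "too late"),
    list(id = "f", year = 2020, month = 9, text = "just in time"),
    list(id = "g", year = 2021, text = "dropped by year"))
  path <- write_temp_jsonl(rows)
  corp <- read_corpus(path, "jsonl", quiet = TRUE)
  expect_setequal(corp$id, c("a", "b", "c", "f"))
  counts <- attr(corp, "corpus_counts")
  expect_identical(unname(counts), c(7L, 4L, 3L))
  expect_identical(counts[["read"]],
                   counts[["kept"]] + counts[["dropped"]])
  expect_identical(corp$text_norm[corp$id == "a"], "alpha")
})

test_that("corpus readers reject malformed records with row context", {
  expect_error(read_corpus(write_temp_jsonl(list(
    list(id = "a", text = "no year"))), "jsonl", quiet = TRUE),
    "row 1.*year")
  expect_error(read_corpus(write_temp_jsonl(list(
    list(id = "a", year = "199x", text = "t"))), "jsonl", quiet = TRUE),
    "unparseable year")
  empty <- tempfile(fileext = ".jsonl"); file.create(empty)
  expect_error(read_corpus(empty, "jsonl", quiet = TRUE), "empty corpus")
  expect_error(read_corpus(write_temp_jsonl(list(
    list(id = "a", year = 2000, text = "t"),
    list(id = "a", year = 2001, text = "u"))), "jsonl", quiet = TRUE),
    "duplicate")
  expect_error(read_corpus(tempfile(), "jsonl"), "does not exist")
})

test_that("the three corpus formats yield identical records", {
  rows <- list(list(id = "x1", year = 1995, month = 3, text = "First doc."),
               list(id = "x2", year = 2010, text = "Second doc’s text."))
  jsonl <- write_temp_jsonl(rows)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = c("x1", "x2"), year = c(1995, 2010),
                              month = c(3, NA),
                              text = c("First doc.", "Second doc’s text.")),
                   csv, row.names = FALSE, fileEncoding = "UTF-8")
  dir <- tempfile(); dir.create(dir)
  writeLines("First doc.", file.path(dir, "x1.txt"), useBytes = TRUE)
  con <- file(file.path(dir, "x2.txt"), open = "wb", encoding = "UTF-8")
  writeLines(enc2utf8("Second doc’s text."), con, useBytes = TRUE)
  close(con)
  utils::write.csv(data.frame(id = c("x1", "x2"), year = c(1995, 2010),
                              month = c(3, NA)),
                   file.path(dir, "dates.csv"), row.names = FALSE)
  a <- read_corpus(jsonl, "jsonl", quiet = TRUE)
  b <- read_corpus(csv, "csv", quiet = TRUE)
  d <- read_corpus(dir, "txt_dir", quiet = TRUE)
  for (col in c("id", "year", "month", "text_norm")) {
    expect_identical(a[[col]], b[[col]])
    expect_identical(a[[col]], d[[col]])
  }
})

test_that("result tables survive a CSV round trip exactly and deterministically", {
  set.seed(7)
  df <- data.frame(phrase = c("b b", "a, \"quoted\"", "c"),
                   n = c(3L, 1L, 2L),
                   value = c(stats::runif(2), 1 / 3))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_table(df, p1, key = "phrase")
  write_table(df[c(3, 1, 2), ], p2, key = "phrase")
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_table(p1, numeric_cols = "value")
  expect_identical(back$value, df$value[order(df$phrase)])
  expect_identical(back$n, df$n[order(df$phrase)])
  # empty table -> header-only file
  p3 <- tempfile(fileext = ".csv")
  write_table(df[0, ], p3)
  expect_identical(readLines(p3), "\"phrase\",\"n\",\"value\"")
})
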