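# Independent oracles used by unit and acceptance tests. These are kept
# deliberately naive and separate from the package implementation paths.

# brute force all-substrings scan: try every start position of every phrase
oracle_scan <- function(text, phrases) {
  out <- list()
  for (ph in phrases) {
    len <- nchar(ph)
    n <- nchar(text)
    if (len > n || len == 0L) next
    st <- seq_len(n - len + 1L)
    hit <- st[substring(text, st, st + len - 1L) == ph]
    if (length(hit)) {
      out[[ph]] <- data.frame(phrase = ph, start = hit, end = hit + len - 1L,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(phrase = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$phrase), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# fine-grid trapezoid evaluation of the JZS Bayes factor integral on the
# u = g/(1+g) scale, in log space
oracle_bf_trapezoid <- function(n, r2, r = sqrt(2) / 4, K = 2^19) {
  s <- n * r^2 / 2
  u <- seq(0, 1, length.out = K + 1L)[-c(1L, K + 1L)]
  g <- u / (1 - u)
  lf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
    0.5 * log(s) - lgamma(0.5) - 1.5 * log(g) - s / g - 2 * log1p(-u)
  M <- max(lf)
  exp(M) * sum(exp(lf - M)) / K
}

# stratified Monte-Carlo average of the likelihood ratio over the
# inverse-gamma(1/2, n r^2/2) mixing distribution of g
oracle_bf_montecarlo <- function(n, r2, r = sqrt(2) / 4, N = 1e6) {
  s <- n * r^2 / 2
  u <- (seq_len(N) - 0.5) / N
  g <- s / stats::qgamma(1 - u, 0.5)
  lt <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))
  M <- max(lt)
  exp(M) * mean(exp(lt - M))
}

# closed-form simple linear regression (textbook normal equations)
oracle_ols <- function(y, x) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  tss <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (tss <= 0) 0 else 1 - sum(res^2) / tss)
}

# random corpus over a tiny alphabet with a random short-string dictionary;
# produces dense overlapping and nested matches
random_scan_case <- function(max_docs = 100L) {
  alph <- c("a", "b", "c", " ")
  ndocs <- sample(3:max_docs, 1L)
  dict <- unique(replicate(8L, paste(sample(alph, sample(2:6, 1L), TRUE),
                                     collapse = "")))
  dict <- dict[nzchar(trimws(dict)) & dict == trimws(dict)]
  if (length(dict) == 0L) dict <- "ab"
  texts <- vapply(seq_len(ndocs), function(i)
    paste(sample(alph, sample(30:80, 1L), TRUE), collapse = ""),
    character(1))
  list(corpus = data.frame(id = sprintf("d%03d", seq_len(ndocs)),
                           year = 2000L, text_norm = texts,
                           stringsAsFactors = FALSE),
       dict = dict)
}

# small article corpus written to a temp JSONL file
write_temp_jsonl <- function(rows) {
  path <- tempfile(fileext = ".jsonl")
  writeLines(vapply(rows, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE), character(1)), path)
  path
}
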