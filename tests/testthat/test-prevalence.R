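test_that("year binning partitions the study window", {
  expect_identical(bin_start_year(1990L, 1L), 1990L)
  expect_identical(bin_start_year(1992L, 3L), 1990L)
  expect_identical(bin_start_year(2019L, 3L), 2017L)
  expect_identical(bin_start_year(2020L, 3L), 2020L)  # partial terminal bin
  expect_error(bin_start_year(1989L, 3L), "window")
  expect_error(bin_start_year(2000L, 2L), "width")

  set.seed(406)
  years <- sample(1990:2020, 500, replace = TRUE)
  s <- data.frame(year = years, phrase_positive = stats::runif(500) < 0.2)
  for (w in c(1L, 3L)) {
    b <- bin_by_period(s, w)
    expect_identical(nrow(b), if (w == 1L) 31L else 11L)
    expect_identical(sum(b$n_total), 500L)  # every record in exactly one bin
    expect_identical(sum(b$n_positive), sum(s$phrase_positive))
    expect_true(all(b$n_positive <= b$n_total))
  }
  b3 <- bin_by_period(s, 3L)
  expect_identical(b3$bin_start, seq(1990L, 2020L, by = 3L))
  expect_identical(b3$bin_width[nrow(b3)], 1L)
})

test_that("continuity-corrected intervals reproduce the published headline proportion", {
  ci <- proportion_ci(49134, 567758)
  expect_equal(round(ci$estimate, 4), 0.0865)
  expect_equal(round(ci$ci_low, 4), 0.0858)
  expect_equal(round(ci$ci_high, 4), 0.0873)
  expect_identical(proportion_ci(0, 100)$ci_low, 0)
  expect_identical(proportion_ci(100, 100)$ci_high, 1)
  expect_error(proportion_ci(5, 0), "at least 1")
  expect_error(proportion_ci(5, 4), "0 <= x <= n")
})

test_that("intervals solve the continuity-corrected score equation", {
  # independent oracle: invert |p_hat - p| - 1/(2n) = z sqrt(p(1-p)/n)
  # numerically for each endpoint
  z <- 1.959964
  invert_ci <- function(x, n) {
    p <- x / n
    f_lo <- function(q) (p - q - 1 / (2 * n)) - z * sqrt(q * (1 - q) / n)
    f_hi <- function(q) (q - p - 1 / (2 * n)) - z * sqrt(q * (1 - q) / n)
    c(if (x == 0) 0 else stats::uniroot(f_lo, c(1e-12, p), tol = 1e-12)$root,
      if (x == n) 1 else stats::uniroot(f_hi, c(p, 1 - 1e-12),
                                        tol = 1e-12)$root)
  }
  grid <- expand.grid(n = c(10L, 50L, 500L, 5000L, 567758L),
                      frac = c(0.001, 0.05, 0.0865, 0.5, 0.93))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    x <- max(1L, min(n - 1L, round(n * grid$frac[i])))
    ours <- proportion_ci(x, n)
    ref <- invert_ci(x, n)
    expect_equal(ours$ci_low, ref[1], tolerance = 1e-9)
    expect_equal(ours$ci_high, ref[2], tolerance = 1e-9)
    # the base-R continuity-corrected test is a close large-n relative
    if (n >= 1e5) {
      pt <- stats::prop.test(x, n, correct = TRUE)$conf.int
      expect_equal(ours$ci_low, pt[1], tolerance = 1e-4)
      expect_equal(ours$ci_high, pt[2], tolerance = 1e-4)
    }
  }
})

test_that("interval width shrinks as the denominator grows", {
  ns <- c(50L, 200L, 1000L, 20000L)
  widths <- vapply(ns, function(n) {
    ci <- proportion_ci(round(0.0865 * n), n)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("prevalence tables agree with direct per-document computation", {
  corp <- data.frame(
    id = sprintf("d%03d", 1:200), year = 2005L,
    text_norm = c(rep("an almost significant effect", 20),
                  rep("plain filler text", 180)),
    stringsAsFactors = FALSE)
  scan <- scan_corpus(corp, c("almost significant", "a clear trend"))
  prev <- prevalence_table(scan$summary, scan$hits,
                           dict = c("almost significant", "a clear trend"))
  ov <- prev[prev$scope == "overall", ]
  expect_identical(nrow(ov), 1L)
  expect_equal(ov$prevalence, 0.10)
  # cross-module conservation
  expect_identical(sum(ov$n_positive), sum(scan$summary$phrase_positive))
  # a phrase absent from the corpus keeps zero prevalence rows
  absent <- prev[prev$scope == "phrase" & prev$phrase == "a clear trend", ]
  expect_true(all(absent$n_positive == 0L))
  expect_true(all(absent$prevalence == 0))
  expect_true(all(prev$ci_low <= prev$prevalence &
                    prev$prevalence <= prev$ci_high))
})

test_that("estimated yearly prevalence tracks a constant generating rate", {
  specs <- data.frame(phrase = "marginally significant",
                      pi0 = 0.0865, beta = 0)
  cfg <- synthetic_config(years = 2000:2009, docs_per_year = 2000L,
                          phrase_specs = specs, words_per_doc = 10L,
                          seed = 408L)
  gen <- generate_corpus(cfg)
  scan <- scan_corpus(gen$corpus, specs$phrase)
  prev <- prevalence_table(scan$summary, width_overall = 1L)
  ov <- prev[prev$scope == "overall", ]
  sd3 <- 3 * sqrt(0.0865 * (1 - 0.0865) / 2000)
  expect_true(all(abs(ov$prevalence - 0.0865) < sd3))
})
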