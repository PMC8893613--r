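#' Configuration for a full pipeline run
#'
#' Collects every knob of the scan / extract / prevalence / trend pipeline.
#' Can also be loaded from a YAML or JSON file via
#' \code{pipeline_config_from_file()}.
#'
#' @param corpus path to the corpus file or directory.
#' @param format corpus format, see [read_corpus()].
#' @param dictionary path to the phrase dictionary (default: shipped
#'   dictionary).
#' @param out_dir output directory for the result bundle; created if
#'   absent.
#' @param width_overall,width_phrase bin widths for overall and per-phrase
#'   prevalence series.
#' @param window P-value search window width in characters.
#' @param bf a [bf_config()].
#' @param nested hit-counting variant used for per-phrase prevalence, see
#'   [prevalence_table()].
#' @param word_boundary require word boundaries around phrase matches.
#' @param include_partial_bin include the 2020 partial bin in trend fits.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds any stochastic convenience step).
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(corpus, format = "jsonl",
                            dictionary = default_dictionary_path(),
                            out_dir = "almostsig-out",
                            width_overall = 1L, width_phrase = 3L,
                            window = 100L, bf = bf_config(),
                            nested = "all", word_boundary = FALSE,
                            include_partial_bin = FALSE, seed = 1L) {
  structure(list(corpus = corpus, format = format, dictionary = dictionary,
                 out_dir = out_dir, width_overall = as.integer(width_overall),
                 width_phrase = as.integer(width_phrase),
                 window = as.integer(window), bf = bf, nested = nested,
                 word_boundary = isTRUE(word_boundary),
                 include_partial_bin = isTRUE(include_partial_bin),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (.yml/.yaml) or JSON file with fields named as the
#'   arguments of \code{pipeline_config()} (the \code{bf} entry may be a
#'   list of [bf_config()] arguments).
#' @export
pipeline_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$bf)) vals$bf <- do.call(bf_config, as.list(vals$bf))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Reads and filters the corpus, scans it against the dictionary, extracts
#' directly referred P values, tabulates yearly overall prevalence and
#' 3-year per-phrase prevalence with continuity-corrected confidence
#' intervals, scores per-phrase temporal trends with JZS Bayes factors, and
#' writes the bundle to \code{config$out_dir}:
#' \code{corpus_summary.csv}, \code{prevalence_overall.csv},
#' \code{phrase_counts.csv}, \code{prevalence_phrase.csv},
#' \code{trends.csv}, \code{pvalue_mentions.csv},
#' \code{pvalue_summary.csv} and \code{manifest.json}. A failure in any
#' stage aborts with the stage name and removes files written so far;
#' identical configuration and corpus produce a byte-identical bundle.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config file.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory tables (\code{corpus}
#'   counts, \code{summary}, \code{hits}, \code{phrase_counts},
#'   \code{prevalence}, \code{trends}, \code{mentions},
#'   \code{pvalue_summary}, \code{manifest}).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config_from_file(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  written <- character(0)
  emit <- function(df, name, key = NULL) {
    p <- file.path(config$out_dir, name)
    write_table(df, p, key = key)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  corpus <- stage("read_corpus",
                  read_corpus(config$corpus, config$format, quiet = quiet))
  dict <- stage("load_dictionary", load_dictionary(config$dictionary))
  scan <- stage("scan_corpus",
                scan_corpus(corpus, dict,
                            word_boundary = config$word_boundary))
  counts <- attr(corpus, "corpus_counts")
  summary_tab <- data.frame(
    metric = c("documents_read", "documents_kept", "documents_dropped",
               "phrase_positive_documents", "total_hits"),
    value = c(counts[["read"]], counts[["kept"]], counts[["dropped"]],
              sum(scan$summary$phrase_positive), nrow(scan$hits)))
  stage("corpus_summary", emit(summary_tab, "corpus_summary.csv"))

  prev <- stage("prevalence_table",
                prevalence_table(scan$summary, scan$hits, dict = NULL,
                                 width_overall = config$width_overall,
                                 width_phrase = config$width_phrase,
                                 nested = config$nested))
  stage("prevalence_overall",
        emit(prev[prev$scope == "overall", , drop = FALSE],
             "prevalence_overall.csv", key = "bin_start"))
  stage("prevalence_phrase",
        emit(prev[prev$scope == "phrase", , drop = FALSE],
             "prevalence_phrase.csv", key = c("phrase", "bin_start")))

  pc <- stage("phrase_counts", phrase_counts(scan$hits))
  stage("phrase_counts_write", emit(pc, "phrase_counts.csv"))

  trends <- stage("trend_table",
                  trend_table(prev, cfg = config$bf,
                              include_partial_bin =
                                config$include_partial_bin))
  stage("trends_write", emit(trends, "trends.csv"))

  mentions <- stage("extract_pvalues",
                    extract_pvalues(corpus, scan$hits,
                                    width = config$window))
  stage("mentions_write",
        emit(mentions, "pvalue_mentions.csv",
             key = c("article_id", "phrase", "distance")))
  psum <- stage("summarize_pvalues", summarize_pvalues(mentions))
  psum_tab <- data.frame(
    statistic = c("n_windows", "n_extracted", "extraction_rate",
                  "q05", "q25", "median", "q75", "q95",
                  paste0("prop_", psum$categories$category),
                  paste0("ci_low_", psum$categories$category),
                  paste0("ci_high_", psum$categories$category)),
    value = c(psum$n_windows, psum$n, psum$extraction_rate,
              unname(psum$quantiles), psum$categories$proportion,
              psum$categories$ci_low, psum$categories$ci_high))
  stage("pvalue_summary_write", emit(psum_tab, "pvalue_summary.csv"))

  manifest <- list(
    package = "almostsig",
    package_version = as.character(utils::packageVersion("almostsig")),
    config = config_as_list(config),
    corpus_md5 = unname(tools::md5sum(
      if (dir.exists(config$corpus)) {
        file.path(config$corpus, "dates.csv")
      } else config$corpus)),
    dictionary_md5 = unname(tools::md5sum(config$dictionary)),
    n_phrases = length(dict),
    counts = as.list(summary_tab$value),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(sort(written)))),
      basename(sort(written))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!quiet) {
    message("pipeline bundle written to ", config$out_dir, " (",
            length(written) + 1L, " files)")
  }
  invisible(list(corpus_counts = counts, summary = scan$summary,
                 hits = scan$hits, phrase_counts = pc, prevalence = prev,
                 trends = trends, mentions = mentions,
                 pvalue_summary = psum, manifest = manifest))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$bf <- unclass(out$bf)
  out
}

#' Self-contained demonstration run on a synthetic corpus
#'
#' Generates a synthetic corpus of 30 years by \code{docs_per_year}
#' documents with a handful of phrase specifications — one phrase at the
#' constant overall prevalence reported for almost-significance phrasing
#' (8.65 per cent), one with a strong increasing trend, one with a
#' decreasing trend and one rare stable phrase — then runs the full
#' pipeline against the shipped 505-phrase dictionary.
#'
#' @param seed integer seed driving corpus generation.
#' @param out_dir output directory (default: a subdirectory of
#'   \code{tempdir()}).
#' @param docs_per_year documents per year (default 500).
#' @param quiet suppress progress messages.
#' @return the [run_pipeline()] result list, with the generation
#'   \code{ground_truth} attached.
#' @export
demo_pipeline <- function(seed = 1L, out_dir = file.path(tempdir(),
                                                         "almostsig-demo"),
                          docs_per_year = 500L, quiet = FALSE) {
  specs <- data.frame(
    phrase = c("marginally significant", "a numerical trend",
               "failed to reach statistical significance",
               "a borderline trend"),
    pi0 = c(0.0865, 0.02, 0.03, 0.004),
    beta = c(0, 0.08, -0.06, 0),
    stringsAsFactors = FALSE)
  cfg <- synthetic_config(years = 1990:2019,
                          docs_per_year = docs_per_year,
                          phrase_specs = specs, seed = seed)
  gen <- generate_corpus(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  corpus_path <- file.path(out_dir, "corpus_synthetic.jsonl")
  write_corpus_jsonl(gen$corpus, corpus_path)
  res <- run_pipeline(pipeline_config(corpus = corpus_path,
                                      format = "jsonl",
                                      out_dir = out_dir, seed = seed),
                      quiet = quiet)
  attr(res, "ground_truth") <- gen$ground_truth
  invisible(res)
}
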