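#' Read a corpus of article records
#'
#' Loads plain-text article records from JSONL (one object per line with
#' fields \code{id}, \code{year}, optional \code{month}, \code{text}),
#' CSV with the same columns, or a directory of \code{<id>.txt} files with
#' a sidecar \code{dates.csv} (columns \code{id}, \code{year}, optional
#' \code{month}). Text is normalized with [normalize_text()] and the
#' publication time-frame filter January 1990 through September 2020 is
#' applied: records with a month are kept when the (year, month) pair lies
#' inside the window; records without a month are kept at year level
#' (1990--2020).
#'
#' @param path file (jsonl/csv) or directory (txt_dir).
#' @param format one of \code{"jsonl"}, \code{"csv"}, \code{"txt_dir"}.
#' @param quiet suppress the read/kept/dropped message.
#' @return a \code{data.frame} with columns \code{id}, \code{year},
#'   \code{month} (NA when absent), \code{text_raw}, \code{text_norm},
#'   carrying an attribute \code{corpus_counts} =
#'   \code{c(read, kept, dropped)}.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv", "txt_dir"),
                        quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus path does not exist: ", path)
  raw <- switch(format,
    jsonl = read_corpus_jsonl(path),
    csv = read_corpus_csv(path),
    txt_dir = read_corpus_txtdir(path)
  )
  if (nrow(raw) == 0L) stop("empty corpus: ", path)
  as_corpus(raw, quiet = quiet)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), year = integer(0),
                      month = integer(0), text_raw = character(0)))
  }
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("row ", i, ": invalid JSON: ",
                                             conditionMessage(e)))
    for (f in c("id", "year", "text")) {
      if (is.null(obj[[f]])) stop("row ", i, ": missing required field '",
                                  f, "'")
    }
    list(id = as.character(obj$id), year = parse_year(obj$year, i),
         month = parse_month(obj$month, i), text_raw = as.character(obj$text))
  })
  data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    year = vapply(recs, `[[`, integer(1), "year"),
    month = vapply(recs, `[[`, integer(1), "month"),
    text_raw = vapply(recs, `[[`, character(1), "text_raw"),
    stringsAsFactors = FALSE
  )
}

read_corpus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (f in c("id", "year", "text")) {
    if (!f %in% names(df)) stop("corpus CSV lacks required column '", f, "'")
  }
  if (anyNA(df$id) || any(!nzchar(df$id))) {
    stop("row ", which(is.na(df$id) | !nzchar(df$id))[1], ": empty id")
  }
  data.frame(
    id = as.character(df$id),
    year = vapply(seq_len(nrow(df)), function(i) parse_year(df$year[i], i),
                  integer(1)),
    month = if ("month" %in% names(df)) {
      vapply(seq_len(nrow(df)), function(i) parse_month(df$month[i], i),
             integer(1))
    } else rep(NA_integer_, nrow(df)),
    text_raw = as.character(df$text),
    stringsAsFactors = FALSE
  )
}

read_corpus_txtdir <- function(path) {
  sidecar <- file.path(path, "dates.csv")
  if (!file.exists(sidecar)) {
    stop("txt_dir corpus needs a sidecar dates.csv in ", path)
  }
  dates <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  if (!all(c("id", "year") %in% names(dates))) {
    stop("dates.csv must have columns id, year")
  }
  files <- file.path(path, paste0(dates$id, ".txt"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("no .txt file for id(s): ",
         paste(dates$id[missing], collapse = ", "))
  }
  data.frame(
    id = as.character(dates$id),
    year = vapply(seq_len(nrow(dates)), function(i)
      parse_year(dates$year[i], i), integer(1)),
    month = if ("month" %in% names(dates)) {
      vapply(seq_len(nrow(dates)), function(i)
        parse_month(dates$month[i], i), integer(1))
    } else rep(NA_integer_, nrow(dates)),
    text_raw = vapply(files, function(f)
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
      character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

parse_year <- function(y, row) {
  yi <- suppressWarnings(as.integer(y))
  if (length(yi) != 1L || is.na(yi)) stop("row ", row,
                                          ": unparseable year '", y, "'")
  yi
}

parse_month <- function(m, row) {
  if (is.null(m) || length(m) == 0L || is.na(m)) return(NA_integer_)
  mi <- suppressWarnings(as.integer(m))
  if (is.na(mi) || mi < 1L || mi > 12L) stop("row ", row,
                                             ": invalid month '", m, "'")
  mi
}

# time-frame filter: Jan 1990 -- Sep 2020; year-level when month missing
in_time_frame <- function(year, month) {
  ifelse(is.na(month),
         year >= 1990L & year <= 2020L,
         (year > 1990L | (year == 1990L & month >= 1L)) &
           (year < 2020L | (year == 2020L & month <= 9L)) & year >= 1990L)
}

as_corpus <- function(df, quiet = FALSE) {
  if (any(!nzchar(df$id) | is.na(df$id))) {
    stop("row ", which(!nzchar(df$id) | is.na(df$id))[1], ": empty id")
  }
  dup <- duplicated(df$id)
  if (any(dup)) {
    stop("duplicate article id(s): ",
         paste(unique(df$id[dup]), collapse = ", "))
  }
  n_read <- nrow(df)
  keep <- in_time_frame(df$year, df$month)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$text_norm <- normalize_text(out$text_raw)
  counts <- c(read = n_read, kept = nrow(out), dropped = n_read - nrow(out))
  attr(out, "corpus_counts") <- counts
  if (!quiet) {
    message("corpus: read ", counts[["read"]], ", kept ", counts[["kept"]],
            ", dropped ", counts[["dropped"]],
            " (outside Jan 1990 - Sep 2020)")
  }
  out
}

#' Write a result table as deterministic CSV
#'
#' Writes a data.frame as UTF-8 CSV with a header. Rows are sorted by the
#' given key columns and numeric columns are formatted with 17 significant
#' digits so that doubles survive a read/write round trip exactly; two runs
#' on the same input produce byte-identical files.
#'
#' @param df data.frame of homogeneous rows.
#' @param path output file path.
#' @param key character vector of column names to sort by (default: none,
#'   keep row order).
#' @return \code{path}, invisibly.
#' @seealso [read_table()]
#' @export
write_table <- function(df, path, key = NULL) {
  stopifnot(is.data.frame(df))
  if (!is.null(key) && nrow(df) > 0L) {
    missing_key <- setdiff(key, names(df))
    if (length(missing_key)) stop("unknown key column(s): ",
                                  paste(missing_key, collapse = ", "))
    df <- df[do.call(order, df[key]), , drop = FALSE]
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      s[is.infinite(v)] <- ifelse(v[is.infinite(v)] > 0, "Inf", "-Inf")
      out[[j]] <- s
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE, eol = "\n", na = "")
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path CSV file path.
#' @param numeric_cols optional character vector of columns to coerce to
#'   numeric; by default columns are type-detected by \code{read.csv}.
#' @return data.frame.
#' @export
read_table <- function(path, numeric_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        na.strings = "")
  for (col in numeric_cols %||% character(0)) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
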