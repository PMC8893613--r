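#' Load a phrase dictionary
#'
#' Reads a plain-text dictionary, one phrase per line; lines starting with
#' \code{#} are comments and blank lines are skipped (and counted). Every
#' phrase is passed through [normalize_text()] and must already be its own
#' normalization fixed point after that step; duplicates (after
#' normalization) are collapsed order-preservingly with a warning.
#'
#' @param path dictionary file; defaults to the dictionary shipped with the
#'   package (see [default_dictionary()]).
#' @return a character vector of class \code{phrase_dictionary} with
#'   attributes \code{n_duplicates} and \code{n_blank}.
#' @export
load_dictionary <- function(path = default_dictionary_path()) {
  if (!file.exists(path)) stop("dictionary file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- !is_comment & !nzchar(trimws(lines))
  keep_idx <- which(!is_comment & !is_blank)
  if (length(keep_idx) == 0L) stop("dictionary contains no phrases: ", path)
  norm <- normalize_text(lines[keep_idx])
  empty <- !nzchar(norm)
  if (any(empty)) {
    stop("line ", keep_idx[empty][1],
         ": phrase normalizes to the empty string")
  }
  dup <- duplicated(norm)
  if (any(dup)) {
    warning(sum(dup), " duplicate phrase(s) collapsed: ",
            paste(unique(norm[dup]), collapse = ", "))
  }
  phrases <- norm[!dup]
  structure(phrases,
            class = c("phrase_dictionary", "character"),
            n_duplicates = sum(dup),
            n_blank = sum(is_blank),
            source = path)
}

#' The dictionary shipped with the package
#'
#' A synthetic stand-in for the 505-entry dictionary of phrases used to
#' describe results that approach but do not reach statistical
#' significance: it contains the phrases reported in published work on
#' almost-significance phrasing plus template-generated variants of the same
#' linguistic families ("a ... trend", "... significant",
#' "failed to reach ...", "on the verge of ...", ...), padded to exactly
#' 505 unique normalized entries.
#'
#' @return \code{default_dictionary()} loads and returns the
#'   \code{phrase_dictionary}; \code{default_dictionary_path()} returns the
#'   installed file path.
#' @export
default_dictionary <- function() {
  load_dictionary(default_dictionary_path())
}

#' @rdname default_dictionary
#' @export
default_dictionary_path <- function() {
  system.file("extdata", "phrases_synthetic.txt", package = "almostsig",
              mustWork = TRUE)
}

#' @export
print.phrase_dictionary <- function(x, ...) {
  cat("<phrase_dictionary> ", length(x), " phrases (",
      attr(x, "n_duplicates") %||% 0L, " duplicates collapsed)\n", sep = "")
  n <- min(5L, length(x))
  cat(paste0("  ", x[seq_len(n)], collapse = "\n"), "\n")
  if (length(x) > n) cat("  ... and ", length(x) - n, " more\n", sep = "")
  invisible(x)
}
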