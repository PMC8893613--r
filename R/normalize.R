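#' Normalize article text for exact phrase matching
#'
#' Applies the cleaning used throughout the package before any dictionary
#' scan: lowercasing, Unicode canonical decomposition with removal of
#' combining diacritical marks, mapping of curly quote variants to ASCII
#' quotes and of en/em dashes (and the Unicode minus) to a plain hyphen,
#' and collapsing of all whitespace runs (including newlines and
#' non-breaking spaces) to a single space. The multiplication sign
#' \code{U+00D7} is kept as-is because the P-value grammar needs it.
#'
#' The function is total and idempotent:
#' \code{normalize_text(normalize_text(x))} equals \code{normalize_text(x)}.
#'
#' @param x character vector of raw text.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_text("Marginally Significant")
#' normalize_text("café trend")
#' @export
normalize_text <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- as.character(x)
  out <- stringi::stri_trans_tolower(x)
  out <- stringi::stri_trans_nfd(out)
  out <- stringi::stri_replace_all_regex(out, "\\p{Mn}+", "")
  # quote variants -> ASCII; en/em dash and Unicode minus -> hyphen
  # (stringi rather than chartr: byte-oriented translation is unsafe for
  # multibyte code points under a C locale)
  out <- stringi::stri_replace_all_fixed(
    out,
    c("\u2018", "\u2019", "\u201a", "\u201b", "\u201c", "\u201d",
      "\u201e", "\u201f", "\u2013", "\u2014", "\u2212"),
    c("'", "'", "'", "'", "\"", "\"", "\"", "\"", "-", "-", "-"),
    vectorize_all = FALSE)
  out <- stringi::stri_replace_all_regex(out, "[\\s\\u00a0\\p{Z}]+", " ")
  stringi::stri_trim_both(out)
}
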