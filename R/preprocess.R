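#' Canonicalize a raw entity name
#'
#' Reduces an arbitrary surface name to its comparable canonical form:
#' Unicode letters are transliterated to ASCII where a standard decomposition
#' exists ("é" becomes "e"), the string is lowercased, and every run of
#' non-alphanumeric characters becomes a single token boundary. Digits are
#' kept ("HER2" canonicalizes to "her2"). Hyphens and other punctuation split
#' tokens rather than being deleted in place: "beta-blocker" yields tokens
#' "beta", "blocker".
#'
#' The transformation is idempotent and case/punctuation invariant, so two
#' surface forms that differ only in casing, spacing, or punctuation share a
#' canonical form. An input with no alphanumeric characters yields the empty
#' canonical text and an empty token list; downstream matchers treat such
#' queries as unmatched.
#'
#' @param name a character scalar (arbitrary encoding; converted to UTF-8).
#' @return an object of class `canonical_name`: a list with `text` (the
#'   space-joined canonical string) and `tokens` (character vector of
#'   lowercase alphanumeric tokens).
#' @examples
#' preprocess("Non-Small Cell Lung Cancer (NSCLC)")$tokens
#' preprocess("Imatinib")$text
#' @export
preprocess <- function(name) {
  if (inherits(name, "canonical_name")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  text <- canonical_text(name)
  new_canonical_name(text)
}

new_canonical_name <- function(text) {
  tokens <- if (nzchar(text)) strsplit(text, " ", fixed = TRUE)[[1L]] else character(0)
  structure(list(text = text, tokens = tokens), class = "canonical_name")
}

#' Vectorized canonical text
#'
#' The vectorized core of [preprocess()]: returns only the canonical text for
#' each element. Used internally when building dictionaries and running
#' batches.
#'
#' @param x character vector of raw names.
#' @return character vector of canonical texts (`""` when no alphanumeric
#'   character survives).
#' @export
canonical_text <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  x[is.na(x)] <- ""
  x <- enc2utf8(x)
  # Latin-ASCII covers accented Latin letters; unmapped characters stay
  # non-ASCII and fall through to the boundary rule below.
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[^a-z0-9]+", " ")
  stringi::stri_trim_both(x)
}

#' @export
print.canonical_name <- function(x, ...) {
  cat("<canonical_name> \"", x$text, "\" (", length(x$tokens), " tokens)\n",
      sep = "")
  invisible(x)
}
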