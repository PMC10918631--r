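#' Match result
#'
#' The outcome of one matcher (or of the whole cascade) for one query:
#' `step` is one of `"exact"`, `"token"`, `"ngram"`, `"partial"`, `"none"`;
#' `matched_names` are the canonical texts of the matched entries;
#' `identifiers` is the union of their identifier sets; `distance` is the
#' normalized edit distance (present only for partial matches). `step ==
#' "none"` iff both sets are empty.
#'
#' @param query a `canonical_name`.
#' @param dict a `reference_dictionary`.
#' @param idx integer vector of matched entry indices (internal).
#' @param step step label (internal).
#' @param distance normalized distance or `NA` (internal).
#' @name match_result
#' @keywords internal
NULL

new_match_result <- function(query, dict, idx, step, distance = NA_real_) {
  if (length(idx) == 0L) {
    step <- "none"
    distance <- NA_real_
  }
  structure(list(query = query,
                 matched_names = if (length(idx)) dict$canonical[idx] else character(0),
                 identifiers = if (length(idx)) dict_entry_ids(dict, idx) else character(0),
                 step = step,
                 distance = distance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> \"%s\" -> step %s%s; ids: %s\n",
              x$query$text, x$step,
              if (!is.na(x$distance)) sprintf(" (distance %.4g)", x$distance) else "",
              if (length(x$identifiers)) paste(x$identifiers, collapse = ";") else "-"))
  invisible(x)
}

as_canonical <- function(query) {
  if (inherits(query, "canonical_name")) query else preprocess(query)
}

# Per-session counters of matcher invocations; used to verify cascade
# short-circuiting (fuzzy matchers must never run for exact hits).
.match_counters <- new.env(parent = emptyenv())

reset_match_counters <- function() {
  for (s in c("exact", "token", "ngram", "partial"))
    assign(s, 0L, envir = .match_counters)
  invisible(NULL)
}

match_counters <- function() {
  if (is.null(.match_counters$exact)) reset_match_counters()
  c(exact = .match_counters$exact, token = .match_counters$token,
    ngram = .match_counters$ngram, partial = .match_counters$partial)
}

bump_counter <- function(step) {
  cur <- get0(step, envir = .match_counters, ifnotfound = 0L)
  assign(step, cur + 1L, envir = .match_counters)
}

#' Step 1: exact match of the canonical text
#'
#' Looks the query's canonical text up in the dictionary's exact index.
#' An empty canonical text never matches.
#'
#' @param query a `canonical_name` or raw character scalar.
#' @param dict a `reference_dictionary`.
#' @return a `match_result` with step `"exact"` or `"none"`.
#' @export
exact_match <- function(query, dict) {
  query <- as_canonical(query)
  bump_counter("exact")
  idx <- if (nzchar(query$text))
    get0(query$text, envir = dict$exact_index, ifnotfound = NULL)
  else NULL
  new_match_result(query, dict, as.integer(idx), "exact")
}

#' Step 2a: order-invariant token match
#'
#' Matches entries whose sorted-token key equals the query's sorted-token
#' key, i.e. names that are word permutations of one another ("cancer, lung"
#' matches "lung cancer").
#'
#' @inheritParams exact_match
#' @return a `match_result` with step `"token"` or `"none"`.
#' @export
token_match <- function(query, dict) {
  query <- as_canonical(query)
  bump_counter("token")
  idx <- if (length(query$tokens))
    get0(token_key_of(query$tokens), envir = dict$token_index, ifnotfound = NULL)
  else NULL
  new_match_result(query, dict, as.integer(idx), "token")
}

#' Step 2b: word n-gram containment match
#'
#' Matches in either direction of containment: (a) some word n-gram of the
#' query equals a reference entry's canonical text (or is a token
#' permutation of it), so "invasive ductal carcinoma of breast" finds the
#' entry "ductal carcinoma"; or (b) the query's full canonical text equals
#' one of a reference entry's word n-grams, so "ductal carcinoma" finds
#' "invasive ductal carcinoma". Entries hit by either rule are unioned.
#'
#' @inheritParams exact_match
#' @param n word n-gram size; defaults to the dictionary's `ngram_size`.
#' @return a `match_result` with step `"ngram"` or `"none"`.
#' @export
ngram_match <- function(query, dict, n = dict$ngram_size) {
  query <- as_canonical(query)
  bump_counter("ngram")
  idx <- integer(0)
  if (length(query$tokens)) {
    grams <- unique(word_ngrams(query$tokens, n))
    for (g in grams) {
      hit <- get0(g, envir = dict$exact_index, ifnotfound = NULL)
      if (!is.null(hit)) idx <- c(idx, hit)
      gk <- token_key_of(strsplit(g, " ", fixed = TRUE)[[1L]])
      hit <- get0(gk, envir = dict$token_index, ifnotfound = NULL)
      if (!is.null(hit)) idx <- c(idx, hit)
    }
    if (n == dict$ngram_size) {
      hit <- get0(query$text, envir = dict$gram_index, ifnotfound = NULL)
      if (!is.null(hit)) idx <- c(idx, hit)
    } else {
      # gram index was built for a different n: recompute reference grams
      for (i in seq_along(dict$canonical)) {
        if (query$text %in% word_ngrams(dict$tokens[[i]], n)) idx <- c(idx, i)
      }
    }
  }
  new_match_result(query, dict, sort(unique(as.integer(idx))), "ngram")
}

#' Step 3: normalized edit-distance ("partial") match
#'
#' Computes the normalized edit distance between the query's canonical text
#' and every entry's canonical text (spaces count as characters), and
#' returns all entries attaining the minimum distance, provided that minimum
#' is at or below `threshold` (inclusive). Returning only the closest set —
#' rather than everything under the threshold — minimizes the number of
#' identifiers a curator has to inspect; ties return all co-minimal entries.
#' This step scans the full dictionary and is therefore the costly one the
#' cascade defers to last.
#'
#' @inheritParams exact_match
#' @param threshold maximum allowed normalized distance, in \[0, 1\];
#'   default 0.2 (20% of the longer name).
#' @return a `match_result` with step `"partial"` (with `distance` set) or
#'   `"none"`.
#' @export
partial_match <- function(query, dict, threshold = 0.2) {
  query <- as_canonical(query)
  stopifnot(threshold >= 0, threshold <= 1)
  bump_counter("partial")
  if (!nzchar(query$text)) return(new_match_result(query, dict, integer(0), "partial"))
  d <- levenshtein(query$text, dict$canonical)
  nd <- d / pmax(nchar(query$text), nchar(dict$canonical))
  ok <- which(nd <= threshold)
  if (length(ok) == 0L) return(new_match_result(query, dict, integer(0), "partial"))
  dmin <- min(nd[ok])
  idx <- ok[nd[ok] == dmin]
  new_match_result(query, dict, idx, "partial", distance = dmin)
}
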