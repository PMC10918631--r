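#' Word n-grams of a token sequence
#'
#' Contiguous windows of `n` tokens, each joined by single spaces, in order.
#' Sequences shorter than `n` yield the single gram of all their tokens (so a
#' one-token drug name is still indexed under a bigram index); an empty token
#' list yields no grams.
#'
#' @param tokens character vector of tokens.
#' @param n window size, integer >= 1.
#' @return character vector of grams.
#' @examples
#' word_ngrams(c("small", "cell", "lung", "carcinoma"), 2)
#' @export
word_ngrams <- function(tokens, n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  t <- length(tokens)
  if (t == 0L) return(character(0))
  if (t < n) return(paste(tokens, collapse = " "))
  vapply(seq_len(t - n + 1L),
         function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
         character(1))
}

token_key_of <- function(tokens) {
  # lexicographic sort must not depend on the user's locale
  paste(stringi::stri_sort(tokens, locale = "C"), collapse = " ")
}

#' Build a reference dictionary
#'
#' Preprocesses every (name, identifier) pair and builds the three lookup
#' structures the matching cascade uses: an exact index keyed by canonical
#' text, a token index keyed by the sorted-token key (order-invariant), and a
#' word n-gram index mapping each gram of an entry to the entries containing
#' it. Surface forms whose canonical texts collide are merged into one entry
#' whose identifier set is the union — ontologies legitimately share surface
#' forms across identifiers, and callers decide how to handle multi-identifier
#' results. Names that canonicalize to the empty string are dropped; their
#' count is available as `n_dropped` (with a warning at build time).
#'
#' @param pairs a data.frame whose first two columns are raw name and
#'   identifier (columns `name` and `id` if named), or a list of length-2
#'   vectors.
#' @param ngram_size word n-gram window size for the gram index; default 2
#'   (bigrams), the operating point at which gram matching trades recall
#'   against result-set size well for cancer-type names.
#' @return an object of class `reference_dictionary` with fields `canonical`
#'   (character vector of entry canonical texts), `tokens`, `token_key`,
#'   `identifiers` (list of character vectors), `raw_names`, the three index
#'   environments, `ngram_size` and `n_dropped`.
#' @examples
#' d <- build_dictionary(data.frame(name = c("Imatinib", "Gleevec"),
#'                                  id = c("CHEMBL941", "CHEMBL941")))
#' d$canonical
#' @export
build_dictionary <- function(pairs, ngram_size = 2L) {
  pairs <- as_pairs_df(pairs)
  if (nrow(pairs) == 0L) stop("empty pairs list: cannot build a usable dictionary")
  ngram_size <- as.integer(ngram_size)
  stopifnot(length(ngram_size) == 1L, !is.na(ngram_size), ngram_size >= 1L)

  canon <- canonical_text(pairs$name)
  keep <- nzchar(canon) & !is.na(pairs$id) & nzchar(pairs$id)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(sprintf("dropped %d pair(s) with empty canonical name or identifier",
                    n_dropped))
  if (!any(keep)) stop("no usable pairs after preprocessing")
  canon <- canon[keep]
  ids <- as.character(pairs$id)[keep]
  raw <- as.character(pairs$name)[keep]

  # merge canonical collisions
  grp <- split(seq_along(canon), canon)
  canonical <- names(grp)
  identifiers <- lapply(grp, function(i) sort(unique(ids[i])))
  raw_names <- lapply(grp, function(i) sort(unique(raw[i])))
  tokens <- strsplit(canonical, " ", fixed = TRUE)
  token_key <- vapply(tokens, token_key_of, character(1))

  exact_index <- new.env(parent = emptyenv(), hash = TRUE,
                         size = max(29L, length(canonical)))
  token_index <- new.env(parent = emptyenv(), hash = TRUE,
                         size = max(29L, length(canonical)))
  gram_index <- new.env(parent = emptyenv(), hash = TRUE,
                        size = max(29L, 2L * length(canonical)))
  for (i in seq_along(canonical)) {
    assign(canonical[i], i, envir = exact_index)
    k <- token_key[i]
    token_index[[k]] <- c(if (!is.null(token_index[[k]])) token_index[[k]], i)
    for (g in unique(word_ngrams(tokens[[i]], ngram_size))) {
      gram_index[[g]] <- c(if (!is.null(gram_index[[g]])) gram_index[[g]], i)
    }
  }

  structure(list(canonical = canonical,
                 tokens = tokens,
                 token_key = token_key,
                 identifiers = unname(identifiers),
                 raw_names = unname(raw_names),
                 exact_index = exact_index,
                 token_index = token_index,
                 gram_index = gram_index,
                 ngram_size = ngram_size,
                 n_dropped = n_dropped),
            class = "reference_dictionary")
}

as_pairs_df <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(ncol(pairs) >= 2L)
    nm <- if (all(c("name", "id") %in% names(pairs))) pairs[c("name", "id")]
          else pairs[, 1:2]
    names(nm) <- c("name", "id")
    nm$name <- as.character(nm$name)
    nm$id <- as.character(nm$id)
    return(nm)
  }
  if (is.list(pairs)) {
    stopifnot(all(vapply(pairs, length, 1L) == 2L))
    return(data.frame(name = vapply(pairs, function(p) as.character(p[[1]]), ""),
                      id = vapply(pairs, function(p) as.character(p[[2]]), ""),
                      stringsAsFactors = FALSE))
  }
  stop("pairs must be a data.frame or a list of (name, identifier) pairs")
}

#' @export
print.reference_dictionary <- function(x, ...) {
  cat(sprintf("<reference_dictionary> %d entries, %d identifiers, ngram_size=%d%s\n",
              length(x$canonical),
              length(unique(unlist(x$identifiers))),
              x$ngram_size,
              if (x$n_dropped > 0) sprintf(" (%d dropped)", x$n_dropped) else ""))
  invisible(x)
}

#' @export
length.reference_dictionary <- function(x) length(x$canonical)

dict_entry_ids <- function(dict, idx) {
  sort(unique(unlist(dict$identifiers[idx], use.names = FALSE)))
}
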