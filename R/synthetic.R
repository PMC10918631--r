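# Seeded synthetic dictionaries and gold standards with known ground truth.
#
# Dictionary names are built from a consonant-vowel syllable vocabulary
# (consonants b..z minus j,q,w,x,y) while perturbation context words and
# unmatchable queries use the disjoint alphabet {j,q,w,x,y}+vowels, so
# context tokens can never collide with dictionary tokens.

VOCAB_CONSONANTS <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n",
                      "p", "r", "s", "t", "v", "z")
ALIEN_CONSONANTS <- c("j", "q", "w", "x", "y")
VOWELS <- c("a", "e", "i", "o", "u")

PERTURBATION_KINDS <- c("identity", "case_punct", "token_shuffle",
                        "embed_in_phrase", "char_edit", "unmatchable")

# run expr under a seed, restoring (or clearing) the caller's RNG state
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_word <- function(consonants, n_syllables = sample(2:4, 1L)) {
  paste0(paste0(sample(consonants, n_syllables, replace = TRUE),
                sample(VOWELS, n_syllables, replace = TRUE)),
         collapse = "")
}

#' Generate a synthetic reference dictionary
#'
#' Draws `n_entries` names of 1–4 tokens from a seeded synthetic vocabulary,
#' under three separation constraints enforced by rejection sampling:
#' canonical texts are pairwise distinct, sorted-token keys are pairwise
#' distinct (so no entry is a word permutation of another), and every pair
#' of canonical texts has normalized edit distance greater than
#' `2 * partial_threshold`. The separation makes perturbation ground truth
#' unambiguous: a query within the threshold of its source entry cannot be
#' equally close to any other entry, so the expected match of every
#' perturbed record is unique. Real dictionaries lack this property, which
#' is one reason real-data F1 stays below 1.
#'
#' @param n_entries number of dictionary entries, >= 1.
#' @param vocab_size size of the token vocabulary, default 200.
#' @param seed integer seed; the same seed reproduces the same pairs.
#' @param partial_threshold the partial-matching threshold the separation is
#'   calibrated against, default 0.2.
#' @return data.frame with columns `name`, `id` (identifiers `SYN:0001`...).
#' @export
make_dictionary <- function(n_entries, vocab_size = 200L, seed = 1L,
                            partial_threshold = 0.2) {
  stopifnot(n_entries >= 1L, vocab_size >= 8L)
  min_sep <- 2 * partial_threshold
  with_seed(seed, {
    vocab <- character(0)
    tries <- 0L
    while (length(vocab) < vocab_size && tries < 50L * vocab_size) {
      vocab <- unique(c(vocab, random_word(VOCAB_CONSONANTS)))
      tries <- tries + 1L
    }
    if (length(vocab) < vocab_size)
      stop("could not build a vocabulary of the requested size")

    canon <- character(0)
    keys <- character(0)
    max_tries <- 200L * n_entries
    tries <- 0L
    while (length(canon) < n_entries && tries < max_tries) {
      tries <- tries + 1L
      k <- sample(1:4, 1L)
      name <- paste(sample(vocab, k), collapse = " ")
      if (nchar(name) < 5L) next                       # room for >=1 char edit
      key <- token_key_of(strsplit(name, " ", fixed = TRUE)[[1L]])
      if (name %in% canon || key %in% keys) next
      if (length(canon)) {
        nd <- normalized_edit_distance(name, canon)
        if (any(nd <= min_sep)) next
      }
      canon <- c(canon, name)
      keys <- c(keys, key)
    }
    if (length(canon) < n_entries)
      stop("could not satisfy dictionary separation constraints after ",
           max_tries, " tries; use fewer entries or a larger vocabulary")
    data.frame(name = canon,
               id = sprintf("SYN:%04d", seq_len(n_entries)),
               stringsAsFactors = FALSE)
  })
}

#' Perturb a name
#'
#' Applies one named transformation to a surface name, producing a query
#' whose earliest recoverable cascade step is determined by `kind`:
#' `identity` and `case_punct` (random case flips plus punctuation noise
#' that preprocessing removes) are recovered at step exact; `token_shuffle`
#' (a non-identity token permutation) at step token; `embed_in_phrase`
#' (the name embedded in unrelated context words) at step ngram when the
#' name has exactly `ngram_size` tokens; `char_edit` (exactly `edit_count`
#' random character substitutions/insertions/deletions on the canonical
#' text) at step partial while the resulting normalized distance stays
#' within the threshold; `unmatchable` replaces the name with an
#' out-of-vocabulary string.
#'
#' `token_shuffle` on a one-token name falls back to identity and flags the
#' result with attribute `fallback = TRUE`.
#'
#' @param name a non-empty raw name.
#' @param kind one of `r paste(PERTURBATION_KINDS, collapse = ", ")`.
#' @param edit_count number of character edits for `char_edit`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [make_gold()]).
#' @return a character scalar (possibly with attribute `fallback`).
#' @export
perturb <- function(name, kind = PERTURBATION_KINDS, edit_count = 1L,
                    seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  run <- function() perturb_impl(name, kind, as.integer(edit_count))
  if (is.null(seed)) run() else with_seed(seed, run())
}

perturb_impl <- function(name, kind, edit_count) {
  canon <- canonical_text(name)
  tokens <- if (nzchar(canon)) strsplit(canon, " ", fixed = TRUE)[[1L]] else character(0)
  switch(kind,
    identity = name,
    case_punct = perturb_case_punct(tokens),
    token_shuffle = {
      if (length(tokens) < 2L || length(unique(tokens)) < 2L) {
        out <- name
        attr(out, "fallback") <- TRUE
        out
      } else {
        repeat {
          sh <- sample(tokens)
          if (!identical(sh, tokens)) break
        }
        paste(sh, collapse = " ")
      }
    },
    embed_in_phrase = {
      pre <- replicate(sample(1:2, 1L), random_word(ALIEN_CONSONANTS))
      post <- if (stats::runif(1) < 0.5)
        replicate(sample(1:2, 1L), random_word(ALIEN_CONSONANTS)) else character(0)
      paste(c(pre, tokens, post), collapse = " ")
    },
    char_edit = perturb_char_edit(canon, edit_count),
    unmatchable = paste(replicate(sample(2:3, 1L),
                                  random_word(ALIEN_CONSONANTS, sample(3:4, 1L))),
                        collapse = " ")
  )
}

perturb_case_punct <- function(tokens) {
  toks <- vapply(tokens, function(tk) {
    ch <- strsplit(tk, "")[[1L]]
    flip <- stats::runif(length(ch)) < 0.5
    ch[flip] <- toupper(ch[flip])
    paste(ch, collapse = "")
  }, character(1))
  seps <- sample(c(" ", "-", ", ", " - ", "  ", "/"),
                 max(0L, length(toks) - 1L), replace = TRUE)
  body <- if (length(toks) == 1L) toks else
    paste0(paste0(toks[-length(toks)], seps, collapse = ""), toks[length(toks)])
  wrap <- sample(c("", "(", "  "), 1L)
  tail <- sample(c("", ")", ".", "!"), 1L)
  paste0(wrap, body, tail)
}

# exactly edit_count letter-level edits on a canonical text; never touches
# spaces and never empties a token, so the result is its own canonical form
# and lev(result, canon) <= edit_count
perturb_char_edit <- function(canon, edit_count) {
  stopifnot(edit_count >= 1L)
  letters_pool <- c(VOCAB_CONSONANTS, VOWELS)
  s <- strsplit(canon, "")[[1L]]
  for (e in seq_len(edit_count)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    nonspace <- which(s != " ")
    if (op == "del") {
      # deletable: non-space chars whose token has >= 2 chars
      tok_len <- function(i) {
        l <- i; while (l > 1L && s[l - 1L] != " ") l <- l - 1L
        r <- i; while (r < length(s) && s[r + 1L] != " ") r <- r + 1L
        r - l + 1L
      }
      cand <- nonspace[vapply(nonspace, tok_len, 1L) >= 2L]
      if (length(cand) == 0L) op <- "sub"
      else s <- s[-sample_one(cand)]
    }
    if (op == "sub") {
      i <- sample_one(nonspace)
      s[i] <- sample_one(setdiff(letters_pool, s[i]))
    } else if (op == "ins") {
      i <- sample.int(length(s) + 1L, 1L)   # insert before position i
      s <- append(s, sample_one(letters_pool), after = i - 1L)
    }
  }
  paste(s, collapse = "")
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# structural membership checks against the dictionary indexes, used to
# guarantee that a generated query cannot be caught by an earlier step
hits_exact <- function(text, dict) {
  nzchar(text) && !is.null(get0(text, envir = dict$exact_index, ifnotfound = NULL))
}
hits_token <- function(text, dict) {
  toks <- if (nzchar(text)) strsplit(text, " ", fixed = TRUE)[[1L]] else character(0)
  length(toks) > 0L &&
    !is.null(get0(token_key_of(toks), envir = dict$token_index, ifnotfound = NULL))
}
hits_ngram <- function(text, dict) {
  toks <- if (nzchar(text)) strsplit(text, " ", fixed = TRUE)[[1L]] else character(0)
  if (length(toks) == 0L) return(FALSE)
  for (g in unique(word_ngrams(toks, dict$ngram_size))) {
    if (!is.null(get0(g, envir = dict$exact_index, ifnotfound = NULL))) return(TRUE)
    gk <- token_key_of(strsplit(g, " ", fixed = TRUE)[[1L]])
    if (!is.null(get0(gk, envir = dict$token_index, ifnotfound = NULL))) return(TRUE)
  }
  !is.null(get0(text, envir = dict$gram_index, ifnotfound = NULL))
}

#' Generate a synthetic gold standard
#'
#' Draws `n_records` gold-standard records from a dictionary according to a
#' mix of perturbation kinds, recording for every record the identifier it
#' must normalize to (or the negative marker) and the earliest cascade step
#' able to recover it. `char_edit` queries are rejection-sampled until the
#' perturbed name is within `partial_threshold` of its source entry and
#' strictly beyond it for every other entry, and is invisible to the exact,
#' token and n-gram steps; `unmatchable` queries are resampled until their
#' normalized distance to every dictionary name exceeds
#' `2 * partial_threshold` and no step can match them.
#'
#' @param dictionary_pairs data.frame of (name, id) pairs, e.g. from
#'   [make_dictionary()].
#' @param mix named numeric vector of proportions over the perturbation
#'   kinds (must sum to 1). Default: 20% identity, 20% case/punctuation,
#'   20% token shuffle, 10% phrase embedding, 20% character edits, 10%
#'   unmatchable.
#' @param n_records number of gold records.
#' @param seed integer seed; same seed, same gold standard.
#' @param partial_threshold,ngram_size cascade parameters the ground truth
#'   is constructed against.
#' @param edit_count character edits per `char_edit` record.
#' @return an object of class `synthetic_gold`: list with `dictionary_pairs`,
#'   `records` (data.frame `query`, `expected`), `expected_step`, `kind` and
#'   `params`.
#' @export
make_gold <- function(dictionary_pairs,
                      mix = c(identity = 0.2, case_punct = 0.2,
                              token_shuffle = 0.2, embed_in_phrase = 0.1,
                              char_edit = 0.2, unmatchable = 0.1),
                      n_records = 100L, seed = 1L,
                      partial_threshold = 0.2, ngram_size = 2L,
                      edit_count = 1L) {
  stopifnot(!is.null(names(mix)), all(names(mix) %in% PERTURBATION_KINDS),
            all(mix >= 0), abs(sum(mix) - 1) < 1e-8, n_records >= 1L)
  dict <- build_dictionary(dictionary_pairs, ngram_size)
  entry_id <- vapply(dict$identifiers, `[[`, "", 1L)
  n_tok <- lengths(dict$tokens)

  # largest-remainder apportionment of n_records over the mix
  raw_n <- mix * n_records
  counts <- floor(raw_n)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    extra <- order(raw_n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }

  pools <- list(
    identity = seq_along(dict$canonical),
    case_punct = seq_along(dict$canonical),
    token_shuffle = which(n_tok >= 2L &
                            vapply(dict$tokens, function(t) length(unique(t)) >= 2L, TRUE)),
    embed_in_phrase = which(n_tok == ngram_size),
    char_edit = which(nchar(dict$canonical) >= ceiling(edit_count / partial_threshold)),
    unmatchable = NA
  )
  for (k in names(counts)) {
    if (counts[[k]] > 0L && k != "unmatchable" && length(pools[[k]]) == 0L)
      stop(sprintf("dictionary has no entry eligible for kind '%s'", k))
  }

  expected_for <- c(identity = "exact", case_punct = "exact",
                    token_shuffle = "token", embed_in_phrase = "ngram",
                    char_edit = "partial", unmatchable = "none")

  with_seed(seed, {
    kinds <- sample(rep(names(counts), times = counts))
    query <- character(n_records)
    expected <- character(n_records)
    for (r in seq_len(n_records)) {
      k <- kinds[r]
      if (k == "unmatchable") {
        q <- resample_until(function() perturb_impl("x", "unmatchable", edit_count),
                            function(q) {
                              ct <- canonical_text(q)
                              !hits_exact(ct, dict) && !hits_token(ct, dict) &&
                                !hits_ngram(ct, dict) &&
                                min(normalized_edit_distance(ct, dict$canonical)) >
                                  2 * partial_threshold
                            }, what = "unmatchable query")
        query[r] <- q
        expected[r] <- NO_MATCH_MARKER
      } else if (k == "char_edit") {
        src <- sample_one(pools[[k]])
        q <- resample_until(function() perturb_char_edit(dict$canonical[src], edit_count),
                            function(q) {
                              if (q == dict$canonical[src]) return(FALSE)
                              if (hits_exact(q, dict) || hits_token(q, dict) ||
                                  hits_ngram(q, dict)) return(FALSE)
                              nd <- normalized_edit_distance(q, dict$canonical)
                              nd[src] <= partial_threshold && nd[src] > 0 &&
                                all(nd[-src] > partial_threshold)
                            }, what = "char_edit query")
        query[r] <- q
        expected[r] <- entry_id[src]
      } else {
        src <- sample_one(pools[[k]])
        query[r] <- as.character(perturb_impl(dict$canonical[src], k, edit_count))
        expected[r] <- entry_id[src]
      }
    }
    structure(list(dictionary_pairs = dictionary_pairs,
                   records = data.frame(query = query, expected = expected,
                                        stringsAsFactors = FALSE),
                   expected_step = unname(expected_for[kinds]),
                   kind = kinds,
                   params = list(mix = as.list(mix), n_records = n_records,
                                 seed = as.integer(seed),
                                 partial_threshold = partial_threshold,
                                 ngram_size = as.integer(ngram_size),
                                 edit_count = as.integer(edit_count))),
              class = "synthetic_gold")
  })
}

resample_until <- function(gen, ok, max_tries = 200L, what = "sample") {
  for (i in seq_len(max_tries)) {
    x <- gen()
    if (ok(x)) return(x)
  }
  stop("could not generate a valid ", what, " after ", max_tries, " tries")
}

#' @export
print.synthetic_gold <- function(x, ...) {
  cat(sprintf("<synthetic_gold> %d records over %d dictionary pairs (seed %d)\n",
              nrow(x$records), nrow(x$dictionary_pairs), x$params$seed))
  print(table(x$kind))
  invisible(x)
}

#' Write synthetic fixtures to disk
#'
#' Writes the dictionary as a two-column synonym-table TSV (`id`, `name`),
#' the gold standard in the two-column gold format (`query`, `expected`),
#' and a JSON manifest of all generator parameters, so the files round-trip
#' through [parse_synonym_table()] and [read_gold_standard()] and the CLI.
#'
#' @param gold a `synthetic_gold` object.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the three paths.
#' @export
write_fixtures <- function(gold, dir) {
  stopifnot(inherits(gold, "synthetic_gold"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dict_path <- file.path(dir, "dictionary.tsv")
  gold_path <- file.path(dir, "gold.tsv")
  manifest_path <- file.path(dir, "manifest.json")
  utils::write.table(data.frame(id = gold$dictionary_pairs$id,
                                name = gold$dictionary_pairs$name),
                     dict_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gold$records, gold_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(gold$params, list(n_dictionary = nrow(gold$dictionary_pairs))),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(dictionary = dict_path, gold = gold_path, manifest = manifest_path))
}
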