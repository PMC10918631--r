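#' Cascade configuration
#'
#' Bundles the tunable parameters of the matching cascade. Defaults mirror
#' the recommended operating point: partial threshold 0.2 (a query may
#' differ from a reference name in up to 20% of the longer name's
#' characters), word bigrams for gram matching, all steps enabled. Moderate
#' thresholds (20%–30%) with bigrams buy recall at little precision cost;
#' higher thresholds inflate the number of candidate identifiers returned.
#'
#' @param partial_threshold maximum normalized edit distance for step 3, in
#'   \[0, 1\].
#' @param ngram_size word n-gram window for step 2b, integer >= 1.
#' @param enable_token,enable_ngram,enable_partial logical flags switching
#'   individual fuzzy steps off (exact matching always runs).
#' @return an object of class `match_config`.
#' @export
match_config <- function(partial_threshold = 0.2, ngram_size = 2L,
                         enable_token = TRUE, enable_ngram = TRUE,
                         enable_partial = TRUE) {
  stopifnot(is.numeric(partial_threshold), length(partial_threshold) == 1L,
            partial_threshold >= 0, partial_threshold <= 1)
  ngram_size <- as.integer(ngram_size)
  stopifnot(!is.na(ngram_size), ngram_size >= 1L)
  structure(list(partial_threshold = partial_threshold,
                 ngram_size = ngram_size,
                 enable_token = isTRUE(enable_token),
                 enable_ngram = isTRUE(enable_ngram),
                 enable_partial = isTRUE(enable_partial)),
            class = "match_config")
}

#' Normalize one name through the matching cascade
#'
#' Preprocesses the raw name, then applies the matchers in fixed order of
#' increasing cost — exact, token, n-gram, partial — stopping at the first
#' step that finds a match. The costly steps only ever run for queries the
#' cheap steps could not resolve, which is what makes batch normalization
#' fast when most queries are clean. Unmatched queries return step
#' `"none"`; nothing errors.
#'
#' @param raw a raw name (character scalar) or a `canonical_name`.
#' @param dict a `reference_dictionary`.
#' @param config a [match_config()].
#' @return an object of class `cascade_trace`: list with `result` (a
#'   `match_result`), `steps_attempted` (ordered character vector of the
#'   steps that actually ran) and `elapsed` (seconds, wall time).
#' @examples
#' d <- build_dictionary(data.frame(name = "Imatinib", id = "CHEMBL941"))
#' normalize_name("imatinab", d)$result$step   # "partial"
#' @export
normalize_name <- function(raw, dict, config = match_config()) {
  stopifnot(inherits(dict, "reference_dictionary"),
            inherits(config, "match_config"))
  t0 <- proc.time()[["elapsed"]]
  query <- as_canonical(raw)
  steps <- character(0)

  res <- exact_match(query, dict)
  steps <- c(steps, "exact")
  if (res$step == "none" && config$enable_token) {
    res <- token_match(query, dict)
    steps <- c(steps, "token")
  }
  if (res$step == "none" && config$enable_ngram) {
    res <- ngram_match(query, dict, config$ngram_size)
    steps <- c(steps, "ngram")
  }
  if (res$step == "none" && config$enable_partial) {
    res <- partial_match(query, dict, config$partial_threshold)
    steps <- c(steps, "partial")
  }
  structure(list(result = res,
                 steps_attempted = steps,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "cascade_trace")
}

#' @export
print.cascade_trace <- function(x, ...) {
  cat(sprintf("<cascade_trace> attempted [%s]\n",
              paste(x$steps_attempted, collapse = ", ")))
  print(x$result)
  invisible(x)
}

#' Normalize a batch of names
#'
#' Element-wise [normalize_name()], order preserved. Use
#' [time_batch()] for an aggregate timing and step-attempt summary, and
#' [batch_identifiers()] to extract the predicted identifier sets for
#' scoring.
#'
#' @param raws character vector of raw names.
#' @inheritParams normalize_name
#' @return list of `cascade_trace`, one per input.
#' @export
normalize_batch <- function(raws, dict, config = match_config()) {
  lapply(as.character(raws), normalize_name, dict = dict, config = config)
}

#' Extract identifier sets from a batch of traces
#'
#' @param traces list of `cascade_trace` from [normalize_batch()].
#' @return list of character vectors (empty vector for unmatched queries).
#' @export
batch_identifiers <- function(traces) {
  lapply(traces, function(tr) tr$result$identifiers)
}
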