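#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions, and
#' substitutions transforming `a` into `b`. Computed by a two-row dynamic
#' program in C++; vectorized with scalar recycling on either argument.
#'
#' @param a,b character vectors (equal length, or either of length 1).
#' @return integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' levenshtein("gleevec", "glivec")  # 2
#' @export
levenshtein <- function(a, b) {
  .lev_dist_cpp(as.character(a), as.character(b))
}

#' Normalized edit distance
#'
#' Levenshtein distance divided by the length of the longer string, giving a
#' length-independent dissimilarity in \[0, 1\]: 0 iff the strings are equal,
#' 1 when no characters align. This is the quantity the partial matcher
#' thresholds (default threshold 0.2, i.e. up to 20% of the longer name may
#' differ).
#'
#' @param a,b character vectors (equal length, or either of length 1). A pair
#'   of two empty strings has no defined ratio and is an error.
#' @return numeric vector of distances in \[0, 1\].
#' @examples
#' normalized_edit_distance("gleevec", "glivec")   # 2/7
#' normalized_edit_distance("imatinab", "imatinib") # 1/8
#' @export
normalized_edit_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  na <- nchar(a, type = "bytes"); nb <- nchar(b, type = "bytes")
  denom <- pmax(na, nb)
  if (any(denom == 0L))
    stop("normalized edit distance is undefined for two empty strings")
  levenshtein(a, b) / denom
}
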