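# Independent edit-distance oracle: plain memoized recursion, no DP table
# reuse, no shared code with the package's C++ implementation.
lev_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  na <- length(av)
  nb <- length(bv)
  memo <- matrix(NA_integer_, na + 1L, nb + 1L)
  rec <- function(i, j) {
    m <- memo[i + 1L, j + 1L]
    if (!is.na(m)) return(m)
    r <- if (i == 0L) j
    else if (j == 0L) i
    else min(rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + (av[i] != bv[j]))
    memo[i + 1L, j + 1L] <<- r
    r
  }
  rec(na, nb)
}

# all strings of length 0..max_len over an alphabet
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

random_strings <- function(n, max_len, alphabet = letters) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample.int(max_len + 1L, 1L) - 1L, replace = TRUE),
          collapse = "")
  }, character(1))
}
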