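test_that("exact_match hits only on identical canonical text", {
  d <- toy_dict(c("imatinib", "D1"))
  expect_equal(exact_match(preprocess("imatinib"), d)$identifiers, "D1")
  expect_equal(exact_match(preprocess("imatinib"), d)$step, "exact")
  expect_equal(exact_match(preprocess("imatinab"), d)$step, "none")
  res <- exact_match(preprocess(""), d)
  expect_equal(res$step, "none")
  expect_length(res$identifiers, 0)
})

test_that("token_match is order-invariant equality of token multisets", {
  d <- toy_dict(c("lung cancer", "C1"))
  expect_equal(token_match(preprocess("cancer lung"), d)$identifiers, "C1")
  expect_equal(token_match(preprocess("lung cancers"), d)$step, "none")
  expect_equal(token_match(preprocess("lung cancer"), d)$identifiers, "C1")
})

test_that("ngram_match matches by containment in both directions", {
  d <- toy_dict(c("ductal carcinoma", "C2"))
  res <- ngram_match(preprocess("invasive ductal carcinoma of breast"), d, 2)
  expect_equal(res$identifiers, "C2")
  expect_equal(res$step, "ngram")

  d2 <- toy_dict(c("invasive ductal carcinoma", "C3"))
  expect_equal(ngram_match(preprocess("ductal carcinoma"), d2, 2)$identifiers, "C3")

  d3 <- toy_dict(c("lung cancer", "C1"))
  expect_equal(ngram_match(preprocess("imatinib"), d3, 2)$step, "none")
})

test_that("ngram_match unions hits from both rules", {
  d <- toy_dict(c("ductal carcinoma", "C2"), c("carcinoma ductal invasive", "C4"))
  res <- ngram_match(preprocess("invasive ductal carcinoma"), d, 2)
  # rule (a) query gram "ductal carcinoma" -> C2; rule (b) full query text is
  # order-invariantly... C4 has 3 tokens, its bigrams differ; only C2 expected
  expect_equal(res$identifiers, "C2")
  # sorted-gram lookup: query gram that is a permutation of an entry
  d2 <- toy_dict(c("cancer lung", "C5"))
  expect_equal(ngram_match(preprocess("advanced lung cancer stage"), d2, 2)$identifiers,
               "C5")
})

test_that("levenshtein agrees with the memoized recursive oracle", {
  # exhaustive on short strings (full sweep lives in the acceptance suite)
  strs <- all_strings(c("a", "b", "c"), 2)
  for (a in strs) {
    expect_identical(levenshtein(a, strs),
                     vapply(strs, lev_oracle, 0L, a = a, USE.NAMES = FALSE))
  }
  set.seed(11)
  for (i in 1:300) {
    a <- random_strings(1, 20)
    b <- random_strings(1, 20)
    expect_identical(levenshtein(a, b), lev_oracle(a, b))
  }
})

test_that("levenshtein is symmetric, zero iff equal, and triangular", {
  expect_identical(levenshtein("abc", "abc"), 0L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(levenshtein("gleevec", "glivec"), 2L)
  set.seed(5)
  for (i in 1:200) {
    s <- random_strings(3, 15, c("a", "b", "c", "d"))
    ab <- levenshtein(s[1], s[2]); bc <- levenshtein(s[2], s[3])
    ac <- levenshtein(s[1], s[3])
    expect_identical(ab, levenshtein(s[2], s[1]))
    expect_lte(ac, ab + bc)
    expect_identical(ab == 0L, s[1] == s[2])
  }
})

test_that("normalized_edit_distance matches the worked values", {
  expect_equal(normalized_edit_distance("imatinib", "imatinib"), 0)
  expect_equal(normalized_edit_distance("gleevec", "glivec"), 2 / 7)
  expect_equal(normalized_edit_distance("imatinab", "imatinib"), 0.125)
  expect_equal(normalized_edit_distance("a", "b"), 1)
  expect_equal(normalized_edit_distance("", "ab"), 1)
  expect_error(normalized_edit_distance("", ""), "undefined")
})

test_that("partial_match thresholds inclusively and returns the nearest set", {
  d <- toy_dict(c("imatinib", "D1"))
  res <- partial_match(preprocess("imatinab"), d, 0.2)
  expect_equal(res$identifiers, "D1")
  expect_equal(res$distance, 0.125)
  expect_equal(res$step, "partial")

  d2 <- toy_dict(c("glivec", "D1"))
  expect_equal(partial_match(preprocess("gleevec"), d2, 0.2)$step, "none")
  expect_equal(partial_match(preprocess("gleevec"), d2, 0.3)$identifiers, "D1")

  # only co-minimal entries are returned even when more are under threshold
  d3 <- toy_dict(c("abcde", "D1"), c("abcdx", "D2"), c("abcxx", "D3"))
  res <- partial_match(preprocess("abcde"), d3, 0.5)
  expect_equal(res$identifiers, "D1")
  expect_equal(res$distance, 0)
  res <- partial_match(preprocess("abcdz"), d3, 0.5)   # ties: D1 and D2 at 1/5
  expect_setequal(res$identifiers, c("D1", "D2"))
  expect_equal(res$distance, 0.2)

  expect_equal(partial_match(preprocess("??"), d3, 0.5)$step, "none")
})

test_that("partial matching is monotone in the threshold", {
  set.seed(21)
  pairs <- make_dictionary(25, seed = 3)
  d <- build_dictionary(pairs)
  queries <- c(pairs$name,
               vapply(pairs$name[1:10], function(n) perturb(n, "char_edit"), ""),
               random_strings(10, 12))
  grid <- c(0, 0.1, 0.2, 0.3, 0.5)
  matched <- lapply(grid, function(t) {
    which(vapply(queries, function(q)
      partial_match(preprocess(q), d, t)$step != "none", TRUE))
  })
  for (i in seq_along(grid)[-1])
    expect_true(all(matched[[i - 1]] %in% matched[[i]]))
})

test_that("exact matches are subsumed by token and partial matching", {
  set.seed(2)
  pairs <- make_dictionary(15, seed = 8)
  d <- build_dictionary(pairs)
  for (n in pairs$name) {
    q <- preprocess(n)
    expect_equal(exact_match(q, d)$step, "exact")
    expect_true(exact_match(q, d)$identifiers %in% token_match(q, d)$identifiers)
    pm <- partial_match(q, d, 0)
    expect_equal(pm$distance, 0)
    expect_identical(pm$identifiers, exact_match(q, d)$identifiers)
  }
})

test_that("oversized n degrades ngram_match to token-sequence equality", {
  d <- toy_dict(c("lung cancer", "C1"), c("melanoma", "C9"))
  n <- 10  # larger than query and all reference token counts
  expect_equal(ngram_match(preprocess("lung cancer"), d, n)$identifiers, "C1")
  expect_equal(ngram_match(preprocess("cancer lung"), d, n)$identifiers, "C1")
  expect_equal(ngram_match(preprocess("lung"), d, n)$step, "none")
  expect_equal(ngram_match(preprocess("lung cancer type"), d, n)$step, "none")
})
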