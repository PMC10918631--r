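test_that("make_dictionary is seed-deterministic and well separated", {
  p1 <- make_dictionary(30, seed = 7)
  p2 <- make_dictionary(30, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_dictionary(30, seed = 8)))

  expect_false(anyDuplicated(p1$name) > 0)
  keys <- vapply(strsplit(p1$name, " "), function(t)
    paste(sort(t), collapse = " "), "")
  expect_false(anyDuplicated(keys) > 0)

  # pairwise normalized distance exceeds twice the default threshold
  for (i in seq_len(nrow(p1) - 1)) {
    nd <- normalized_edit_distance(p1$name[i], p1$name[(i + 1):nrow(p1)])
    expect_true(all(nd > 0.4))
  }
})

test_that("make_dictionary errors when separation cannot be satisfied", {
  expect_error(make_dictionary(500, vocab_size = 8, seed = 1),
               "fewer entries or a larger vocabulary")
})

test_that("perturbations have the documented recovery structure", {
  set.seed(99)
  expect_identical(perturb("lung cancer", "identity"), "lung cancer")

  for (i in 1:50) {
    out <- perturb("lung cancer nsclc", "case_punct", seed = i)
    expect_identical(canonical_text(out), "lung cancer nsclc")
  }

  for (i in 1:25) {
    out <- perturb("alpha beta gamma", "token_shuffle", seed = i)
    expect_false(identical(out, "alpha beta gamma"))
    expect_identical(paste(sort(strsplit(out, " ")[[1]]), collapse = " "),
                     "alpha beta gamma")
  }
  one <- perturb("imatinib", "token_shuffle", seed = 1)
  expect_identical(as.character(one), "imatinib")
  expect_true(attr(one, "fallback"))

  for (i in 1:25) {
    out <- perturb("ductal carcinoma", "embed_in_phrase", seed = i)
    toks <- strsplit(canonical_text(out), " ")[[1]]
    expect_true("ductal carcinoma" %in% word_ngrams(toks, 2))
    expect_gt(length(toks), 2)
  }

  for (i in 1:50) {
    out <- perturb("imatinib", "char_edit", edit_count = 1, seed = i)
    nd <- normalized_edit_distance(canonical_text(out), "imatinib")
    expect_gt(nd, 0)
    expect_lte(nd, 1 / 8)
  }
  # multi-edit bound: at most edit_count edits worth of distance
  for (i in 1:25) {
    out <- perturb("pembrolizumab", "char_edit", edit_count = 2, seed = i)
    expect_lte(levenshtein(canonical_text(out), "pembrolizumab"), 2L)
  }

  expect_error(perturb("", "identity"))
})

test_that("make_gold honors the mix, the seed, and its construction bounds", {
  pairs <- make_dictionary(40, seed = 23)
  g1 <- make_gold(pairs, n_records = 60, seed = 23)
  g2 <- make_gold(pairs, n_records = 60, seed = 23)
  expect_identical(g1, g2)

  expect_equal(nrow(g1$records), 60)
  expect_equal(unname(table(g1$kind)[c("identity", "unmatchable")]),
               c(12L, 6L), ignore_attr = TRUE)

  pos <- g1$records$expected != NO_MATCH_MARKER
  expect_true(all(g1$records$expected[pos] %in% pairs$id))
  expect_true(all(g1$records$expected[g1$kind == "unmatchable"] == NO_MATCH_MARKER))

  # char_edit queries stay within the threshold of their source entry
  canon <- canonical_text(pairs$name)
  for (r in which(g1$kind == "char_edit")) {
    src <- canon[match(g1$records$expected[r], pairs$id)]
    expect_lte(normalized_edit_distance(canonical_text(g1$records$query[r]), src),
               0.2)
  }
  # unmatchable queries are far from everything
  for (r in which(g1$kind == "unmatchable")) {
    nd <- normalized_edit_distance(canonical_text(g1$records$query[r]), canon)
    expect_gt(min(nd), 0.4)
  }

  expect_error(make_gold(pairs, mix = c(identity = 0.5), n_records = 10),
               "sum")
})

test_that("expected_step matches the kind labels", {
  pairs <- make_dictionary(30, seed = 29)
  g <- make_gold(pairs, n_records = 50, seed = 29)
  lookup <- c(identity = "exact", case_punct = "exact", token_shuffle = "token",
              embed_in_phrase = "ngram", char_edit = "partial",
              unmatchable = "none")
  expect_identical(g$expected_step, unname(lookup[g$kind]))
})

test_that("cascade recovers every record at its expected step", {
  pairs <- make_dictionary(40, seed = 37)
  g <- make_gold(pairs, n_records = 80, seed = 37)
  d <- build_dictionary(pairs)
  traces <- normalize_batch(g$records$query, d)
  steps <- vapply(traces, function(tr) tr$result$step, "")
  expect_identical(steps, g$expected_step)

  m <- score(g$records, batch_identifiers(traces))
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  # disabling partial drops exactly the char_edit records
  cfg <- match_config(enable_partial = FALSE)
  steps2 <- vapply(normalize_batch(g$records$query, d, cfg),
                   function(tr) tr$result$step, "")
  expect_identical(which(steps2 == "none" & steps != "none"),
                   which(g$kind == "char_edit"))
})

test_that("fixtures round-trip through the loaders byte-identically", {
  pairs <- make_dictionary(20, seed = 41)
  g <- make_gold(pairs, n_records = 30, seed = 41)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_fixtures(g, dir1)
  p2 <- write_fixtures(g, dir2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))

  reload <- parse_synonym_table(p1[["dictionary"]], id_col = "id",
                                name_col = "name")
  expect_setequal(paste(reload$id, reload$name),
                  paste(pairs$id, pairs$name))
  gold <- read_gold_standard(p1[["gold"]])
  expect_identical(gold$query, trimws(g$records$query))  # loader trims ws
  expect_identical(gold$expected, g$records$expected)

  manifest <- jsonlite::read_json(p1[["manifest"]])
  expect_equal(manifest$seed, 41)
  expect_equal(manifest$n_records, 30)
  expect_equal(manifest$n_dictionary, 20)
})
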