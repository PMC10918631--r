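#' Score predictions against a gold standard
#'
#' Strict NER-style counting, per aligned record:
#' * positive record (expected identifier): prediction contains the expected
#'   identifier -> TP; prediction non-empty but wrong -> FP *and* FN (a
#'   wrong identifier is penalized on both axes); prediction empty -> FN.
#' * negative record (expected is [NO_MATCH_MARKER]): empty prediction ->
#'   TN; non-empty -> FP.
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R); all defined
#' as 0 when their denominator is 0. A prediction set containing the
#' expected identifier among others still counts as TP — the reported
#' `mean_prediction_size` tracks how many identifiers a curator would have
#' to inspect.
#'
#' @param records data.frame with columns `query`, `expected` (see
#'   [read_gold_standard()]).
#' @param predictions list of character vectors of predicted identifiers,
#'   aligned with `records` by position (empty vector = no match).
#' @return an object of class `eval_metrics`: list with `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`, `n`, `mean_prediction_size`.
#' @examples
#' recs <- data.frame(query = c("a", "b", "c"), expected = c("A", "B", "NONE"))
#' score(recs, list("A", "C", character(0)))
#' @export
score <- function(records, predictions) {
  stopifnot(is.data.frame(records), all(c("query", "expected") %in% names(records)))
  if (length(predictions) != nrow(records))
    stop(sprintf("length mismatch: %d records vs %d predictions",
                 nrow(records), length(predictions)))
  expected <- as.character(records$expected)
  negative <- expected == NO_MATCH_MARKER
  npred <- lengths(predictions)
  hit <- mapply(function(e, p) e %in% p, expected, predictions,
                USE.NAMES = FALSE)

  tp <- sum(!negative & hit)
  fp <- sum(!negative & !hit & npred > 0L) + sum(negative & npred > 0L)
  fn <- sum(!negative & !hit)          # wrong-id and empty both count as fn
  tn <- sum(negative & npred == 0L)

  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 n = nrow(records),
                 mean_prediction_size = if (nrow(records)) mean(npred) else 0),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n=%d tp=%d fp=%d fn=%d tn=%d | P=%.4f R=%.4f F1=%.4f\n",
              x$n, x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Bootstrap evaluation metrics
#'
#' Resamples aligned (record, prediction) pairs with replacement to the
#' original size, scores each replicate, and summarizes precision, recall
#' and F1 by their mean and population standard deviation (the error bars
#' one would draw on a benchmark plot). Fully determined by `seed`; the
#' caller's RNG state is left untouched.
#'
#' @inheritParams score
#' @param replicates number of bootstrap replicates, default 100.
#' @param seed integer seed.
#' @return an object of class `bootstrap_summary`: list with `replicates`,
#'   `seed`, and `mean` / `sd` named vectors over precision, recall, f1.
#' @export
bootstrap_metrics <- function(records, predictions, replicates = 100L, seed = 1L) {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  if (nrow(records) == 0L) stop("cannot bootstrap an empty record list")
  if (length(predictions) != nrow(records))
    stop("length mismatch between records and predictions")

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n <- nrow(records)
  mat <- vapply(seq_len(replicates), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- score(records[idx, , drop = FALSE], predictions[idx])
    c(precision = m$precision, recall = m$recall, f1 = m$f1)
  }, numeric(3))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(replicates = replicates, seed = as.integer(seed),
                 mean = rowMeans(mat),
                 sd = apply(mat, 1L, pop_sd)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %d replicates (seed %d)\n", x$replicates, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Time a normalization batch
#'
#' Runs [normalize_batch()] and summarizes per-query wall time and how often
#' each cascade step was attempted. Because later steps only run on earlier
#' failure, attempt counts are non-increasing along the cascade order; a
#' batch of clean dictionary names never touches the fuzzy steps.
#'
#' @inheritParams normalize_batch
#' @return list with `n`, `mean_s`, `median_s`, `total_s`, `attempts`
#'   (named counts for exact/token/ngram/partial) and `traces`.
#' @export
time_batch <- function(raws, dict, config = match_config()) {
  traces <- normalize_batch(raws, dict, config)
  el <- vapply(traces, `[[`, numeric(1), "elapsed")
  steps <- c("exact", "token", "ngram", "partial")
  attempts <- vapply(steps, function(s)
    sum(vapply(traces, function(tr) s %in% tr$steps_attempted, TRUE)), 0L)
  list(n = length(traces),
       mean_s = if (length(el)) mean(el) else 0,
       median_s = if (length(el)) stats::median(el) else 0,
       total_s = sum(el),
       attempts = attempts,
       traces = traces)
}

#' Write evaluation metrics to TSV and JSON
#'
#' @param metrics an `eval_metrics` object.
#' @param path output path without extension, or with `.tsv`/`.json`
#'   (both files are written with the respective extensions).
#' @param bootstrap optional `bootstrap_summary` to embed in the JSON.
#' @return invisibly, the two paths written.
#' @export
write_metrics <- function(metrics, path, bootstrap = NULL) {
  base <- sub("\\.(tsv|json)$", "", path)
  tsv <- paste0(base, ".tsv"); js <- paste0(base, ".json")
  df <- data.frame(metric = c("tp", "fp", "fn", "tn", "precision", "recall",
                              "f1", "n", "mean_prediction_size"),
                   value = c(metrics$tp, metrics$fp, metrics$fn, metrics$tn,
                             metrics$precision, metrics$recall, metrics$f1,
                             metrics$n, metrics$mean_prediction_size))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- unclass(metrics)
  if (!is.null(bootstrap))
    payload$bootstrap <- list(replicates = bootstrap$replicates,
                              seed = bootstrap$seed,
                              mean = as.list(bootstrap$mean),
                              sd = as.list(bootstrap$sd))
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
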