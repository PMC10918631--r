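#' Parse an OBO ontology file
#'
#' Minimal reader for OBO 1.2/1.4 flat files as distributed by the Disease
#' Ontology: one term per `[Term]` stanza, capturing `id`, `name`, all
#' `synonym` lines (the quoted surface form, with its EXACT/RELATED/NARROW/
#' BROAD scope kept as metadata), `is_a` parents and the `is_obsolete` flag.
#' Other tags (xrefs, defs, relationship edges such as part_of) are ignored:
#' only `is_a` edges define the subtree used for dictionary restriction.
#'
#' @param file path to an OBO file (UTF-8).
#' @return a list of terms; each term is a list with `id`, `name`,
#'   `synonyms` (data.frame with columns `text`, `scope`), `parents`
#'   (character vector of is_a accessions) and `obsolete` (logical).
#' @export
parse_obo <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0L) return(list())
  # stanza i spans starts[i]+1 .. next header-1 (any [Typedef] etc. ends it)
  headers <- which(grepl("^\\[", trimws(lines)))
  terms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    nexth <- headers[headers > s]
    e <- if (length(nexth)) min(nexth) - 1L else length(lines)
    body <- lines[(s + 1L):e]
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]*:", "", body))

    id <- val[tag == "id"]
    if (length(id) == 0L || !nzchar(id[1]))
      stop(sprintf("malformed [Term] stanza at line %d: missing id", s))
    nm <- val[tag == "name"]
    syn_lines <- val[tag == "synonym"]
    syn_text <- character(0); syn_scope <- character(0)
    for (sl in syn_lines) {
      m <- regmatches(sl, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]*)', sl))[[1]]
      if (length(m) >= 2L && nzchar(m[2])) {
        syn_text <- c(syn_text, gsub('\\\\(.)', "\\1", m[2]))
        syn_scope <- c(syn_scope, if (length(m) >= 3L && nzchar(m[3])) m[3] else "RELATED")
      }
    }
    parents <- val[tag == "is_a"]
    parents <- trimws(sub("!.*$", "", parents))
    parents <- parents[nzchar(parents)]
    obsolete <- any(tag == "is_obsolete" & tolower(val) == "true")
    terms[[i]] <- list(id = id[1],
                       name = if (length(nm)) nm[1] else NA_character_,
                       synonyms = data.frame(text = syn_text, scope = syn_scope,
                                             stringsAsFactors = FALSE),
                       parents = parents,
                       obsolete = obsolete)
  }
  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate term ids in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  terms
}

#' Restrict an ontology to the subtree under a root term
#'
#' Returns all terms reachable from `root` by following `is_a` edges in
#' reverse (i.e. the root and all its descendants), excluding obsolete
#' terms. This is how a disease dictionary is restricted to the
#' cancer-related subtree under DOID:162 ("cancer").
#'
#' @param terms list of terms from [parse_obo()].
#' @param root accession string of the subtree root; must be present.
#' @return the filtered term list (original order preserved).
#' @export
subtree <- function(terms, root) {
  ids <- vapply(terms, `[[`, "", "id")
  if (!root %in% ids) stop(sprintf("root term '%s' not found in ontology", root))
  # children[parent] -> child ids
  children <- new.env(parent = emptyenv(), hash = TRUE)
  for (t in terms) {
    for (p in t$parents)
      children[[p]] <- c(if (!is.null(children[[p]])) children[[p]], t$id)
  }
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  queue <- root
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (isTRUE(seen[[cur]])) next
    seen[[cur]] <- TRUE
    kids <- children[[cur]]
    if (!is.null(kids)) queue <- c(queue, kids)
  }
  keep <- vapply(terms, function(t) isTRUE(seen[[t$id]]) && !t$obsolete, TRUE)
  terms[keep]
}

#' Flatten ontology terms to (name, identifier) pairs
#'
#' Emits one pair for the primary name and one per synonym of every
#' non-obsolete term. All synonym scopes are included by default; restrict
#' to `scopes = "EXACT"` for conservative dictionaries. Duplicate surface
#' forms are deduplicated downstream by [build_dictionary()] via canonical
#' collision merging.
#'
#' @param terms list of terms from [parse_obo()].
#' @param scopes synonym scopes to include.
#' @return data.frame with columns `name`, `id`.
#' @export
ontology_to_pairs <- function(terms,
                              scopes = c("EXACT", "RELATED", "NARROW", "BROAD")) {
  out_name <- character(0); out_id <- character(0)
  for (t in terms) {
    if (t$obsolete) next
    if (!is.na(t$name) && nzchar(t$name)) {
      out_name <- c(out_name, t$name); out_id <- c(out_id, t$id)
    }
    if (nrow(t$synonyms)) {
      sel <- t$synonyms$scope %in% scopes
      out_name <- c(out_name, t$synonyms$text[sel])
      out_id <- c(out_id, rep(t$id, sum(sel)))
    }
  }
  data.frame(name = out_name, id = out_id, stringsAsFactors = FALSE)
}

#' Parse a delimited synonym table
#'
#' Reads (identifier, synonym) pairs from a delimited text file in the style
#' of a ChEMBL or DrugBank synonym export: one row per surface form, with
#' configurable delimiter and id/name columns addressed by name or 1-based
#' index. Rows whose name or identifier is empty are skipped; the skip count
#' is attached as attribute `n_skipped` (with a warning when non-zero).
#'
#' @param file path to the delimited file.
#' @param id_col,name_col column of identifiers / surface names, by name
#'   (requires `header = TRUE`) or by 1-based index. Must differ.
#' @param delimiter field separator, default tab.
#' @param header whether the first row is a header.
#' @return data.frame with columns `name`, `id` and attribute `n_skipped`.
#' @export
parse_synonym_table <- function(file, id_col = 1L, name_col = 2L,
                                delimiter = "\t", header = TRUE) {
  tab <- data.table::fread(file, sep = delimiter, header = header,
                           colClasses = "character", data.table = FALSE,
                           encoding = "UTF-8")
  resolve <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(tab))
        stop(sprintf("%s column '%s' not found (columns: %s)", what, col,
                     paste(names(tab), collapse = ", ")))
      return(match(col, names(tab)))
    }
    col <- as.integer(col)
    if (is.na(col) || col < 1L || col > ncol(tab))
      stop(sprintf("%s column index %s out of range (file has %d columns)",
                   what, col, ncol(tab)))
    col
  }
  i_id <- resolve(id_col, "identifier")
  i_name <- resolve(name_col, "name")
  if (i_id == i_name) stop("identifier and name columns must differ")
  ids <- trimws(tab[[i_id]]); nms <- trimws(tab[[i_name]])
  keep <- !is.na(ids) & nzchar(ids) & !is.na(nms) & nzchar(nms)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d row(s) with empty name or identifier", n_skipped))
  out <- data.frame(name = nms[keep], id = ids[keep], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a gold-standard file
#'
#' Two-column delimited file: query name, expected identifier. The literal
#' token `"NONE"` in the identifier column marks a query with no valid
#' mapping (see [NO_MATCH_MARKER]). Rows with an empty query or missing
#' identifier are malformed; all offending line numbers are reported in one
#' error.
#'
#' @param file path to the gold-standard file.
#' @param delimiter field separator, default tab.
#' @param header whether the first row is a header.
#' @return data.frame with columns `query`, `expected`.
#' @export
read_gold_standard <- function(file, delimiter = "\t", header = TRUE) {
  tab <- data.table::fread(file, sep = delimiter, header = header,
                           colClasses = "character", data.table = FALSE,
                           encoding = "UTF-8")
  if (ncol(tab) < 2L) stop("gold-standard file must have two columns (query, expected)")
  q <- trimws(tab[[1L]]); e <- trimws(tab[[2L]])
  bad <- which(is.na(q) | !nzchar(q) | is.na(e) | !nzchar(e))
  if (length(bad)) {
    off <- bad + if (header) 1L else 0L
    stop("malformed gold-standard row(s) at line(s): ", paste(off, collapse = ", "))
  }
  data.frame(query = q, expected = e, stringsAsFactors = FALSE)
}
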