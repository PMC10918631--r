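extdata <- function(f) system.file("extdata", f, package = "entnorm", mustWork = TRUE)

toy_dict <- function(...) {
  pairs <- list(...)
  build_dictionary(data.frame(name = vapply(pairs, `[[`, "", 1L),
                              id = vapply(pairs, `[[`, "", 2L),
                              stringsAsFactors = FALSE))
}

# minimal in-code ontology term constructor (same shape as parse_obo output)
term <- function(id, name = id, parents = character(0), obsolete = FALSE,
                 synonyms = character(0), scopes = rep("EXACT", length(synonyms))) {
  list(id = id, name = name,
       synonyms = data.frame(text = synonyms, scope = scopes,
                             stringsAsFactors = FALSE),
       parents = parents, obsolete = obsolete)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
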