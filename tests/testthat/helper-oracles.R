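# Independent brute-force oracles and tiny in-code fixtures shared by the
# tests.  The oracles avoid the implementation's regex path: occurrence
# checks use fixed-string search plus manual boundary inspection.

# all whole-term occurrences of `term` in `text` (0-based half-open starts),
# fixed-string scan with manual boundary checks
oracle_occurrences <- function(text, term) {
  low <- tolower(text)
  m <- gregexpr(term, low, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  len <- nchar(term)
  ok <- vapply(m, function(s) {
    before <- s == 1L || !grepl("[a-z0-9]", substr(low, s - 1L, s - 1L))
    e <- s + len - 1L
    after <- e == nchar(low) || !grepl("[a-z0-9]", substr(low, e + 1L, e + 1L))
    before && after
  }, logical(1))
  as.integer(m[ok]) - 1L
}

oracle_unit_has_term <- function(text, term) length(oracle_occurrences(text, term)) > 0L

# unit ids of sentences containing every term of `terms` (linear scan)
oracle_units_with_terms <- function(corpus, terms) {
  hits <- character(0)
  for (ab in corpus) {
    for (s in ab$sentences) {
      if (all(vapply(terms, oracle_unit_has_term, logical(1), text = s$text))) {
        hits <- c(hits, s$unit_id)
      }
    }
  }
  sort(hits)
}

# pmids of abstracts containing each term somewhere (possibly different
# sentences)
oracle_pmids_with_terms <- function(corpus, terms) {
  hits <- character(0)
  for (ab in corpus) {
    texts <- vapply(ab$sentences, function(s) s$text, character(1))
    per_term <- vapply(terms, function(t) {
      any(vapply(texts, oracle_unit_has_term, logical(1), term = t))
    }, logical(1))
    if (all(per_term)) hits <- c(hits, ab$pmid)
  }
  sort(hits)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_drug_lexicon <- function() {
  lexicon(c("irinotecan", "ondansetron"), c("irinotecan", "ondansetron"),
          kind = "drug")
}

tiny_se_lexicon <- function() {
  lexicon(c("diarrhea", "nausea", "pain"), c("diarrhea", "nausea", "pain"),
          kind = "side_effect")
}

pair_keys_of <- function(df) paste(df$drug_id, df$se_id, sep = "\t")

extraction_precision_recall <- function(result, truth, which = "all") {
  found <- if (which == "all") result$all_candidates else result$novel
  fk <- pair_keys_of(found)
  tk <- pair_keys_of(truth$pairs)
  list(precision = if (length(fk)) mean(fk %in% tk) else NA_real_,
       recall = mean(tk %in% fk))
}
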