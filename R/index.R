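# Inverted index over the sentence-segmented corpus: the in-memory stand-in
# for a local search engine keyed on lexicon terms.

#' Build an inverted index over a corpus
#'
#' Scans every sentence once with [find_term_matches()] for both lexicons and
#' records, per normalized lexicon term, the set of sentence unit ids (and
#' derived abstract pmids) containing it as a whole-term match.  Terms absent
#' from both lexicons are not indexed.  Raw (pre-NP-filter) matches are
#' cached per sentence so downstream classification and enumeration do not
#' rescan text.
#'
#' @param abstracts List of [abstract_record()] objects; pmids must be unique.
#' @param drugs Drug [lexicon()].
#' @param ses Side-effect [lexicon()].
#' @return Object of class `kdse_index`.
#' @export
build_index <- function(abstracts, drugs, ses) {
  stopifnot(inherits(drugs, "kdse_lexicon"), inherits(ses, "kdse_lexicon"))
  pmids <- vapply(abstracts, function(a) a$pmid, character(1))
  if (anyDuplicated(pmids)) {
    stop(sprintf("duplicate pmid in corpus: %s",
                 pmids[duplicated(pmids)][1L]), call. = FALSE)
  }
  postings <- new.env(parent = emptyenv())   # term -> character vec of unit_ids
  units <- new.env(parent = emptyenv())      # unit_id -> kdse_sentence
  unit_matches <- new.env(parent = emptyenv())  # unit_id -> list(drug=, se=)
  abs_store <- new.env(parent = emptyenv())  # pmid -> kdse_abstract

  for (ab in abstracts) {
    assign(ab$pmid, ab, envir = abs_store)
    for (s in ab$sentences) {
      assign(s$unit_id, s, envir = units)
      md <- find_term_matches(s, drugs)
      ms <- find_term_matches(s, ses)
      assign(s$unit_id, list(drug = md, se = ms), envir = unit_matches)
      for (term in unique(normalize_term(c(md$surface, ms$surface)))) {
        cur <- if (exists(term, envir = postings, inherits = FALSE)) {
          get(term, envir = postings)
        } else character(0)
        assign(term, c(cur, s$unit_id), envir = postings)
      }
    }
  }
  structure(
    list(postings = postings, units = units, unit_matches = unit_matches,
         abstracts = abs_store, drugs = drugs, ses = ses),
    class = "kdse_index"
  )
}

#' @export
print.kdse_index <- function(x, ...) {
  cat(sprintf("<kdse_index> %d abstracts, %d sentences, %d indexed terms\n",
              length(ls(x$abstracts)), length(ls(x$units)),
              length(ls(x$postings))))
  invisible(x)
}

#' All sentence unit ids of an index
#' @param index A [build_index()] object.
#' @return Character vector of `"pmid:k"` unit ids.
#' @export
index_unit_ids <- function(index) ls(index$units)

#' All abstract pmids of an index
#' @param index A [build_index()] object.
#' @return Character vector of pmids.
#' @export
index_pmids <- function(index) ls(index$abstracts)

#' @keywords internal
unit_pmid <- function(unit_ids) sub(":[0-9]+$", "", unit_ids)

#' @keywords internal
postings_for_term <- function(index, term) {
  if (exists(term, envir = index$postings, inherits = FALSE)) {
    get(term, envir = index$postings)
  } else character(0)
}

# Union of sentence postings over all surface terms of a canonical id.
#' @keywords internal
postings_for_id <- function(index, id, lex) {
  terms <- lexicon_terms(lex, id)
  if (length(terms) == 0L) stop(sprintf("unknown id '%s'", id), call. = FALSE)
  unique(unlist(lapply(terms, postings_for_term, index = index)))
}

#' Retrieve units containing a drug-SE pair
#'
#' Sentence level returns sentences whose text contains both terms; abstract
#' level (with the default `"anywhere"` scope) returns pmids whose abstract
#' contains the drug in some sentence and the SE in some, possibly different,
#' sentence — the looser channel that makes abstract-level extraction a
#' noisier superset of sentence-level extraction.
#'
#' @param index A [build_index()] object.
#' @param drug_id,se_id Canonical ids; unknown ids are an error.
#' @param level `"sentence"` or `"abstract"`.
#' @param abstract_scope `"anywhere"` (default) or `"same_sentence"`, which
#'   requires the pair within one sentence and reports its pmid.
#' @return Character vector of unit ids (sentence level) or pmids.
#' @export
query_pair <- function(index, drug_id, se_id,
                       level = c("sentence", "abstract"),
                       abstract_scope = c("anywhere", "same_sentence")) {
  stopifnot(inherits(index, "kdse_index"))
  level <- match.arg(level)
  abstract_scope <- match.arg(abstract_scope)
  d_units <- postings_for_id(index, drug_id, index$drugs)
  s_units <- postings_for_id(index, se_id, index$ses)
  if (level == "sentence") {
    sort(intersect(d_units, s_units))
  } else if (abstract_scope == "same_sentence") {
    sort(unique(unit_pmid(intersect(d_units, s_units))))
  } else {
    sort(intersect(unique(unit_pmid(d_units)), unique(unit_pmid(s_units))))
  }
}

# Cached raw matches for one sentence unit.
#' @keywords internal
unit_raw_matches <- function(index, unit_id) {
  get(unit_id, envir = index$unit_matches)
}

# Drug/SE canonical ids surviving the NP filter in one sentence unit.
#' @keywords internal
unit_filtered_ids <- function(index, unit_id, np = np_config()) {
  m <- unit_raw_matches(index, unit_id)
  s <- get(unit_id, envir = index$units)
  list(
    drug = unique(np_filter(m$drug, s, np)$id),
    se = unique(np_filter(m$se, s, np)$id)
  )
}

# Per-abstract union of NP-filtered ids over its sentences.
#' @keywords internal
abstract_filtered_ids <- function(index, pmid, np = np_config()) {
  ab <- get(pmid, envir = index$abstracts)
  ids <- lapply(ab$sentences, function(s) unit_filtered_ids(index, s$unit_id, np))
  list(
    drug = unique(unlist(lapply(ids, `[[`, "drug"))),
    se = unique(unlist(lapply(ids, `[[`, "se")))
  )
}
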