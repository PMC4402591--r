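# Knowledge-driven extraction: prior drug-SE pairs gate which units count as
# SE-related, then candidate pairs are enumerated from those units only.

#' Classify units as SE-related via prior knowledge
#'
#' A unit (sentence or abstract) is SE-related iff it contains at least one
#' known drug-SE pair from the prior knowledge base; with `np$gate` the
#' pair's matches must also survive the NP restriction.  Units not retrieved
#' for any prior pair are SE-unrelated.
#'
#' @param index A [build_index()] object.
#' @param prior A non-empty [known_pairs()] knowledge base.
#' @param level `"sentence"` or `"abstract"`.
#' @param np An [np_config()].
#' @param abstract_scope Passed to [query_pair()].
#' @return Sorted character vector of SE-related unit ids (or pmids).
#' @export
classify_units <- function(index, prior, level = c("sentence", "abstract"),
                           np = np_config(),
                           abstract_scope = c("anywhere", "same_sentence")) {
  stopifnot(inherits(index, "kdse_index"), inherits(prior, "kdse_kb"))
  level <- match.arg(level)
  abstract_scope <- match.arg(abstract_scope)
  if (kb_size(prior) == 0L) stop("empty prior knowledge base", call. = FALSE)
  apply_np <- np$gate && np$mode != "off"
  hits <- character(0)
  for (i in seq_len(kb_size(prior))) {
    d <- prior$pairs$drug_id[i]
    s <- prior$pairs$se_id[i]
    cand <- query_pair(index, d, s, level = level,
                       abstract_scope = abstract_scope)
    cand <- setdiff(cand, hits)  # already confirmed units need no recheck
    if (length(cand) == 0L) next
    if (apply_np) {
      ok <- vapply(cand, function(u) {
        ids <- if (level == "sentence") {
          unit_filtered_ids(index, u, np)
        } else if (abstract_scope == "same_sentence") {
          ab <- get(u, envir = index$abstracts)
          per <- lapply(ab$sentences,
                        function(x) unit_filtered_ids(index, x$unit_id, np))
          hit <- vapply(per, function(p) d %in% p$drug && s %in% p$se, logical(1))
          if (any(hit)) list(drug = d, se = s) else list(drug = character(0),
                                                        se = character(0))
        } else {
          abstract_filtered_ids(index, u, np)
        }
        d %in% ids$drug && s %in% ids$se
      }, logical(1))
      cand <- cand[ok]
    }
    hits <- c(hits, cand)
  }
  sort(unique(hits))
}

#' Enumerate candidate pairs within one SE-related unit
#'
#' The cross product of the distinct drug ids and distinct SE ids whose
#' matches survive the NP filter in the unit.  At sentence level the unit is
#' one sentence; at abstract level matches anywhere in the abstract
#' contribute.  Pairs are deduplicated within the unit.
#'
#' @param index A [build_index()] object.
#' @param unit_id Sentence unit id (`"pmid:k"`) or pmid, per `level`.
#' @inheritParams classify_units
#' @return data.frame with columns `drug_id`, `se_id`.
#' @export
enumerate_candidates <- function(index, unit_id,
                                 level = c("sentence", "abstract"),
                                 np = np_config()) {
  level <- match.arg(level)
  ids <- if (level == "sentence") {
    unit_filtered_ids(index, unit_id, np)
  } else {
    abstract_filtered_ids(index, unit_id, np)
  }
  if (length(ids$drug) == 0L || length(ids$se) == 0L) {
    return(data.frame(drug_id = character(0), se_id = character(0),
                      stringsAsFactors = FALSE))
  }
  expand.grid(drug_id = sort(ids$drug), se_id = sort(ids$se),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' @keywords internal
aggregate_candidates <- function(per_unit_pairs, unit_ids, prior, level) {
  support <- new.env(parent = emptyenv())
  for (i in seq_along(unit_ids)) {
    p <- per_unit_pairs[[i]]
    if (nrow(p) == 0L) next
    for (key in pair_key(p$drug_id, p$se_id)) {
      cur <- if (exists(key, envir = support, inherits = FALSE)) {
        get(key, envir = support)
      } else character(0)
      assign(key, c(cur, unit_ids[i]), envir = support)
    }
  }
  keys <- ls(support)
  if (length(keys) == 0L) {
    all_candidates <- data.frame(drug_id = character(0), se_id = character(0),
                                 count = integer(0), units = character(0),
                                 stringsAsFactors = FALSE)
  } else {
    ids <- split_pair_key(keys)
    units <- vapply(keys, function(k) {
      paste(sort(unique(get(k, envir = support))), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    count <- vapply(keys, function(k) {
      length(unique(get(k, envir = support)))
    }, integer(1), USE.NAMES = FALSE)
    all_candidates <- data.frame(drug_id = ids$drug_id, se_id = ids$se_id,
                                 count = count, units = units,
                                 stringsAsFactors = FALSE)
    ord <- order(-all_candidates$count, all_candidates$drug_id,
                 all_candidates$se_id)
    all_candidates <- all_candidates[ord, , drop = FALSE]
    rownames(all_candidates) <- NULL
  }
  prior_keys <- if (is.null(prior)) character(0) else kb_keys(prior)
  is_novel <- !(pair_key(all_candidates$drug_id, all_candidates$se_id)
                %in% prior_keys)
  novel <- all_candidates[is_novel, , drop = FALSE]
  rownames(novel) <- NULL
  structure(
    list(level = level, all_candidates = all_candidates, novel = novel,
         classified_units = unit_ids),
    class = "kdse_extraction"
  )
}

#' Knowledge-driven drug-SE pair extraction
#'
#' Classifies units as SE-related with [classify_units()], enumerates
#' candidate pairs per SE-related unit, aggregates per-pair support (one unit
#' contributes at most 1 to a pair's count, however often it mentions it),
#' and separates the novel pairs — those not already in the prior knowledge
#' base.  With `gate = FALSE` the gating step is skipped and candidates come
#' from every unit (plain co-occurrence extraction, the ungated baseline).
#'
#' @inheritParams classify_units
#' @param prior [known_pairs()] prior knowledge; required when `gate = TRUE`.
#'   With `gate = FALSE` it may be `NULL`, in which case `novel` equals
#'   `all_candidates`.
#' @param gate Apply prior-knowledge gating (default `TRUE`).
#' @return Object of class `kdse_extraction`: `level`, `all_candidates` and
#'   `novel` data.frames (`drug_id`, `se_id`, `count`, `units`), and
#'   `classified_units`.
#' @export
extract_pairs <- function(index, prior = NULL,
                          level = c("sentence", "abstract"),
                          np = np_config(), gate = TRUE,
                          abstract_scope = c("anywhere", "same_sentence")) {
  level <- match.arg(level)
  abstract_scope <- match.arg(abstract_scope)
  if (gate) {
    units <- classify_units(index, prior, level = level, np = np,
                            abstract_scope = abstract_scope)
  } else {
    units <- if (level == "sentence") index_unit_ids(index) else index_pmids(index)
  }
  per_unit <- lapply(units, enumerate_candidates, index = index, level = level,
                     np = np)
  aggregate_candidates(per_unit, units, prior, level)
}

#' @export
print.kdse_extraction <- function(x, ...) {
  cat(sprintf("<kdse_extraction> level=%s: %d SE-related units, %d candidate pairs, %d novel\n",
              x$level, length(x$classified_units), nrow(x$all_candidates),
              nrow(x$novel)))
  invisible(x)
}

#' Write extracted pairs to TSV
#'
#' Rows are `drug_id<TAB>se_id<TAB>count<TAB>comma-joined unit ids`, sorted
#' by count descending then ids.
#'
#' @param result A `kdse_extraction` object.
#' @param path Output path.
#' @param which `"novel"` (default) or `"all"`.
#' @export
write_extraction <- function(result, path, which = c("novel", "all")) {
  stopifnot(inherits(result, "kdse_extraction"))
  which <- match.arg(which)
  df <- if (which == "novel") result$novel else result$all_candidates
  writeLines(paste(df$drug_id, df$se_id, df$count, df$units, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}
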