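# Drug and side-effect lexicons, and the known drug-SE pair knowledge base.

#' Normalize a lexicon or text term
#'
#' Lowercases, strips leading/trailing whitespace and collapses internal
#' whitespace runs to single spaces.  Punctuation is preserved, so compound
#' side-effect terms such as `"thrombosis/embolism"` survive intact.  The
#' operation is idempotent.
#'
#' @param raw Character vector of raw terms.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term(" Irinotecan ")
#' normalize_term("Thrombosis/Embolism")
#' @export
normalize_term <- function(raw) {
  gsub("[ \t\r\n]+", " ", trimws(tolower(raw)))
}

#' Construct a lexicon
#'
#' A lexicon maps normalized surface terms to canonical identifiers.  One
#' canonical id may have several surface terms; within a lexicon a surface
#' term resolves to exactly one id.
#'
#' @param terms Character vector of surface terms (normalized internally).
#' @param ids Character vector of canonical ids, parallel to `terms`.
#' @param kind `"drug"` or `"side_effect"`.
#' @param canonical_name Optional named character vector id -> display string;
#'   defaults to the first surface term seen for each id.
#' @return An object of class `kdse_lexicon` with fields `kind`, `entries`
#'   (named character: normalized term -> id) and `canonical_name`.
#' @export
lexicon <- function(terms, ids, kind = c("drug", "side_effect"),
                    canonical_name = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(terms) == length(ids))
  terms <- normalize_term(as.character(terms))
  ids <- as.character(ids)
  if (any(!nzchar(terms))) stop("lexicon terms must be non-empty", call. = FALSE)
  if (any(!nzchar(ids))) stop("lexicon ids must be non-empty", call. = FALSE)

  dup <- duplicated(paste(terms, ids, sep = "\r"))
  terms <- terms[!dup]
  ids <- ids[!dup]
  # a term mapping to two different ids is ambiguous and must be explicit
  clash <- terms[duplicated(terms)]
  if (length(clash) > 0L) {
    stop(sprintf("ambiguous lexicon term(s) map to multiple ids: %s",
                 paste(unique(clash), collapse = ", ")), call. = FALSE)
  }
  entries <- stats::setNames(ids, terms)
  if (is.null(canonical_name)) {
    first <- !duplicated(ids)
    canonical_name <- stats::setNames(terms[first], ids[first])
  }
  structure(
    list(kind = kind, entries = entries, canonical_name = canonical_name),
    class = "kdse_lexicon"
  )
}

#' @export
print.kdse_lexicon <- function(x, ...) {
  cat(sprintf("<kdse_lexicon> kind=%s: %d terms, %d ids\n",
              x$kind, length(x$entries), length(unique(x$entries))))
  invisible(x)
}

#' Load a lexicon from a TSV file
#'
#' Expects `term<TAB>id` rows, UTF-8, with optional `#`-prefixed header or
#' comment lines.  Terms are normalized; duplicate (term, id) rows collapse to
#' one entry; a term mapping to two different ids is a hard error.
#'
#' @param path Path to the TSV file.
#' @inheritParams lexicon
#' @return A [lexicon()] object.
#' @export
load_lexicon <- function(path, kind = c("drug", "side_effect")) {
  kind <- match.arg(kind)
  tab <- read_tsv_cols(path, 2L, what = "lexicon")
  if (nrow(tab) == 0L) stop(sprintf("lexicon '%s' has no rows", path), call. = FALSE)
  lexicon(tab$V1, tab$V2, kind = kind)
}

#' Write a lexicon to TSV
#'
#' Rows are sorted by term for diff-stability; round-trips through
#' [load_lexicon()] to an identical entries map.
#'
#' @param lex A [lexicon()].
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "kdse_lexicon"))
  ord <- order(names(lex$entries))
  writeLines(paste(names(lex$entries)[ord], unname(lex$entries)[ord], sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' All ids of a lexicon
#' @param lex A [lexicon()].
#' @return Character vector of unique canonical ids.
#' @export
lexicon_ids <- function(lex) unique(unname(lex$entries))

#' Surface terms of a canonical id
#' @param lex A [lexicon()].
#' @param id A canonical id.
#' @return Character vector of normalized surface terms.
#' @export
lexicon_terms <- function(lex, id) names(lex$entries)[lex$entries == id]

#' Construct a known drug-SE pair knowledge base
#'
#' Holds a set (no duplicates) of (drug_id, se_id) pairs, the prior knowledge
#' that gates knowledge-driven extraction and the gold pairs used in
#' evaluation.
#'
#' @param drug_id,se_id Parallel character vectors of canonical ids.
#' @return Object of class `kdse_kb` with a `pairs` data.frame
#'   (`drug_id`, `se_id`).
#' @export
known_pairs <- function(drug_id = character(0), se_id = character(0)) {
  stopifnot(length(drug_id) == length(se_id))
  df <- data.frame(drug_id = as.character(drug_id), se_id = as.character(se_id),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(pair_key(df$drug_id, df$se_id)), , drop = FALSE]
  df <- df[order(df$drug_id, df$se_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pairs = df), class = "kdse_kb")
}

#' @export
print.kdse_kb <- function(x, ...) {
  cat(sprintf("<kdse_kb> %d drug-SE pairs over %d drugs\n",
              nrow(x$pairs), length(unique(x$pairs$drug_id))))
  invisible(x)
}

#' Number of pairs in a knowledge base
#' @param kb A [known_pairs()] object.
#' @return Integer count.
#' @export
kb_size <- function(kb) nrow(kb$pairs)

#' @keywords internal
kb_keys <- function(kb) pair_key(kb$pairs$drug_id, kb$pairs$se_id)

#' Load known drug-SE pairs from TSV
#'
#' Expects `drug<TAB>se` rows where each field is a surface term or a
#' canonical id of the corresponding lexicon.  Unresolvable rows are counted,
#' reported via a message, and skipped; zero resolvable rows is a hard error
#' because an empty prior makes knowledge-driven gating vacuous.
#'
#' @param path Path to the TSV file.
#' @param drugs Drug [lexicon()].
#' @param ses Side-effect [lexicon()].
#' @return A [known_pairs()] knowledge base.
#' @export
load_known_pairs <- function(path, drugs, ses) {
  stopifnot(inherits(drugs, "kdse_lexicon"), inherits(ses, "kdse_lexicon"))
  tab <- read_tsv_cols(path, 2L, what = "pair file")
  resolve <- function(x, lex) {
    x_norm <- normalize_term(x)
    id <- unname(lex$entries[x_norm])
    # accept a canonical id spelled directly
    direct <- x %in% lex$entries
    id[is.na(id) & direct] <- x[is.na(id) & direct]
    id
  }
  d <- resolve(tab$V1, drugs)
  s <- resolve(tab$V2, ses)
  ok <- !is.na(d) & !is.na(s)
  n_skip <- sum(!ok)
  if (n_skip > 0L) {
    message(sprintf("load_known_pairs: skipped %d unresolvable row(s) of %d",
                    n_skip, nrow(tab)))
  }
  if (!any(ok)) stop("no resolvable drug-SE pairs; empty prior knowledge", call. = FALSE)
  known_pairs(d[ok], s[ok])
}

#' Write a knowledge base to TSV
#' @param kb A [known_pairs()] object.
#' @param path Output path.
#' @export
write_known_pairs <- function(kb, path) {
  stopifnot(inherits(kb, "kdse_kb"))
  writeLines(paste(kb$pairs$drug_id, kb$pairs$se_id, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

#' Per-drug random split of a knowledge base
#'
#' For each listed drug its pairs are partitioned disjointly into train and
#' test with `|train| = round(fraction * n)`; pairs of drugs not listed go
#' entirely to train.  Deterministic given `seed`.
#'
#' @param kb A [known_pairs()] knowledge base.
#' @param drugs Character vector of drug ids to split.
#' @param fraction Train fraction in (0, 1); default 0.5 (an equal split).
#' @param seed Integer seed.
#' @return List with `train` and `test` knowledge bases.
#' @export
split_pairs_per_drug <- function(kb, drugs, fraction = 0.5, seed = 17L) {
  stopifnot(inherits(kb, "kdse_kb"), fraction > 0, fraction < 1)
  pairs <- kb$pairs
  n_by_drug <- table(pairs$drug_id)
  missing_or_small <- drugs[!(drugs %in% names(n_by_drug)) | n_by_drug[drugs] < 2L]
  if (length(missing_or_small) > 0L) {
    stop(sprintf("drug(s) with fewer than 2 pairs cannot be split: %s",
                 paste(missing_or_small, collapse = ", ")), call. = FALSE)
  }
  listed <- pairs$drug_id %in% drugs
  train_idx <- which(!listed)
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (d in sort(unique(drugs))) {
      idx <- which(pairs$drug_id == d)
      n_train <- round(fraction * length(idx))
      n_train <- max(1L, min(length(idx) - 1L, n_train))  # both halves non-empty
      take <- sample(idx, n_train)
      train_idx <- c(train_idx, take)
      test_idx <- c(test_idx, setdiff(idx, take))
    }
  })
  list(
    train = known_pairs(pairs$drug_id[train_idx], pairs$se_id[train_idx]),
    test = known_pairs(pairs$drug_id[test_idx], pairs$se_id[test_idx])
  )
}
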