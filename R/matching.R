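# Dictionary matching with the noun-phrase (NP) restriction: matched drug and
# side-effect names must lie inside base noun phrases, the surrogate for the
# parse-tree restriction applied at corpus scale.

#' Noun-phrase restriction configuration
#'
#' @param mode How to treat sentences without supplied NP spans:
#'   `"fallback"` (default) chunks the sentence with [default_np_spans()],
#'   `"require"` drops all matches, `"off"` disables the NP filter entirely.
#' @param strict If `TRUE` a match must coincide exactly with an NP span;
#'   the default requires only containment in one.
#' @param gate If `TRUE` (default) the same NP restriction is applied when
#'   deciding whether a unit contains a known prior pair, not only during
#'   candidate enumeration.
#' @return Object of class `kdse_np_config`.
#' @export
np_config <- function(mode = c("fallback", "require", "off"), strict = FALSE,
                      gate = TRUE) {
  structure(list(mode = match.arg(mode), strict = isTRUE(strict),
                 gate = isTRUE(gate)),
            class = "kdse_np_config")
}

#' @keywords internal
term_regex <- function(term) {
  # escape regex metacharacters, then let any internal space match a
  # whitespace run so raw text with irregular spacing still matches
  esc <- gsub("([][.\\\\+*?^$(){}=!<>|:#/-])", "\\\\\\1", term, perl = TRUE)
  gsub(" ", "\\s+", esc, fixed = TRUE)
}

#' @keywords internal
first_token <- function(terms) {
  tok <- regmatches(terms, regexpr("[a-z0-9]+", terms))
  out <- rep(NA_character_, length(terms))
  out[regexpr("[a-z0-9]+", terms) > 0L] <- tok
  out
}

#' Find lexicon term matches in a sentence
#'
#' Case-insensitive whole-term matching at word boundaries.  A boundary is
#' the start/end of the text or a non-alphanumeric character; `/` and `-` are
#' internal only when they are part of the lexicon term itself
#' (`"thrombosis/embolism"` matches as one term).  Overlapping candidates are
#' resolved longest-match-leftmost so multi-word terms beat embedded
#' unigrams; each text position belongs to at most one match per lexicon.
#'
#' @param sentence A [sentence_record()].
#' @param lex A [lexicon()].
#' @return data.frame with columns `unit_id`, `kind`, `id`, `start`, `end`
#'   (0-based half-open), `surface`.
#' @export
find_term_matches <- function(sentence, lex) {
  stopifnot(inherits(sentence, "kdse_sentence"), inherits(lex, "kdse_lexicon"))
  empty <- data.frame(unit_id = character(0), kind = character(0),
                      id = character(0), start = integer(0), end = integer(0),
                      surface = character(0), stringsAsFactors = FALSE)
  text <- sentence$text
  if (!nzchar(text)) return(empty)
  low <- tolower(text)
  sent_tokens <- unique(regmatches(low, gregexpr("[a-z0-9]+", low))[[1L]])
  terms <- names(lex$entries)
  cand <- terms[first_token(terms) %in% sent_tokens]
  if (length(cand) == 0L) return(empty)

  alnum <- function(ch) grepl("^[a-z0-9]$", ch)
  rows <- list()
  for (term in cand) {
    m <- gregexpr(term_regex(term), low, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      s <- m[j]                       # 1-based first char
      e <- m[j] + len[j] - 1L         # 1-based last char
      before_ok <- s == 1L || !alnum(substr(low, s - 1L, s - 1L))
      after_ok <- e == nchar(low) || !alnum(substr(low, e + 1L, e + 1L))
      if (before_ok && after_ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = sentence$unit_id, kind = lex$kind,
          id = unname(lex$entries[term]),
          start = s - 1L, end = e, surface = substr(text, s, e),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # longest-match-leftmost: scan left to right, prefer the longest match
  # starting earliest, drop anything overlapping an accepted match
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  keep <- logical(nrow(out))
  last_end <- 0L
  for (i in seq_len(nrow(out))) {
    if (out$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- out$end[i]
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Closed-class stoplist for the fallback base-NP chunker: determiners,
# prepositions, conjunctions, auxiliaries and common reporting verbs.
np_chunker_stoplist <- c(
  "a", "an", "the", "this", "that", "these", "those", "there", "which", "who",
  "whom", "whose", "it", "its", "we", "they",
  "of", "in", "on", "at", "for", "with", "without", "by", "to", "from",
  "into", "during", "after", "before", "between", "among", "per", "via",
  "over", "under", "within", "through",
  "and", "or", "but", "nor", "than", "as", "while", "whereas", "if", "when",
  "is", "are", "was", "were", "be", "been", "being", "am",
  "has", "have", "had", "having", "do", "does", "did",
  "can", "could", "may", "might", "will", "would", "shall", "should", "must",
  "include", "includes", "included", "including", "observe", "observed",
  "show", "showed", "shown", "report", "reported", "associate", "associated",
  "cause", "caused", "causes", "induce", "induced", "result", "resulted",
  "occur", "occurred", "develop", "developed", "receive", "received",
  "treat", "treated", "administer", "administered", "demonstrate",
  "demonstrated", "reveal", "revealed", "note", "noted", "find", "found",
  "influence", "influenced", "use", "used",
  "not", "no", "also", "respectively", "significantly", "often"
)

#' Rule-based base noun-phrase chunker
#'
#' A deterministic surrogate for a constituency parse when a sentence carries
#' no NP annotation: maximal runs of tokens that are not in a closed-class
#' stoplist (determiners, prepositions, conjunctions, auxiliaries, common
#' reporting verbs), split at commas, semicolons and parentheses.
#'
#' @param text Sentence text.
#' @param matches Unused; accepted so the chunker can slot in wherever gold
#'   spans would.
#' @return Integer matrix of sorted, non-overlapping 0-based half-open spans.
#' @export
default_np_spans <- function(text, matches = NULL) {
  empty <- as_span_matrix(NULL)
  if (is.null(text) || !nzchar(text)) return(empty)
  tok <- gregexpr("[^ \t\r\n]+", text)[[1L]]
  if (tok[1L] == -1L) return(empty)
  starts <- as.integer(tok)
  lens <- attr(tok, "match.length")
  spans <- list()
  run_start <- NA_integer_
  run_end <- NA_integer_
  close_run <- function() {
    if (!is.na(run_start)) spans[[length(spans) + 1L]] <<- c(run_start, run_end)
    run_start <<- NA_integer_
    run_end <<- NA_integer_
  }
  for (i in seq_along(starts)) {
    raw <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    # token core: trim non-alphanumeric edges, keep internal '/' and '-'
    core <- regexpr("[A-Za-z0-9].*[A-Za-z0-9]|[A-Za-z0-9]", raw)
    if (core == -1L) { close_run(); next }
    core_s <- starts[i] + as.integer(core) - 1L
    core_e <- core_s + attr(core, "match.length") - 1L
    leading_break <- grepl("^[(\\[]", raw, perl = TRUE)
    trailing_break <- grepl("[,;:()\\[\\]]",
                            substr(raw, as.integer(core) +
                                     attr(core, "match.length"), nchar(raw)),
                            perl = TRUE)
    word <- tolower(substr(text, core_s, core_e))
    if (leading_break) close_run()
    if (word %in% np_chunker_stoplist) {
      close_run()
    } else {
      if (is.na(run_start)) run_start <- core_s - 1L  # 0-based
      run_end <- core_e                               # half-open
      if (trailing_break) close_run()
    }
  }
  close_run()
  if (length(spans) == 0L) return(empty)
  as_span_matrix(spans)
}

#' Apply the noun-phrase restriction to term matches
#'
#' Keeps a match iff its span lies inside (or, with `strict`, coincides with)
#' a base-NP span of the sentence.  When the sentence carries no annotation
#' the behaviour follows `np$mode`: chunk with [default_np_spans()]
#' (fallback), drop everything (require), or keep everything (off).
#'
#' @param matches Output of [find_term_matches()] for one sentence.
#' @param sentence The [sentence_record()] the matches came from.
#' @param np An [np_config()].
#' @return The filtered subset of `matches` (always a subset; idempotent).
#' @export
np_filter <- function(matches, sentence, np = np_config()) {
  stopifnot(inherits(np, "kdse_np_config"))
  if (np$mode == "off" || nrow(matches) == 0L) return(matches)
  spans <- sentence$np_spans
  if (is.null(spans)) {
    if (np$mode == "require") return(matches[0L, , drop = FALSE])
    spans <- default_np_spans(sentence$text)
  }
  if (nrow(spans) == 0L) return(matches[0L, , drop = FALSE])
  keep <- vapply(seq_len(nrow(matches)), function(i) {
    s <- matches$start[i]; e <- matches$end[i]
    if (np$strict) {
      any(spans[, 1L] == s & spans[, 2L] == e)
    } else {
      any(spans[, 1L] <= s & e <= spans[, 2L])
    }
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
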