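# Corpus containers: sentence and abstract records, segmentation, JSONL I/O.
# Coordinates are 0-based, half-open character offsets throughout.

#' Construct a sentence record
#'
#' @param pmid Abstract identifier (string).
#' @param k 0-based sentence index within the abstract; the title, when
#'   supplied, is sentence 0.
#' @param text Sentence text.
#' @param np_spans Optional integer matrix (or list of length-2 vectors) of
#'   0-based half-open `[start, end)` character intervals marking base noun
#'   phrases; must be sorted and non-overlapping, within text bounds.
#' @return Object of class `kdse_sentence` with fields `unit_id` (`"pmid:k"`),
#'   `pmid`, `text`, `np_spans` (Nx2 matrix or NULL).
#' @export
sentence_record <- function(pmid, k, text, np_spans = NULL) {
  stopifnot(is.character(pmid), length(pmid) == 1L, nzchar(pmid),
            is.character(text), length(text) == 1L)
  if (!is.null(np_spans)) {
    np_spans <- as_span_matrix(np_spans)
    validate_spans(np_spans, nchar(text))
  }
  structure(
    list(unit_id = paste0(pmid, ":", k), pmid = pmid, text = text,
         np_spans = np_spans),
    class = "kdse_sentence"
  )
}

#' @keywords internal
as_span_matrix <- function(spans) {
  if (is.null(spans) || length(spans) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  if (is.data.frame(spans)) spans <- as.matrix(spans)
  if (is.list(spans)) spans <- do.call(rbind, lapply(spans, as.integer))
  spans <- matrix(as.integer(spans), ncol = 2L)
  colnames(spans) <- c("start", "end")
  spans
}

#' @keywords internal
validate_spans <- function(spans, n_chars) {
  if (nrow(spans) == 0L) return(invisible(spans))
  if (any(spans[, 1L] < 0L) || any(spans[, 2L] > n_chars) ||
      any(spans[, 1L] >= spans[, 2L])) {
    stop("invalid NP span: need 0 <= start < end <= nchar(text)", call. = FALSE)
  }
  if (is.unsorted(spans[, 1L], strictly = TRUE) ||
      any(spans[-1L, 1L] < spans[-nrow(spans), 2L])) {
    stop("NP spans must be sorted and non-overlapping", call. = FALSE)
  }
  invisible(spans)
}

#' Construct an abstract record
#'
#' @param pmid Abstract identifier.
#' @param sentences Character vector of sentence texts, or a list of
#'   `list(text = , np_spans = )` entries.  Sentence 0 is the title when one
#'   is supplied.
#' @return Object of class `kdse_abstract` with ordered `kdse_sentence`
#'   elements whose unit ids are `"pmid:0" .. "pmid:(n-1)"`.
#' @export
abstract_record <- function(pmid, sentences) {
  if (is.character(sentences)) {
    sentences <- lapply(sentences, function(t) list(text = t, np_spans = NULL))
  }
  recs <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    sentence_record(pmid, i - 1L, s$text, s$np_spans)
  })
  structure(list(pmid = pmid, sentences = recs), class = "kdse_abstract")
}

#' Segment abstract text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an uppercase letter or digit, never inside parentheses or
#' brackets.  Concatenating the sentences with single spaces reconstructs the
#' input modulo whitespace.
#'
#' @param text Non-empty abstract text.
#' @return Character vector of sentence strings.
#' @export
segment_abstract <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  depth <- 0L
  breaks <- integer(0)  # index of last char of a sentence
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- max(0L, depth - 1L)
    if (depth == 0L && ch %in% c(".", "!", "?")) {
      # absorb a run of closing punctuation after the terminator
      j <- i
      while (j < n && chars[j + 1L] %in% c("\"", "'", ")", "]")) j <- j + 1L
      k <- j + 1L
      while (k <= n && grepl("^\\s$", chars[k])) k <- k + 1L
      if (k > j + 1L && k <= n && grepl("^[A-Z0-9(\"]$", chars[k])) {
        breaks <- c(breaks, j)
        i <- k
        next
      }
    }
    i <- i + 1L
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- vapply(seq_along(starts), function(s) {
    trimws(paste(chars[starts[s]:ends[s]], collapse = ""))
  }, character(1))
  out[nzchar(out)]
}

#' Read a corpus from JSON Lines
#'
#' One abstract per line:
#' `{"pmid": "...", "sentences": [{"text": "...", "np_spans": [[s,e],...]}, ...]}`
#' where `np_spans` is optional.  A plain string in `sentences` is also
#' accepted as a sentence without spans.
#'
#' @param path Path to the JSONL file.
#' @return List of [abstract_record()] objects.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("corpus file '%s' not found", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (is.null(obj$pmid)) stop("corpus line missing 'pmid'", call. = FALSE)
    sents <- lapply(obj$sentences, function(s) {
      if (is.character(s)) return(list(text = s, np_spans = NULL))
      spans <- s$np_spans
      if (!is.null(spans) && length(spans) > 0L) {
        spans <- do.call(rbind, lapply(spans, function(p) as.integer(unlist(p))))
      } else {
        spans <- NULL
      }
      list(text = s$text, np_spans = spans)
    })
    abstract_record(as.character(obj$pmid), sents)
  })
}

#' Write a corpus to JSON Lines
#'
#' @param abstracts List of [abstract_record()] objects.
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(abstracts, path) {
  lines <- vapply(abstracts, function(ab) {
    sents <- lapply(ab$sentences, function(s) {
      out <- list(text = s$text)
      if (!is.null(s$np_spans) && nrow(s$np_spans) > 0L) {
        out$np_spans <- lapply(seq_len(nrow(s$np_spans)),
                               function(i) as.integer(s$np_spans[i, ]))
      }
      out
    })
    jsonlite::toJSON(list(pmid = ab$pmid, sentences = sents), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
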