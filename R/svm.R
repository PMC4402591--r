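# The supervised comparison system: distant labeling of sentences from known
# pairs, bag-of-words TF-IDF features (stemmed, stopword-free), and a
# polynomial-kernel SVM, followed by the same co-occurrence extraction.

#' Packaged English stopword list
#' @return Character vector of stopwords.
#' @export
kdse_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "kdse")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @keywords internal
tokenize_stems <- function(texts, stopwords) {
  lapply(texts, function(t) {
    toks <- regmatches(tolower(t), gregexpr("[a-z0-9]+", tolower(t)))[[1L]]
    toks <- toks[!(toks %in% stopwords)]
    if (length(toks) == 0L) return(character(0))
    porter_stem(toks)
  })
}

#' Build a distantly labeled sentence set
#'
#' Positives are sentences containing at least one known drug-SE pair from
#' `kb` minus `excluded_pairs` (for evaluation, the held-out test pairs of
#' the benchmark drugs); negatives are an equal-size uniform sample, without
#' replacement, from the sentences containing none of those pairs.
#' Deterministic given `seed`.
#'
#' @param index A [build_index()] object.
#' @param kb [known_pairs()] used for distant labeling.
#' @param excluded_pairs Optional [known_pairs()] to remove from `kb` first.
#' @param seed Integer seed for the negative sample.
#' @return Object of class `kdse_labeled`: data.frame `unit_id`, `text`,
#'   `label` (logical), `provenance` (`"distant-positive"` /
#'   `"sampled-negative"`).
#' @export
build_training_set <- function(index, kb, excluded_pairs = NULL, seed = 17L) {
  stopifnot(inherits(index, "kdse_index"), inherits(kb, "kdse_kb"))
  keys <- kb_keys(kb)
  if (!is.null(excluded_pairs)) keys <- setdiff(keys, kb_keys(excluded_pairs))
  if (length(keys) == 0L) stop("no labeling pairs left after exclusion", call. = FALSE)
  kbdf <- split_pair_key(keys)
  pos <- character(0)
  for (i in seq_len(nrow(kbdf))) {
    pos <- union(pos, query_pair(index, kbdf$drug_id[i], kbdf$se_id[i],
                                 level = "sentence"))
  }
  if (length(pos) == 0L) stop("no positive sentences: no labeling pair occurs in the corpus", call. = FALSE)
  pool <- setdiff(index_unit_ids(index), pos)
  if (length(pool) < length(pos)) {
    stop(sprintf("insufficient negatives: need %d, only %d pair-free sentences",
                 length(pos), length(pool)), call. = FALSE)
  }
  neg <- withr::with_seed(seed, sample(sort(pool), length(pos)))
  pos <- sort(pos)
  grab_text <- function(u) get(u, envir = index$units)$text
  df <- data.frame(
    unit_id = c(pos, neg),
    text = vapply(c(pos, neg), grab_text, character(1), USE.NAMES = FALSE),
    label = rep(c(TRUE, FALSE), c(length(pos), length(neg))),
    provenance = rep(c("distant-positive", "sampled-negative"),
                     c(length(pos), length(neg))),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  structure(list(sentences = df), class = "kdse_labeled")
}

#' Fit a TF-IDF featurizer
#'
#' Tokenizes on non-alphanumerics, removes packaged stopwords, applies
#' Porter stemming, and learns the vocabulary and smoothed inverse document
#' frequencies `idf = ln((1 + N) / (1 + df)) + 1`.
#'
#' @param texts Character vector of training sentences.
#' @param stopwords Stopword list; defaults to [kdse_stopwords()].
#' @return Object of class `kdse_featurizer` with `vocabulary` and `idf`.
#' @export
fit_featurizer <- function(texts, stopwords = kdse_stopwords()) {
  stems <- tokenize_stems(texts, stopwords)
  vocab <- sort(unique(unlist(stems)))
  if (length(vocab) == 0L) stop("empty vocabulary", call. = FALSE)
  df_count <- table(factor(unlist(lapply(stems, unique)), levels = vocab))
  n <- length(texts)
  idf <- log((1 + n) / (1 + as.numeric(df_count))) + 1
  structure(list(vocabulary = vocab, idf = stats::setNames(idf, vocab),
                 stopwords = stopwords),
            class = "kdse_featurizer")
}

#' TF-IDF feature matrix
#'
#' Term counts weighted by the featurizer's idf, rows L2-normalized;
#' out-of-vocabulary tokens are ignored, and a sentence of only stopwords
#' maps to a zero row.
#'
#' @param texts Character vector of sentences.
#' @param fit A [fit_featurizer()] object.
#' @return Sparse `dgCMatrix` with one row per sentence and one column per
#'   vocabulary stem.
#' @export
featurize <- function(texts, fit) {
  stopifnot(inherits(fit, "kdse_featurizer"))
  stems <- tokenize_stems(texts, fit$stopwords)
  vocab <- fit$vocabulary
  triplets <- lapply(seq_along(stems), function(i) {
    idx <- match(stems[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    tab <- table(idx)
    cbind(i = i, j = as.integer(names(tab)), x = as.numeric(tab))
  })
  triplets <- do.call(rbind, triplets)
  if (is.null(triplets)) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(texts), length(vocab)))
  } else {
    m <- Matrix::sparseMatrix(i = triplets[, "i"], j = triplets[, "j"],
                              x = triplets[, "x"],
                              dims = c(length(texts), length(vocab)))
  }
  m <- m %*% Matrix::Diagonal(x = unname(fit$idf))
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- Matrix::Diagonal(x = 1 / norms) %*% m
  colnames(m) <- vocab
  methods::as(m, "CsparseMatrix")
}

#' Train the polynomial-kernel SVM sentence classifier
#'
#' Fits a maximum-margin classifier (polynomial kernel; degree and cost are
#' configuration, defaulting to 1 and 1) on TF-IDF features of a distantly
#' labeled sentence set, records k-fold cross-validation accuracy, and
#' asserts that re-featurizing the training sentences reproduces the
#' training matrix bit-for-bit.
#'
#' @param labeled A [build_training_set()] object (both classes present).
#' @param degree Polynomial kernel degree (default 1).
#' @param cost Soft-margin cost C (default 1).
#' @param coef0 Kernel offset (default 1).
#' @param cv Number of cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @return Object of class `kdse_svm` with `featurizer`, `fit`, `config`,
#'   `cv_accuracy` and `seed`.
#' @export
train_svm <- function(labeled, degree = 1, cost = 1, coef0 = 1, cv = 10,
                      seed = 17L) {
  stopifnot(inherits(labeled, "kdse_labeled"))
  df <- labeled$sentences
  if (length(unique(df$label)) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  feat <- fit_featurizer(df$text)
  x <- featurize(df$text, feat)
  x2 <- featurize(df$text, feat)
  if (!identical(as.numeric(x), as.numeric(x2))) {
    stop("featurization is not deterministic", call. = FALSE)  # invariant
  }
  y <- factor(df$label, levels = c(FALSE, TRUE))
  cv <- min(cv, min(table(y)))
  fit <- withr::with_seed(seed, {
    e1071::svm(x = x, y = y, kernel = "polynomial", degree = degree,
               cost = cost, coef0 = coef0, scale = FALSE, cross = cv)
  })
  structure(
    list(featurizer = feat, fit = fit,
         config = list(degree = degree, cost = cost, coef0 = coef0, cv = cv),
         cv_accuracy = mean(fit$accuracies) / 100, seed = seed),
    class = "kdse_svm"
  )
}

#' @export
print.kdse_svm <- function(x, ...) {
  cat(sprintf("<kdse_svm> degree=%d cost=%g |vocab|=%d %d-fold CV accuracy %.3f\n",
              x$config$degree, x$config$cost, length(x$featurizer$vocabulary),
              x$config$cv, x$cv_accuracy))
  invisible(x)
}

#' Classify sentences as SE-related or not
#'
#' @param model A classifier (`kdse_svm` or [constant_classifier()]).
#' @param texts Character vector of sentences.
#' @return Logical vector, `TRUE` = SE-related.
#' @export
classify_sentences <- function(model, texts) UseMethod("classify_sentences")

#' @export
classify_sentences.kdse_svm <- function(model, texts) {
  if (length(texts) == 0L) return(logical(0))
  x <- featurize(texts, model$featurizer)
  as.logical(stats::predict(model$fit, x))
}

#' Constant sentence classifier
#'
#' A diagnostic classifier that labels every sentence with a fixed class;
#' the all-positive variant reduces SVM-style extraction to ungated
#' co-occurrence extraction.
#'
#' @param positive Label to emit (default `TRUE`).
#' @return Object of class `kdse_constant`.
#' @export
constant_classifier <- function(positive = TRUE) {
  structure(list(positive = isTRUE(positive)), class = "kdse_constant")
}

#' @export
classify_sentences.kdse_constant <- function(model, texts) {
  rep(model$positive, length(texts))
}

#' Co-occurrence extraction gated by a sentence classifier
#'
#' Applies the classifier to the input sentences and enumerates candidate
#' pairs from the positively classified ones only; same output contract as
#' [extract_pairs()].
#'
#' @param index A [build_index()] object.
#' @param model A classifier for [classify_sentences()].
#' @param input_filter Optional character vector restricting the sentence
#'   units considered (e.g. sentences containing a benchmark drug and an SE
#'   term); default all sentences.
#' @param np An [np_config()] for candidate enumeration.
#' @param prior Optional [known_pairs()] subtracted to form the `novel` set.
#' @return A `kdse_extraction` object (level `"sentence"`).
#' @export
svm_extract <- function(index, model, input_filter = NULL, np = np_config(),
                        prior = NULL) {
  units <- if (is.null(input_filter)) index_unit_ids(index) else sort(input_filter)
  texts <- vapply(units, function(u) get(u, envir = index$units)$text,
                  character(1), USE.NAMES = FALSE)
  keep <- classify_sentences(model, texts)
  units <- units[keep]
  per_unit <- lapply(units, enumerate_candidates, index = index,
                     level = "sentence", np = np)
  aggregate_candidates(per_unit, units, prior, "sentence")
}
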