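# Per-drug evaluation protocol: precision/recall/F1 of KD and SVM extraction
# against held-out known pairs, with unweighted column averages and the
# per-drug F1-increase of KD over SVM.

#' Harmonic-mean F1 score
#'
#' @param p,r Precision and recall in \[0, 1\].
#' @return `2pr/(p+r)`, defined as 0 when `p + r = 0`.
#' @export
f1_score <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Relative F1 increase of KD over the baseline, in percent
#'
#' @param f1_kd,f1_svm F1 scores; `f1_svm` must be positive.
#' @return `100 * (f1_kd - f1_svm) / f1_svm`.
#' @export
f1_increase <- function(f1_kd, f1_svm) {
  if (any(f1_svm <= 0)) stop("baseline F1 must be positive", call. = FALSE)
  100 * (f1_kd - f1_svm) / f1_svm
}

#' Score one drug's extracted pairs against its held-out pairs
#'
#' @param extracted Character vector identifying the extracted pairs of the
#'   drug (e.g. its SE ids); may be empty.
#' @param test Non-empty character vector of held-out pairs for the drug.
#' @return List with `precision`, `recall`, `f1`.
#' @export
score_drug <- function(extracted, test) {
  if (length(test) == 0L) stop("empty test set", call. = FALSE)
  extracted <- unique(extracted)
  test <- unique(test)
  tp <- length(intersect(extracted, test))
  p <- if (length(extracted) == 0L) 0 else tp / length(extracted)
  r <- tp / length(test)
  list(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Aggregate per-drug scores into an evaluation report
#'
#' Column averages are unweighted means of the per-drug values; the mean F1
#' increase is the mean of the per-drug increases, not the increase of the
#' mean F1s.  Because aggregate F1 can be summarized two ways, the report
#' also carries the F1 of the averaged precision/recall, labeled
#' `f1_of_means`.
#'
#' @param per_drug data.frame with columns `drug_id`, `kd_precision`,
#'   `kd_recall`, `svm_precision`, `svm_recall` (F1 columns are recomputed if
#'   absent).
#' @return Object of class `kdse_report`: `per_drug` (with `kd_f1`,
#'   `svm_f1`, `f1_increase_pct`), `averages`, `mean_f1_increase_pct`,
#'   `f1_of_means`.
#' @export
aggregate_report <- function(per_drug) {
  stopifnot(nrow(per_drug) >= 1L)
  per_drug$kd_f1 <- f1_score(per_drug$kd_precision, per_drug$kd_recall)
  per_drug$svm_f1 <- f1_score(per_drug$svm_precision, per_drug$svm_recall)
  per_drug$f1_increase_pct <- ifelse(
    per_drug$svm_f1 > 0,
    100 * (per_drug$kd_f1 - per_drug$svm_f1) / per_drug$svm_f1,
    NA_real_
  )
  cols <- c("kd_precision", "kd_recall", "kd_f1",
            "svm_precision", "svm_recall", "svm_f1")
  averages <- vapply(per_drug[cols], mean, numeric(1))
  structure(
    list(
      per_drug = per_drug,
      averages = averages,
      mean_f1_increase_pct = mean(per_drug$f1_increase_pct, na.rm = TRUE),
      f1_of_means = c(
        kd = f1_score(averages[["kd_precision"]], averages[["kd_recall"]]),
        svm = f1_score(averages[["svm_precision"]], averages[["svm_recall"]])
      )
    ),
    class = "kdse_report"
  )
}

#' Aggregate a report directly from published precision/recall columns
#'
#' Convenience wrapper: takes per-drug precision/recall for both systems (as
#' printed in a benchmark table) and derives F1s, increases and averages.
#'
#' @inheritParams aggregate_report
#' @return A `kdse_report`.
#' @export
report_from_prf <- function(per_drug) aggregate_report(per_drug)

#' @export
print.kdse_report <- function(x, ...) {
  cat("<kdse_report>\n")
  df <- x$per_drug
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  cat(sprintf("averages: KD %.3f/%.3f/%.3f  SVM %.3f/%.3f/%.3f  mean F1 increase %.1f%%\n",
              x$averages[["kd_precision"]], x$averages[["kd_recall"]],
              x$averages[["kd_f1"]], x$averages[["svm_precision"]],
              x$averages[["svm_recall"]], x$averages[["svm_f1"]],
              x$mean_f1_increase_pct))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per drug plus an `average` row, mirroring the benchmark-table
#' layout (precision/recall/F1 for both systems, then F1 increase).
#'
#' @param report A `kdse_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  df <- report$per_drug
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  lines <- c(
    paste("drug", "kd_precision", "kd_recall", "kd_f1",
          "svm_precision", "svm_recall", "svm_f1", "f1_increase_pct",
          sep = "\t"),
    paste(df$drug_id, fmt(df$kd_precision), fmt(df$kd_recall), fmt(df$kd_f1),
          fmt(df$svm_precision), fmt(df$svm_recall), fmt(df$svm_f1),
          paste0(formatC(df$f1_increase_pct, digits = 1, format = "f"), "%"),
          sep = "\t"),
    paste("average", fmt(report$averages[["kd_precision"]]),
          fmt(report$averages[["kd_recall"]]), fmt(report$averages[["kd_f1"]]),
          fmt(report$averages[["svm_precision"]]),
          fmt(report$averages[["svm_recall"]]),
          fmt(report$averages[["svm_f1"]]),
          paste0(formatC(report$mean_f1_increase_pct, digits = 1,
                         format = "f"), "%"),
          sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Published ten-drug benchmark precision/recall table
#'
#' The packaged per-drug sentence-level precision and recall of
#' knowledge-driven and SVM extraction for the ten drugs with the most known
#' side effects, used as input to the arithmetic of [aggregate_report()].
#'
#' @return data.frame with columns `drug_id`, `kd_precision`, `kd_recall`,
#'   `svm_precision`, `svm_recall`.
#' @export
ten_drug_benchmark <- function() {
  path <- system.file("extdata", "ten_drug_benchmark.tsv", package = "kdse")
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  names(tab) <- c("drug_id", "kd_precision", "kd_recall",
                  "svm_precision", "svm_recall")
  tab
}

# Sentence units containing at least one of `drug_ids` and at least one SE
# term (raw whole-term containment, the shared input filter of the protocol).
#' @keywords internal
protocol_input_units <- function(index, drug_ids) {
  units <- index_unit_ids(index)
  keep <- vapply(units, function(u) {
    m <- unit_raw_matches(index, u)
    any(m$drug$id %in% drug_ids) && nrow(m$se) > 0L
  }, logical(1))
  units[keep]
}

#' Run the ten-drug comparison protocol on a corpus
#'
#' For each evaluated drug, its known pairs are split per-drug into equal
#' train/test halves.  Both systems see the same input sentences — those
#' containing at least one evaluated drug and at least one SE term.  The KD
#' system uses the train split (plus all pairs of non-evaluated drugs) as
#' prior knowledge; the SVM is trained on distant labels built from `kb`
#' minus the evaluated drugs' test pairs.  Each drug is scored on its novel
#' extracted SE ids (train pairs removed) against its test split.
#'
#' @param index A [build_index()] object.
#' @param kb [known_pairs()] knowledge base (each evaluated drug needs >= 2
#'   pairs).
#' @param drugs Character vector of evaluated drug ids.
#' @param seed Integer seed (split, negative sampling, CV folds).
#' @param fraction Train fraction of the per-drug split (default 0.5).
#' @param np An [np_config()] shared by both systems.
#' @param svm_config List with `degree`, `cost`, `coef0`, `cv` for
#'   [train_svm()].
#' @param classifier `"svm"` or `"always_positive"` (diagnostic baseline in
#'   which every input sentence is classified SE-related).
#' @return A `kdse_report` with the fitted split attached as attributes
#'   `train`/`test`.
#' @export
run_protocol <- function(index, kb, drugs, seed = 17L, fraction = 0.5,
                         np = np_config(),
                         svm_config = list(degree = 1, cost = 1, coef0 = 1,
                                           cv = 10),
                         classifier = c("svm", "always_positive")) {
  classifier <- match.arg(classifier)
  split <- split_pairs_per_drug(kb, drugs, fraction = fraction, seed = seed)
  train <- split$train
  test <- split$test
  input_units <- protocol_input_units(index, drugs)

  # KD: gate with the train split, restrict to the shared input sentences
  kd_units <- intersect(
    classify_units(index, train, level = "sentence", np = np),
    input_units
  )
  kd_res <- aggregate_candidates(
    lapply(kd_units, enumerate_candidates, index = index, level = "sentence",
           np = np),
    kd_units, train, "sentence"
  )

  # SVM: distant labels from kb minus the evaluated drugs' test pairs
  model <- if (classifier == "always_positive") {
    constant_classifier(TRUE)
  } else {
    train_svm(build_training_set(index, kb, excluded_pairs = test,
                                 seed = seed),
              degree = svm_config$degree, cost = svm_config$cost,
              coef0 = svm_config$coef0, cv = svm_config$cv, seed = seed)
  }
  svm_res <- svm_extract(index, model, input_filter = input_units, np = np,
                         prior = train)

  novel_ses <- function(res, d) {
    unique(res$novel$se_id[res$novel$drug_id == d])
  }
  rows <- lapply(sort(drugs), function(d) {
    test_d <- test$pairs$se_id[test$pairs$drug_id == d]
    kd <- score_drug(novel_ses(kd_res, d), test_d)
    sv <- score_drug(novel_ses(svm_res, d), test_d)
    data.frame(drug_id = d,
               kd_precision = kd$precision, kd_recall = kd$recall,
               svm_precision = sv$precision, svm_recall = sv$recall,
               stringsAsFactors = FALSE)
  })
  report <- aggregate_report(do.call(rbind, rows))
  attr(report, "train") <- train
  attr(report, "test") <- test
  report
}
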