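# Shared-side-effect correlation analyses: for drug-drug pairs sharing at
# least k side effects, the mean of a pairwise property (shared attributes
# from a drug->attribute table, or a pairwise score from a score table) as a
# function of the cutoff k.

#' Construct a drug attribute table
#'
#' @param drug_id,attribute Parallel character vectors of drug ids and
#'   attribute ids (e.g. target genes, metabolism genes, disease
#'   indications).
#' @param kind Label: `"targets"`, `"metabolism"`, `"indications"`, or any
#'   string.
#' @return Object of class `kdse_attr_table`: `kind` and `sets`, a named
#'   list drug_id -> character vector of attributes.
#' @export
attribute_table <- function(drug_id, attribute, kind = "targets") {
  stopifnot(length(drug_id) == length(attribute))
  sets <- lapply(split(as.character(attribute), as.character(drug_id)), unique)
  if (any(lengths(sets) == 0L)) stop("empty attribute set", call. = FALSE)
  structure(list(kind = kind, sets = sets), class = "kdse_attr_table")
}

#' Load an attribute table from TSV (`drug<TAB>attribute`)
#' @param path Path to the TSV file.
#' @inheritParams attribute_table
#' @return A [attribute_table()].
#' @export
load_attribute_table <- function(path, kind = "targets") {
  tab <- read_tsv_cols(path, 2L, what = "attribute table")
  if (nrow(tab) == 0L) stop(sprintf("attribute table '%s' has no rows", path),
                            call. = FALSE)
  attribute_table(tab$V1, tab$V2, kind = kind)
}

#' Construct a symmetric drug-pair score table
#'
#' @param drug1,drug2 Parallel character vectors (no self-pairs).
#' @param score Non-negative numeric scores.
#' @param kind Label, e.g. `"database"`, `"similarity"`, `"experimental"`.
#' @return Object of class `kdse_score_table` with an environment keyed by
#'   the sorted drug pair.
#' @export
score_table <- function(drug1, drug2, score, kind = "database") {
  stopifnot(length(drug1) == length(drug2), length(drug1) == length(score))
  if (any(drug1 == drug2)) stop("self-pairs are not allowed", call. = FALSE)
  if (any(score < 0)) stop("scores must be non-negative", call. = FALSE)
  env <- new.env(parent = emptyenv())
  a <- pmin(as.character(drug1), as.character(drug2))
  b <- pmax(as.character(drug1), as.character(drug2))
  keys <- paste(a, b, sep = "\t")
  for (i in seq_along(keys)) assign(keys[i], score[i], envir = env)
  structure(list(kind = kind, scores = env), class = "kdse_score_table")
}

#' Load a score table from TSV (`drug1<TAB>drug2<TAB>score`)
#' @param path Path to the TSV file.
#' @inheritParams score_table
#' @return A [score_table()].
#' @export
load_score_table <- function(path, kind = "database") {
  tab <- read_tsv_cols(path, 3L, what = "score table")
  if (nrow(tab) == 0L) stop(sprintf("score table '%s' has no rows", path),
                            call. = FALSE)
  score_table(tab$V1, tab$V2, as.numeric(tab$V3), kind = kind)
}

#' Pairwise shared-SE counts
#'
#' For every unordered pair of distinct drugs appearing in the drug-SE pair
#' set, the number of side effects the two drugs share (0 allowed).
#'
#' @param pairs A [known_pairs()] knowledge base or a data.frame with
#'   `drug_id`, `se_id`.
#' @return data.frame with columns `drug1`, `drug2` (`drug1 < drug2`),
#'   `shared`.
#' @export
shared_se_counts <- function(pairs) {
  df <- if (inherits(pairs, "kdse_kb")) pairs$pairs else pairs
  sets <- lapply(split(df$se_id, df$drug_id), unique)
  drugs <- sort(names(sets))
  n <- length(drugs)
  if (n < 2L) {
    return(data.frame(drug1 = character(0), drug2 = character(0),
                      shared = integer(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  shared <- vapply(seq_len(ncol(idx)), function(k) {
    length(intersect(sets[[drugs[idx[1L, k]]]], sets[[drugs[idx[2L, k]]]]))
  }, integer(1))
  data.frame(drug1 = drugs[idx[1L, ]], drug2 = drugs[idx[2L, ]],
             shared = shared, stringsAsFactors = FALSE)
}

#' @keywords internal
curve_frame <- function(cutoffs, n_pairs, means) {
  out <- data.frame(cutoff = cutoffs, n_pairs = n_pairs, mean = means)
  # sanity: qualifying-pair counts can only shrink as the cutoff grows
  stopifnot(!is.unsorted(rev(out$n_pairs)))
  out
}

#' Shared-SE cutoff curve over a drug attribute table
#'
#' For each cutoff k, restricts to drug pairs sharing at least k SEs with
#' both drugs present in the table, and reports the mean number of shared
#' attributes.  A cutoff with no qualifying pairs yields `NA` (undefined,
#' not 0) and a message.
#'
#' @param shared Output of [shared_se_counts()].
#' @param table A [attribute_table()].
#' @param cutoffs Ascending integer cutoffs; 0 means all drug pairs.
#'   Default `c(0, 1, 10, 50, 100)`.
#' @return data.frame `cutoff`, `n_pairs`, `mean` (class `kdse_curve`).
#' @export
attribute_overlap_curve <- function(shared, table,
                                    cutoffs = c(0, 1, 10, 50, 100)) {
  stopifnot(inherits(table, "kdse_attr_table"), !is.unsorted(cutoffs))
  keep <- shared$drug1 %in% names(table$sets) &
    shared$drug2 %in% names(table$sets)
  sub <- shared[keep, , drop = FALSE]
  overlap <- vapply(seq_len(nrow(sub)), function(i) {
    length(intersect(table$sets[[sub$drug1[i]]], table$sets[[sub$drug2[i]]]))
  }, integer(1))
  means <- numeric(length(cutoffs))
  n_pairs <- integer(length(cutoffs))
  for (j in seq_along(cutoffs)) {
    q <- sub$shared >= cutoffs[j]
    n_pairs[j] <- sum(q)
    if (n_pairs[j] == 0L) {
      message(sprintf("no drug pairs share >= %d SEs; mean undefined", cutoffs[j]))
      means[j] <- NA_real_
    } else {
      means[j] <- mean(overlap[q])
    }
  }
  out <- curve_frame(cutoffs, n_pairs, means)
  class(out) <- c("kdse_curve", class(out))
  attr(out, "kind") <- table$kind
  out
}

#' Shared-SE cutoff curve over a pairwise score table
#'
#' As [attribute_overlap_curve()], but the pair property is a pairwise score
#' rather than an attribute overlap.  Every drug pair of `shared` qualifies
#' (subject to the cutoff); pairs absent from the score table contribute 0
#' with `missing = "zero"` (default) or are dropped from the mean with
#' `missing = "skip"`.
#'
#' @param shared Output of [shared_se_counts()].
#' @param table A [score_table()].
#' @param cutoffs Ascending integer cutoffs.
#' @param missing `"zero"` or `"skip"`.
#' @return data.frame `cutoff`, `n_pairs`, `mean` (class `kdse_curve`).
#' @export
score_curve <- function(shared, table, cutoffs = c(0, 1, 10, 50, 100),
                        missing = c("zero", "skip")) {
  stopifnot(inherits(table, "kdse_score_table"), !is.unsorted(cutoffs))
  missing <- match.arg(missing)
  keys <- paste(pmin(shared$drug1, shared$drug2),
                pmax(shared$drug1, shared$drug2), sep = "\t")
  vals <- vapply(keys, function(k) {
    if (exists(k, envir = table$scores, inherits = FALSE)) {
      get(k, envir = table$scores)
    } else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  if (missing == "zero") vals[is.na(vals)] <- 0
  means <- numeric(length(cutoffs))
  n_pairs <- integer(length(cutoffs))
  for (j in seq_along(cutoffs)) {
    q <- shared$shared >= cutoffs[j]
    n_pairs[j] <- sum(q)
    v <- vals[q]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      message(sprintf("no scored drug pairs share >= %d SEs; mean undefined",
                      cutoffs[j]))
      means[j] <- NA_real_
    } else {
      means[j] <- mean(v)
    }
  }
  out <- curve_frame(cutoffs, n_pairs, means)
  class(out) <- c("kdse_curve", class(out))
  attr(out, "kind") <- table$kind
  out
}

#' Write a cutoff curve to TSV (`cutoff<TAB>n_pairs<TAB>mean`)
#' @param curve A curve from [attribute_overlap_curve()] or [score_curve()].
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  writeLines(
    paste(curve$cutoff, curve$n_pairs,
          ifelse(is.na(curve$mean), "NA", format(curve$mean, digits = 10)),
          sep = "\t"),
    path, useBytes = TRUE
  )
  invisible(path)
}
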