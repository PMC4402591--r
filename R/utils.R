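# Shared internal helpers.

#' @keywords internal
pair_key <- function(drug_id, se_id) paste(drug_id, se_id, sep = "\t")

#' @keywords internal
split_pair_key <- function(key) {
  parts <- strsplit(key, "\t", fixed = TRUE)
  data.frame(
    drug_id = vapply(parts, `[`, character(1), 1L),
    se_id = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Read a 2+ column TSV, skipping blank lines and '#'-prefixed header/comment
# lines.  Returns a character matrix-like data.frame; no type coercion.
#' @keywords internal
read_tsv_cols <- function(path, n_cols, what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("cannot read %s: '%s' does not exist", what, path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(as.data.frame(matrix(character(0), ncol = n_cols), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < n_cols)
  if (length(bad) > 0L) {
    stop(sprintf("%s '%s': line %d has fewer than %d tab-separated fields",
                 what, path, bad[1L], n_cols), call. = FALSE)
  }
  out <- as.data.frame(
    do.call(rbind, lapply(parts, function(p) p[seq_len(n_cols)])),
    stringsAsFactors = FALSE
  )
  names(out) <- paste0("V", seq_len(n_cols))
  out
}

#' @keywords internal
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
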