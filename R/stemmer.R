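# Porter suffix-stripping stemmer (classic steps 1a-5b), used by the
# bag-of-words featurizer.  Operates on lowercase ASCII tokens.

porter_vowels <- c("a", "e", "i", "o", "u")

# consonant at position i: not a,e,i,o,u; 'y' is a consonant unless preceded
# by a consonant
porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% porter_vowels) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

# the measure m of a stem: number of VC sequences
porter_measure <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) return(0L)
  types <- vapply(seq_along(chars), function(i) porter_is_cons(chars, i), logical(1))
  runs <- rle(types)$values
  sum(runs == FALSE & c(runs[-1L], NA) == TRUE, na.rm = TRUE)
}

porter_has_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1L]]
  any(vapply(seq_along(chars), function(i) !porter_is_cons(chars, i), logical(1)))
}

porter_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1L]]
  chars[n] == chars[n - 1L] && porter_is_cons(chars, n)
}

# *o: stem ends consonant-vowel-consonant and the final consonant is not w,x,y
porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1L]]
  porter_is_cons(chars, n - 2L) && !porter_is_cons(chars, n - 1L) &&
    porter_is_cons(chars, n) && !(chars[n] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substr(word, n - k + 1L, n) == suffix
}

porter_replace <- function(word, suffix, rep) {
  paste0(substr(word, 1L, nchar(word) - nchar(suffix)), rep)
}

# rule table steps 2-4: apply the first matching suffix whose stem satisfies
# the measure condition
porter_rule_step <- function(word, rules, min_m) {
  for (i in seq_len(nrow(rules))) {
    suf <- rules$suffix[i]
    if (porter_ends(word, suf)) {
      stem <- substr(word, 1L, nchar(word) - nchar(suf))
      if (porter_measure(stem) > min_m) {
        if (!is.na(rules$cond[i]) && rules$cond[i] == "st" &&
            !grepl("[st]$", stem)) {
          return(word)
        }
        return(paste0(stem, rules$rep[i]))
      }
      return(word)  # longest matching suffix decides, even if condition fails
    }
  }
  word
}

porter_step2_rules <- data.frame(
  suffix = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
  rep = c("ate", "tion", "ence", "ance", "ize", "able", "al", "ent", "e",
          "ous", "ize", "ate", "ate", "al", "ive", "ful", "ous", "al", "ive",
          "ble"),
  cond = NA_character_, stringsAsFactors = FALSE
)

porter_step3_rules <- data.frame(
  suffix = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  rep = c("ic", "", "al", "ic", "ic", "", ""),
  cond = NA_character_, stringsAsFactors = FALSE
)

porter_step4_rules <- data.frame(
  suffix = c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize"),
  rep = "",
  cond = c(rep(NA_character_, 11L), "st", rep(NA_character_, 7L)),
  stringsAsFactors = FALSE
)

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # step 1a
  if (porter_ends(word, "sses")) {
    word <- porter_replace(word, "sses", "ss")
  } else if (porter_ends(word, "ies")) {
    word <- porter_replace(word, "ies", "i")
  } else if (!porter_ends(word, "ss") && porter_ends(word, "s")) {
    word <- porter_replace(word, "s", "")
  }

  # step 1b
  if (porter_ends(word, "eed")) {
    stem <- substr(word, 1L, nchar(word) - 3L)
    if (porter_measure(stem) > 0L) word <- porter_replace(word, "eed", "ee")
  } else {
    hit <- FALSE
    for (suf in c("ed", "ing")) {
      if (porter_ends(word, suf)) {
        stem <- substr(word, 1L, nchar(word) - nchar(suf))
        if (porter_has_vowel(stem)) {
          word <- stem
          hit <- TRUE
        }
        break
      }
    }
    if (hit) {
      if (porter_ends(word, "at") || porter_ends(word, "bl") ||
          porter_ends(word, "iz")) {
        word <- paste0(word, "e")
      } else if (porter_double_cons(word) &&
                 !grepl("[lsz]$", word)) {
        word <- substr(word, 1L, nchar(word) - 1L)
      } else if (porter_measure(word) == 1L && porter_cvc(word)) {
        word <- paste0(word, "e")
      }
    }
  }

  # step 1c
  if (porter_ends(word, "y") &&
      porter_has_vowel(substr(word, 1L, nchar(word) - 1L))) {
    word <- porter_replace(word, "y", "i")
  }

  word <- porter_rule_step(word, porter_step2_rules, 0L)
  word <- porter_rule_step(word, porter_step3_rules, 0L)
  word <- porter_rule_step(word, porter_step4_rules, 1L)

  # step 5a
  if (porter_ends(word, "e")) {
    stem <- substr(word, 1L, nchar(word) - 1L)
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) word <- stem
  }
  # step 5b
  if (porter_measure(word) > 1L && porter_double_cons(word) &&
      porter_ends(word, "l")) {
    word <- substr(word, 1L, nchar(word) - 1L)
  }
  word
}

#' Porter-style word stemming
#'
#' Suffix stripping for English tokens (plurals, -ed/-ing, and the standard
#' derivational suffix ladder).  Input is lowercased first; tokens of length
#' 2 or less pass through unchanged.
#'
#' @param words Character vector of tokens.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("toxicities", "vomiting", "associated", "relational"))
#' @export
porter_stem <- function(words) {
  words <- tolower(words)
  uniq <- unique(words)
  stems <- vapply(uniq, porter_stem_one, character(1), USE.NAMES = TRUE)
  unname(stems[words])
}
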