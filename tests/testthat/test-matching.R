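test_that("whole-term matching respects word boundaries and compound terms", {
  ses <- lexicon(c("neutropenia", "nausea", "thrombosis/embolism"),
                 c("neutropenia", "nausea", "thrombosis/embolism"),
                 kind = "side_effect")
  s <- sentence_record("p", 0L, "neutropenia (21%)")
  m <- find_term_matches(s, ses)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 11L))

  s2 <- sentence_record("p", 1L, "a nauseating smell")
  expect_equal(nrow(find_term_matches(s2, ses)), 0L)

  s3 <- sentence_record("p", 2L, "Grade 3 thrombosis/embolism and nausea.")
  m3 <- find_term_matches(s3, ses)
  expect_setequal(m3$id, c("thrombosis/embolism", "nausea"))
})

test_that("longest match wins at each position, one match per lexicon position", {
  ses <- lexicon(c("nausea", "nausea/vomiting", "decreases in hemoglobin",
                   "hemoglobin"),
                 c("S1", "S2", "S3", "S4"), kind = "side_effect")
  s <- sentence_record("p", 0L, "Decreases in hemoglobin, nausea/vomiting occurred.")
  m <- find_term_matches(s, ses)
  expect_identical(sort(m$id), c("S2", "S3"))  # embedded unigrams lose
})

test_that("matching agrees with a brute-force fixed-string oracle on planted sentences", {
  set.seed(31)
  terms <- c("alphadrug", "betamycin", "gamma toxin", "delta/epsilon", "zeta")
  lex <- lexicon(terms, sprintf("T%d", 1:5), kind = "side_effect")
  fillers <- c("patients", "received", "dose", "mg", "daily", "with",
               "severe", "alphadrugs", "betamycinx")
  for (i in 1:40) {
    words <- sample(c(terms, fillers), sample(4:10, 1), replace = TRUE)
    text <- paste(words, collapse = " ")
    s <- sentence_record("p", 0L, text)
    got <- find_term_matches(s, lex)
    for (t in terms) {
      occ <- oracle_occurrences(text, t)
      # oracle occurrences not shadowed by a longer overlapping term
      expect_setequal(got$start[normalize_term(got$surface) == t], occ)
    }
  }
})

test_that("NP filter keeps contained matches, honours modes, is idempotent", {
  ses <- lexicon("neutropenia", "neutropenia", kind = "side_effect")
  s <- sentence_record("p", 0L, "neutropenia occurred today",
                       list(c(0L, 11L)))
  m <- find_term_matches(s, ses)
  expect_equal(nrow(np_filter(m, s, np_config())), 1L)

  s2 <- sentence_record("p", 1L, "mild neutropenia here", list(c(0L, 4L)))
  m2 <- find_term_matches(s2, ses)
  expect_equal(nrow(np_filter(m2, s2, np_config())), 0L)

  # strict requires exact span equality
  s3 <- sentence_record("p", 2L, "severe neutropenia", list(c(0L, 18L)))
  m3 <- find_term_matches(s3, ses)
  expect_equal(nrow(np_filter(m3, s3, np_config(strict = FALSE))), 1L)
  expect_equal(nrow(np_filter(m3, s3, np_config(strict = TRUE))), 0L)

  # no annotation: require drops, off keeps, fallback chunks
  s4 <- sentence_record("p", 3L, "neutropenia was observed")
  m4 <- find_term_matches(s4, ses)
  expect_equal(nrow(np_filter(m4, s4, np_config(mode = "require"))), 0L)
  expect_equal(nrow(np_filter(m4, s4, np_config(mode = "off"))), 1L)
  expect_equal(nrow(np_filter(m4, s4, np_config(mode = "fallback"))), 1L)

  # subset and idempotence
  f <- np_filter(m4, s4, np_config())
  expect_true(all(f$start %in% m4$start))
  expect_identical(np_filter(f, s4, np_config()), f)
})

test_that("fallback chunker produces the frozen base-NP spans", {
  txt <- "grade 3 or higher toxicity included diarrhea (26%)"
  sp <- default_np_spans(txt)
  chunks <- apply(sp, 1L, function(r) substr(txt, r[1] + 1L, r[2]))
  expect_identical(chunks, c("grade 3", "higher toxicity", "diarrhea", "26"))

  txt2 <- "Ondansetron, lidocaine, and fentanyl were effective in preventing pain."
  sp2 <- default_np_spans(txt2)
  chunks2 <- apply(sp2, 1L, function(r) substr(txt2, r[1] + 1L, r[2]))
  expect_true(all(c("Ondansetron", "lidocaine", "fentanyl") %in% chunks2))

  expect_equal(nrow(default_np_spans("")), 0L)

  # structural: sorted, non-overlapping, within bounds, on arbitrary text
  set.seed(7)
  for (i in 1:25) {
    t <- paste(sample(c("a", "the", "of", "dose", "toxicity,", "(3%)",
                        "severe", "was", "rash."), sample(2:9, 1),
                      replace = TRUE), collapse = " ")
    sp <- default_np_spans(t)
    if (nrow(sp) > 1L) {
      expect_true(all(sp[-1L, 1L] >= sp[-nrow(sp), 2L]))
    }
    if (nrow(sp) > 0L) {
      expect_true(all(sp[, 1L] < sp[, 2L] & sp[, 1L] >= 0L &
                        sp[, 2L] <= nchar(t)))
    }
  }
})
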