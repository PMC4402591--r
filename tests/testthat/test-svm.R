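test_that("Porter stemming matches the canonical suffix-stripping outputs", {
  words <- c("caresses", "ponies", "ties", "caress", "cats", "feed", "agreed",
             "plastered", "motoring", "sing", "conflated", "troubled",
             "sized", "hopping", "tanned", "falling", "hissing", "failing",
             "filing", "happy", "relational", "conditional", "rational",
             "vomiting", "toxicities", "associated")
  stems <- c("caress", "poni", "ti", "caress", "cat", "feed", "agre",
             "plaster", "motor", "sing", "conflat", "troubl", "size", "hop",
             "tan", "fall", "hiss", "fail", "file", "happi", "relat",
             "condit", "ration", "vomit", "toxic", "associ")
  expect_identical(porter_stem(words), stems)
})

test_that("TF-IDF features match the hand-checked reference on a toy corpus", {
  docs <- c("nausea vomit rash", "nausea tremor", "rash rash tremor")
  fit <- fit_featurizer(docs)
  m <- as.matrix(featurize(docs, fit))
  # reference values computed independently with the standard smoothed-idf,
  # L2-normalized TF-IDF formulation
  ref <- rbind(
    c(0.5178561162, 0.5178561162, 0, 0.6809185604),
    c(0.7071067812, 0, 0.7071067812, 0),
    c(0, 0.8944271910, 0.4472135955, 0)
  )
  colnames(ref) <- c("nausea", "rash", "tremor", "vomit")
  expect_equal(m, ref, tolerance = 1e-9, ignore_attr = "dimnames")
  expect_identical(colnames(m), colnames(ref))

  # stopword-only sentence is a zero vector; identical sentences get
  # identical rows; OOV tokens are ignored at predict time
  m2 <- as.matrix(featurize(c("the of and", "nausea vomit rash",
                              "nausea vomit rash", "zzz nausea"), fit))
  expect_true(all(m2[1, ] == 0))
  expect_identical(m2[2, ], m2[3, ])
  expect_identical(unname(m2[4, ]), c(1, 0, 0, 0))
})

test_that("distant labeling picks pair-bearing positives and balanced negatives", {
  b <- synth_generate(synth_params(n_drugs = 10L, n_ses = 20L,
                                   n_abstracts = 40L, seed = 12L))
  idx <- build_index(b$corpus, b$drugs, b$ses)
  ls1 <- build_training_set(idx, b$prior, seed = 2L)
  df <- ls1$sentences
  expect_equal(sum(df$label), sum(!df$label))  # exact class balance

  # positive set equals the linear-scan oracle of pair containment
  oracle <- character(0)
  for (i in seq_len(kb_size(b$prior))) {
    dt <- lexicon_terms(b$drugs, b$prior$pairs$drug_id[i])
    st <- lexicon_terms(b$ses, b$prior$pairs$se_id[i])
    oracle <- union(oracle, oracle_units_with_terms(b$corpus, c(dt, st)))
  }
  expect_setequal(df$unit_id[df$label], oracle)
  # negatives contain none of the labeling pairs
  expect_length(intersect(df$unit_id[!df$label], oracle), 0L)

  # determinism given the seed
  ls2 <- build_training_set(idx, b$prior, seed = 2L)
  expect_identical(ls1$sentences, ls2$sentences)

  # a corpus where every sentence has a KB pair leaves no negatives
  one <- abstract_record("only1", "Irinotecan caused diarrhea.")
  drugs <- tiny_drug_lexicon(); ses <- tiny_se_lexicon()
  idx1 <- build_index(list(one), drugs, ses)
  expect_error(build_training_set(idx1, known_pairs("irinotecan", "diarrhea")),
               "insufficient negatives")
})

test_that("SVM training is deterministic, separates separable data, and chance-level on shuffled labels", {
  set.seed(40)
  mk <- function(words, n, id0) {
    data.frame(
      unit_id = sprintf("t%d:%d", id0, seq_len(n)),
      text = vapply(seq_len(n), function(i) {
        paste(sample(words, 6, replace = TRUE), collapse = " ")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  pos_words <- c("toxicity", "adverse", "nausea", "neutropenia", "grade")
  neg_words <- c("efficacy", "response", "survival", "enrollment", "phase")
  pos <- mk(pos_words, 100L, 1L); pos$label <- TRUE
  neg <- mk(neg_words, 100L, 2L); neg$label <- FALSE
  pos$provenance <- "distant-positive"; neg$provenance <- "sampled-negative"
  labeled <- structure(list(sentences = rbind(pos, neg)),
                       class = "kdse_labeled")

  model <- train_svm(labeled, seed = 3L)
  expect_equal(model$cv_accuracy, 1.0)

  m2 <- train_svm(labeled, seed = 3L)
  probe <- c("toxicity nausea grade", "efficacy survival phase")
  expect_identical(classify_sentences(model, probe),
                   classify_sentences(m2, probe))
  expect_identical(classify_sentences(model, probe), c(TRUE, FALSE))

  # label permutation destroys the signal: mean CV accuracy over a few
  # permutations sits at chance level, far below the separable case
  perm_acc <- vapply(1:3, function(s) {
    shuffled <- labeled
    shuffled$sentences$label <- withr::with_seed(s,
                                                 sample(shuffled$sentences$label))
    train_svm(shuffled, seed = 3L)$cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(perm_acc) - 0.5), 0.1)
  expect_lt(max(perm_acc), 0.7)

  mono <- labeled
  mono$sentences$label <- TRUE
  expect_error(train_svm(mono), "one class")
})

test_that("classifier-gated extraction reduces to the expected limits", {
  b <- synth_generate(synth_params(n_drugs = 10L, n_ses = 20L,
                                   n_abstracts = 40L, seed = 19L))
  idx <- build_index(b$corpus, b$drugs, b$ses)

  none <- svm_extract(idx, constant_classifier(FALSE))
  expect_equal(nrow(none$all_candidates), 0L)

  all_pos <- svm_extract(idx, constant_classifier(TRUE))
  ungated <- extract_pairs(idx, NULL, "sentence", gate = FALSE)
  expect_identical(all_pos$all_candidates, ungated$all_candidates)

  # trivially-positive classification recalls at least as much as KD gating
  kd <- extract_pairs(idx, b$prior, "sentence")
  tk <- pair_keys_of(b$truth$pairs)
  recall_all <- mean(tk %in% pair_keys_of(all_pos$all_candidates))
  recall_kd <- mean(tk %in% pair_keys_of(kd$all_candidates))
  expect_gte(recall_all, recall_kd)
})
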