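# The worked-example corpus (four published sentences) is the canonical
# small fixture for gating behaviour.
demo_idx <- local({
  b <- demo_fixture_bundle()
  list(bundle = b, index = build_index(b$corpus, b$drugs, b$ses))
})

test_that("prior-pair gating classifies exactly the pair-bearing sentences", {
  idx <- demo_idx$index
  prior <- demo_idx$bundle$prior
  got <- classify_units(idx, prior, "sentence")
  expect_setequal(got, c("19139178:0", "12032018:0"))
  # the multi-drug trial title contains no known pair and is never SE-related
  expect_false("tpc0000001:0" %in% got)

  absent <- known_pairs("fentanyl", "diarrhea")
  expect_length(classify_units(idx, absent, "sentence"), 0L)
  expect_error(classify_units(idx, known_pairs(), "sentence"), "empty prior")
})

test_that("candidate enumeration is the drug x SE cross product of a unit", {
  idx <- demo_idx$index
  expect_equal(nrow(enumerate_candidates(idx, "19139178:0")), 6L)  # 1 x 6
  expect_equal(nrow(enumerate_candidates(idx, "17577624:0")), 9L)  # 3 x 3
  expect_equal(nrow(enumerate_candidates(idx, "tpc0000001:0")), 0L)  # drugs only
})

test_that("knowledge-driven extraction reproduces the worked examples", {
  res <- extract_pairs(demo_idx$index, demo_idx$bundle$prior, "sentence")
  novel <- res$novel
  expect_equal(nrow(novel), 8L)
  iri <- novel$se_id[novel$drug_id == "irinotecan"]
  expect_setequal(iri, c("neutropenia", "nausea", "fatigue", "anorexia",
                         "thrombosis/embolism"))
  pain <- novel$drug_id[novel$se_id == "pain"]
  expect_setequal(pain, c("lidocaine", "tramadol", "fentanyl"))
  # prior pairs are excluded from the novel set but kept among candidates
  expect_equal(nrow(res$all_candidates), 10L)
  expect_false(any(pair_keys_of(novel) %in% kdse:::kb_keys(demo_idx$bundle$prior)))
})

test_that("classification matches a brute-force scan for any prior pair", {
  b <- synth_generate(synth_params(n_drugs = 10L, n_ses = 20L,
                                   n_abstracts = 30L, seed = 8L))
  idx <- build_index(b$corpus, b$drugs, b$ses)
  prior <- b$prior
  got <- classify_units(idx, prior, "sentence", np = np_config(gate = FALSE))
  oracle <- character(0)
  for (i in seq_len(kb_size(prior))) {
    dt <- lexicon_terms(b$drugs, prior$pairs$drug_id[i])
    st <- lexicon_terms(b$ses, prior$pairs$se_id[i])
    oracle <- union(oracle, oracle_units_with_terms(b$corpus, c(dt, st)))
  }
  expect_setequal(got, oracle)
})

test_that("growing the prior never shrinks the classified units or candidates", {
  b <- synth_generate(synth_params(n_drugs = 12L, n_ses = 24L,
                                   n_abstracts = 50L, seed = 3L))
  idx <- build_index(b$corpus, b$drugs, b$ses)
  n <- kb_size(b$truth)
  small <- known_pairs(b$truth$pairs$drug_id[1:20], b$truth$pairs$se_id[1:20])
  big <- known_pairs(b$truth$pairs$drug_id[1:60], b$truth$pairs$se_id[1:60])
  u_small <- classify_units(idx, small, "sentence")
  u_big <- classify_units(idx, big, "sentence")
  expect_true(all(u_small %in% u_big))
  r_small <- extract_pairs(idx, small, "sentence")
  r_big <- extract_pairs(idx, big, "sentence")
  expect_true(all(pair_keys_of(r_small$all_candidates) %in%
                    pair_keys_of(r_big$all_candidates)))
})

test_that("gated extraction is a subset of ungated co-occurrence extraction", {
  b <- synth_generate(synth_params(n_drugs = 12L, n_ses = 24L,
                                   n_abstracts = 50L, seed = 13L))
  idx <- build_index(b$corpus, b$drugs, b$ses)
  kd <- extract_pairs(idx, b$prior, "sentence")
  naive <- extract_pairs(idx, NULL, "sentence", gate = FALSE)
  expect_true(all(pair_keys_of(kd$novel) %in%
                    pair_keys_of(naive$all_candidates)))
})

test_that("every sentence-level pair of an abstract appears at abstract level", {
  b <- synth_generate(synth_params(n_drugs = 10L, n_ses = 20L,
                                   n_abstracts = 40L, seed = 21L))
  idx <- build_index(b$corpus, b$drugs, b$ses)
  for (pmid in sample(index_pmids(idx), 10L)) {
    ab <- get(pmid, envir = idx$abstracts)
    sent_pairs <- do.call(rbind, lapply(ab$sentences, function(s) {
      enumerate_candidates(idx, s$unit_id, "sentence")
    }))
    abs_pairs <- enumerate_candidates(idx, pmid, "abstract")
    expect_true(all(pair_keys_of(sent_pairs) %in% pair_keys_of(abs_pairs)))
  }
})

test_that("a truth-complete prior on a noise-free corpus leaves nothing novel", {
  b <- synth_generate(synth_params(n_drugs = 10L, n_ses = 20L,
                                   n_abstracts = 60L, confound_rate = 0,
                                   prior_coverage = 1, seed = 6L))
  idx <- build_index(b$corpus, b$drugs, b$ses)
  res <- extract_pairs(idx, b$prior, "sentence")
  expect_equal(nrow(res$novel), 0L)
  # and the candidates recover the planted truth exactly
  pr <- extraction_precision_recall(res, b$truth)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
})

test_that("support counts one unit per pair and the TSV writer sorts by count", {
  b <- demo_fixture_bundle()
  # duplicate-mention sentence: the same pair twice in one sentence
  ab <- abstract_record("dup1", "Irinotecan nausea and irinotecan nausea again.")
  idx <- build_index(c(b$corpus, list(ab)), b$drugs, b$ses)
  res <- extract_pairs(idx, known_pairs("irinotecan", "nausea"), "sentence",
                       np = np_config(mode = "off"))
  row <- res$all_candidates[res$all_candidates$drug_id == "irinotecan" &
                              res$all_candidates$se_id == "nausea", ]
  expect_equal(row$count, 2L)  # two sentences, not three mentions
  path <- withr::local_tempfile(fileext = ".tsv")
  write_extraction(res, path, which = "all")
  lines <- readLines(path)
  counts <- as.integer(vapply(strsplit(lines, "\t"), `[`, character(1), 3L))
  expect_true(!is.unsorted(rev(counts)))
})
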