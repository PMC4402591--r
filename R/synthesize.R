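# Latent-class synthetic corpus generator.  Emulates the two sentence
# archetypes the knowledge-driven gate relies on: SE-reporting sentences in
# which a drug co-occurs with several of its true side effects, and
# confounding treatment-style sentences in which a drug co-occurs with
# SE-lexicon terms that are NOT its side effects.  Drug attribute and score
# tables are tied to the same latent classes so shared-SE and
# shared-attribute structure co-vary.

#' Parameters of the synthetic bundle generator
#'
#' @param n_drugs,n_ses,n_abstracts Corpus dimensions.
#' @param true_pair_density Expected fraction of the drug x SE grid that is
#'   a true pair; each drug gets `max(ses_per_sentence, 2,
#'   round(true_pair_density * n_ses))` true SEs.
#' @param ses_per_sentence True SEs listed per SE-reporting sentence
#'   (>= 2: a drug's side effects are reported several at a time).
#' @param confound_rate Fraction of body sentences that are confounding
#'   treatment-style sentences.
#' @param prior_coverage Fraction of the truth knowledge base released as
#'   prior knowledge.  Priors are nested: at a fixed seed the prior at a
#'   lower coverage is a subset of the prior at a higher one.
#' @param n_latent_classes Number of drug classes (<= n_drugs) controlling
#'   SE sharing and the attribute/score structure.
#' @param seed Integer seed.
#' @return Object of class `kdse_synth_params`.
#' @export
synth_params <- function(n_drugs = 30L, n_ses = 60L, n_abstracts = 200L,
                         true_pair_density = 0.15, ses_per_sentence = 3L,
                         confound_rate = 0.3, prior_coverage = 0.5,
                         n_latent_classes = 5L, seed = 17L) {
  stopifnot(is_count(n_drugs), is_count(n_ses), is_count(n_abstracts),
            true_pair_density > 0, true_pair_density < 1,
            is_count(ses_per_sentence), ses_per_sentence >= 2L,
            confound_rate >= 0, confound_rate <= 1,
            prior_coverage >= 0, prior_coverage <= 1,
            is_count(n_latent_classes), n_latent_classes <= n_drugs)
  structure(
    list(n_drugs = as.integer(n_drugs), n_ses = as.integer(n_ses),
         n_abstracts = as.integer(n_abstracts),
         true_pair_density = true_pair_density,
         ses_per_sentence = as.integer(ses_per_sentence),
         confound_rate = confound_rate, prior_coverage = prior_coverage,
         n_latent_classes = as.integer(n_latent_classes),
         seed = as.integer(seed)),
    class = "kdse_synth_params"
  )
}

# assemble a sentence from literal and term fragments, tracking 0-based
# half-open spans of the term fragments (the gold base-NP annotation)
#' @keywords internal
build_sentence <- function(fragments) {
  text <- ""
  spans <- list()
  for (f in fragments) {
    if (isTRUE(f$term)) {
      spans[[length(spans) + 1L]] <- c(nchar(text), nchar(text) + nchar(f$text))
    }
    text <- paste0(text, f$text)
  }
  list(text = text, np_spans = as_span_matrix(spans))
}

#' @keywords internal
lit <- function(x) list(text = x, term = FALSE)
#' @keywords internal
trm <- function(x) list(text = x, term = TRUE)

#' @keywords internal
se_listing <- function(terms) {
  frags <- list()
  n <- length(terms)
  for (i in seq_len(n)) {
    if (i > 1L) frags[[length(frags) + 1L]] <- lit(if (i == n) " and " else ", ")
    frags[[length(frags) + 1L]] <- trm(terms[i])
  }
  frags
}

#' Generate a synthetic bundle
#'
#' Drugs are assigned to latent classes; each drug's true SEs are drawn
#' mostly from its class pool (within-class sharing) with the remainder
#' global.  Each abstract has a title (sentence 0, drug mention only) and
#' three body sentences, each either SE-reporting (the focal drug plus
#' `ses_per_sentence` of its true SEs, cycling through the drug's SE list so
#' the corpus eventually emits every true pair) or confounding (the drug
#' plus a non-SE lexicon term).  Gold NP spans mark every emitted term.
#' Attribute tables (targets, metabolism, indications) and two of the three
#' score tables (database, similarity) are class-linked; the experimental
#' score table is drawn independently of class.  Deterministic given the
#' seed.
#'
#' @param params A [synth_params()] object.
#' @return Object of class `kdse_bundle`: `corpus` (list of
#'   [abstract_record()]), `truth` and `prior` ([known_pairs()]), `drugs` and
#'   `ses` lexicons, `attributes` (list of [attribute_table()]), `scores`
#'   (list of [score_table()]), `params`.
#' @export
synth_generate <- function(params = synth_params()) {
  stopifnot(inherits(params, "kdse_synth_params"))
  p <- params
  withr::with_seed(p$seed, {
    drug_terms <- sprintf("drugax%03d", seq_len(p$n_drugs))
    drug_ids <- sprintf("D%03d", seq_len(p$n_drugs))
    se_terms <- sprintf("toxeff%03d", seq_len(p$n_ses))
    se_terms[seq_len(p$n_ses) %% 5L == 0L] <-
      paste(se_terms[seq_len(p$n_ses) %% 5L == 0L], "syndrome")
    se_ids <- sprintf("S%03d", seq_len(p$n_ses))
    drugs <- lexicon(drug_terms, drug_ids, kind = "drug")
    ses <- lexicon(se_terms, se_ids, kind = "side_effect")

    classes <- rep_len(seq_len(p$n_latent_classes), p$n_drugs)
    se_pool <- split(seq_len(p$n_ses),
                     rep_len(seq_len(p$n_latent_classes), p$n_ses))

    m <- max(p$ses_per_sentence, 2L, round(p$true_pair_density * p$n_ses))
    truth_list <- lapply(seq_len(p$n_drugs), function(d) {
      pool <- se_pool[[classes[d]]]
      n_in <- min(length(pool), ceiling(0.8 * m))
      own <- sample(pool, n_in)
      rest <- setdiff(seq_len(p$n_ses), own)
      c(own, sample(rest, m - n_in))
    })
    truth <- known_pairs(
      rep(drug_ids, each = m),
      se_ids[unlist(truth_list)]
    )

    # per-drug emission order: a fixed shuffle cycled across sentences
    emit_order <- lapply(truth_list, sample)
    emit_pos <- rep(1L, p$n_drugs)

    focal <- rep_len(seq_len(p$n_drugs), p$n_abstracts)
    corpus <- vector("list", p$n_abstracts)
    for (a in seq_len(p$n_abstracts)) {
      d <- focal[a]
      sents <- list(build_sentence(list(
        lit("Efficacy and safety of "), trm(drug_terms[d]),
        lit(" in a randomized controlled trial.")
      )))
      for (b in 1:3) {
        if (stats::runif(1) < p$confound_rate) {
          non_se <- setdiff(seq_len(p$n_ses), truth_list[[d]])
          target <- if (length(non_se) > 0L) sample(non_se, 1L) else NA_integer_
          if (is.na(target)) next
          sents[[length(sents) + 1L]] <- build_sentence(list(
            trm(drug_terms[d]), lit(" was effective in the treatment of "),
            trm(se_terms[target]), lit(" in this cohort.")
          ))
        } else {
          k <- p$ses_per_sentence
          ord <- emit_order[[d]]
          take <- ((emit_pos[d] - 1L + 0:(k - 1L)) %% length(ord)) + 1L
          emit_pos[d] <- ((emit_pos[d] - 1L + k) %% length(ord)) + 1L
          picked <- unique(ord[take])
          sents[[length(sents) + 1L]] <- build_sentence(c(
            list(lit("Treatment with "), trm(drug_terms[d]),
                 lit(" was associated with ")),
            se_listing(se_terms[picked]),
            list(lit("."))
          ))
        }
      }
      corpus[[a]] <- abstract_record(sprintf("syn%06d", a), sents)
    }

    # nested prior: a seeded permutation prefix of the truth pairs
    perm <- sample(kb_size(truth))
    n_prior <- ceiling(p$prior_coverage * kb_size(truth))
    prior_idx <- perm[seq_len(n_prior)]
    prior <- known_pairs(truth$pairs$drug_id[prior_idx],
                         truth$pairs$se_id[prior_idx])

    if (kb_size(prior) > 0L) {
      emitted <- unlist(lapply(corpus, function(ab) {
        unlist(lapply(ab$sentences, function(s) s$text))
      }))
      placed <- any(vapply(seq_len(kb_size(prior)), function(i) {
        dterm <- lexicon_terms(drugs, prior$pairs$drug_id[i])[1L]
        sterm <- lexicon_terms(ses, prior$pairs$se_id[i])[1L]
        any(grepl(dterm, emitted, fixed = TRUE) &
              grepl(sterm, emitted, fixed = TRUE))
      }, logical(1)))
      if (!placed) {
        stop("no prior pair could be placed in any sentence; increase n_abstracts or lower confound_rate",
             call. = FALSE)
      }
    }

    make_attr <- function(prefix, pool_size, keep, n_unique, kind) {
      pools <- lapply(seq_len(p$n_latent_classes), function(g) {
        sprintf("%s_c%d_%02d", prefix, g, seq_len(pool_size))
      })
      d_id <- character(0); attr_id <- character(0)
      for (d in seq_len(p$n_drugs)) {
        got <- c(sample(pools[[classes[d]]], keep),
                 sprintf("%s_u_%s_%d", prefix, drug_ids[d], seq_len(n_unique)))
        d_id <- c(d_id, rep(drug_ids[d], length(got)))
        attr_id <- c(attr_id, got)
      }
      attribute_table(d_id, attr_id, kind = kind)
    }
    attributes <- list(
      targets = make_attr("TG", 8L, 5L, 1L, "targets"),
      metabolism = make_attr("MG", 6L, 4L, 1L, "metabolism"),
      indications = make_attr("IND", 10L, 6L, 2L, "indications")
    )

    idx <- utils::combn(p$n_drugs, 2L)
    d1 <- drug_ids[idx[1L, ]]; d2 <- drug_ids[idx[2L, ]]
    same <- classes[idx[1L, ]] == classes[idx[2L, ]]
    n_pair <- ncol(idx)
    db <- ifelse(same, stats::runif(n_pair, 5, 10), stats::runif(n_pair, 0, 3))
    sim <- ifelse(same, stats::runif(n_pair, 2, 6), stats::runif(n_pair, 0, 2))
    exper <- stats::runif(n_pair, 0, 5)
    scores <- list(
      database = score_table(d1, d2, db, kind = "database"),
      similarity = score_table(d1, d2, sim, kind = "similarity"),
      experimental = score_table(d1, d2, exper, kind = "experimental")
    )

    structure(
      list(corpus = corpus, truth = truth, prior = prior, drugs = drugs,
           ses = ses, attributes = attributes, scores = scores,
           params = p),
      class = "kdse_bundle"
    )
  })
}

#' @export
print.kdse_bundle <- function(x, ...) {
  cat(sprintf("<kdse_bundle> %d abstracts, %d drugs, %d SEs, %d truth pairs (%d prior)\n",
              length(x$corpus), length(lexicon_ids(x$drugs)),
              length(lexicon_ids(x$ses)), kb_size(x$truth), kb_size(x$prior)))
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Emits the standard on-disk formats: `corpus.jsonl`, `drugs.tsv`,
#' `ses.tsv`, `truth.tsv`, `prior.tsv`, one `attr_<kind>.tsv` per attribute
#' table and one `score_<kind>.tsv` per score table.
#'
#' @param bundle A [synth_generate()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "kdse_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(bundle$corpus, file.path(dir, "corpus.jsonl"))
  write_lexicon(bundle$drugs, file.path(dir, "drugs.tsv"))
  write_lexicon(bundle$ses, file.path(dir, "ses.tsv"))
  write_known_pairs(bundle$truth, file.path(dir, "truth.tsv"))
  write_known_pairs(bundle$prior, file.path(dir, "prior.tsv"))
  for (kind in names(bundle$attributes)) {
    tab <- bundle$attributes[[kind]]
    rows <- unlist(lapply(names(tab$sets), function(d) {
      paste(d, tab$sets[[d]], sep = "\t")
    }))
    writeLines(sort(rows), file.path(dir, sprintf("attr_%s.tsv", kind)),
               useBytes = TRUE)
  }
  for (kind in names(bundle$scores)) {
    env <- bundle$scores[[kind]]$scores
    keys <- ls(env)
    rows <- vapply(keys, function(k) {
      paste(k, format(get(k, envir = env), digits = 10), sep = "\t")
    }, character(1), USE.NAMES = FALSE)
    writeLines(sort(rows), file.path(dir, sprintf("score_%s.tsv", kind)),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Packaged worked-example corpus
#'
#' Four published example sentences (PMIDs 19139178, 12032018 and 17577624,
#' plus a multi-drug trial title under a synthetic pmid), with hand-built
#' drug and SE lexicons, gold NP spans located programmatically over the
#' lexicon terms, and the two prior pairs (irinotecan-diarrhea and the
#' erroneous treatment pair ondansetron-pain) that drive the worked
#' examples.  `rocuronium` is deliberately absent from the drug lexicon, so
#' the injection-pain sentence yields exactly three incorrectly propagated
#' pairs.
#'
#' @return A `kdse_bundle` with `corpus`, `truth` (= `prior`), `drugs`,
#'   `ses`, `prior`; attribute and score tables are empty lists.
#' @export
demo_fixture_bundle <- function() {
  drugs <- lexicon(
    c("irinotecan", "docetaxel", "cisplatin", "ondansetron", "lidocaine",
      "tramadol", "fentanyl", "mitomycin"),
    c("irinotecan", "docetaxel", "cisplatin", "ondansetron", "lidocaine",
      "tramadol", "fentanyl", "mitomycin"),
    kind = "drug"
  )
  ses <- lexicon(
    c("diarrhea", "neutropenia", "nausea", "fatigue", "anorexia",
      "thrombosis/embolism", "pain", "decreases in hemoglobin",
      "nausea/vomiting", "hyperbilirubinemia"),
    c("diarrhea", "neutropenia", "nausea", "fatigue", "anorexia",
      "thrombosis/embolism", "pain", "decreases in hemoglobin",
      "nausea/vomiting", "hyperbilirubinemia"),
    kind = "side_effect"
  )
  texts <- list(
    "19139178" = paste0(
      "At the final irinotecan dose of 50 mg/m(2), grade 3 or higher ",
      "toxicity included diarrhea (26%), neutropenia (21%), nausea (18%), ",
      "fatigue (16%), anorexia (13%), and thrombosis/embolism (13%)."),
    "tpc0000001" = paste0(
      "Weekly docetaxel, cisplatin, and irinotecan (TPC): results of a ",
      "multicenter phase II trial in patients with metastatic ",
      "esophagogastric cancer."),
    "12032018" = paste0(
      "Ondansetron, lidocaine, tramadol, and fentanyl were effective in ",
      "preventing and decreasing the level of rocuronium injection pain."),
    "17577624" = paste0(
      "Decreases in hemoglobin, nausea/vomiting, and hyperbilirubinemia ",
      "were observed to be influenced by the previous use of irinotecan ",
      "(OR = 3.07, P = 0.003), mitomycin (OR = 2.28, P = 0.004), and ",
      "cisplatin (OR = 1.60, P = 0.007), respectively.")
  )
  corpus <- lapply(names(texts), function(pmid) {
    bare <- sentence_record(pmid, 0L, texts[[pmid]])
    spans <- rbind(find_term_matches(bare, drugs)[, c("start", "end")],
                   find_term_matches(bare, ses)[, c("start", "end")])
    spans <- as_span_matrix(spans[order(spans$start), , drop = FALSE])
    abstract_record(pmid, list(list(text = texts[[pmid]], np_spans = spans)))
  })
  prior <- known_pairs(c("irinotecan", "ondansetron"), c("diarrhea", "pain"))
  structure(
    list(corpus = corpus, truth = prior, prior = prior, drugs = drugs,
         ses = ses, attributes = list(), scores = list(), params = NULL),
    class = "kdse_bundle"
  )
}
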