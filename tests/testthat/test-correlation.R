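test_that("shared-SE counts equal brute-force set intersections", {
  kb <- known_pairs(rep(c("d1", "d2"), each = 7),
                    c(sprintf("s%d", 1:7), sprintf("s%d", 1:7)))
  sh <- shared_se_counts(kb)
  expect_equal(sh$shared, 7L)

  kb2 <- known_pairs(rep(c("d1", "d2"), each = 3),
                     c("a", "b", "c", "x", "y", "z"))
  expect_equal(shared_se_counts(kb2)$shared, 0L)

  set.seed(77)
  n <- 20L
  df <- data.frame(
    drug_id = sample(sprintf("d%02d", 1:n), 300, replace = TRUE),
    se_id = sample(sprintf("s%02d", 1:40), 300, replace = TRUE)
  )
  sh3 <- shared_se_counts(df)
  sets <- lapply(split(df$se_id, df$drug_id), unique)
  for (i in sample(nrow(sh3), 50)) {
    expect_equal(sh3$shared[i],
                 length(intersect(sets[[sh3$drug1[i]]], sets[[sh3$drug2[i]]])))
  }
  # every unordered pair appears exactly once
  expect_equal(nrow(sh3), choose(length(sets), 2))
  expect_true(all(sh3$drug1 < sh3$drug2))
})

test_that("attribute curves average shared attributes over qualifying pairs", {
  kb <- known_pairs(rep(c("d1", "d2", "d3"), each = 2),
                    c("s1", "s2", "s1", "s2", "s8", "s9"))
  sh <- shared_se_counts(kb)
  tab <- attribute_table(c("d1", "d2", "d3"), rep("common", 3))
  cv <- attribute_overlap_curve(sh, tab, cutoffs = c(0, 1))
  expect_equal(cv$mean, c(1, 1))  # all drugs share the one attribute
  expect_equal(cv$n_pairs, c(3L, 1L))

  # cutoff beyond the maximum shared count is undefined, not zero
  expect_message(cv2 <- attribute_overlap_curve(sh, tab, cutoffs = c(0, 99)),
                 "undefined")
  expect_true(is.na(cv2$mean[2]))
  expect_equal(cv2$n_pairs[2], 0L)

  # drugs absent from the table are excluded from its curve
  tab2 <- attribute_table(c("d1", "d2"), c("g1", "g1"))
  cv3 <- attribute_overlap_curve(sh, tab2, cutoffs = c(0))
  expect_equal(cv3$n_pairs, 1L)
  expect_equal(cv3$mean, 1)
})

test_that("score curves honour the missing-pair policy", {
  kb <- known_pairs(rep(c("d1", "d2", "d3"), each = 2),
                    c("s1", "s2", "s1", "s2", "s3", "s4"))
  sh <- shared_se_counts(kb)
  tab <- score_table(c("d1", "d1", "d2"), c("d2", "d3", "d3"), c(4, 4, 4))
  cv <- score_curve(sh, tab, cutoffs = c(0, 2))
  expect_equal(cv$mean, c(4, 4))  # constant scores average to the constant

  empty_pair <- score_table("d1", "d2", 5)
  cv_zero <- score_curve(sh, empty_pair, cutoffs = 0, missing = "zero")
  expect_equal(cv_zero$mean, 5 / 3)  # two absent pairs contribute 0
  cv_skip <- score_curve(sh, empty_pair, cutoffs = 0, missing = "skip")
  expect_equal(cv_skip$mean, 5)
})

test_that("qualifying-pair counts never increase with the cutoff", {
  set.seed(3)
  for (i in 1:10) {
    df <- data.frame(
      drug_id = sample(sprintf("d%d", 1:8), 60, replace = TRUE),
      se_id = sample(sprintf("s%d", 1:25), 60, replace = TRUE)
    )
    sh <- shared_se_counts(df)
    tab <- attribute_table(sprintf("d%d", 1:8),
                           sample(sprintf("g%d", 1:5), 8, replace = TRUE))
    cv <- suppressMessages(
      attribute_overlap_curve(sh, tab, cutoffs = c(0, 1, 2, 4, 8))
    )
    expect_true(!is.unsorted(rev(cv$n_pairs)))
  }
})

test_that("class-linked curves rise with the cutoff; permuted attributes flatten", {
  b <- synth_generate(synth_params(seed = 11L))
  sh <- shared_se_counts(b$truth)
  cv <- attribute_overlap_curve(sh, b$attributes$targets, cutoffs = c(0, 1, 5))
  expect_true(all(diff(cv$mean) > 0))

  # permutation null: shuffling drug -> attribute assignments removes the
  # association between shared SEs and shared attributes
  perm_sets <- withr::with_seed(4L, {
    s <- b$attributes$targets$sets
    stats::setNames(s, sample(names(s)))
  })
  perm_tab <- structure(list(kind = "targets", sets = perm_sets),
                        class = "kdse_attr_table")
  cvp <- attribute_overlap_curve(sh, perm_tab, cutoffs = c(0, 5))
  overall <- cvp$mean[1]
  high <- cvp$mean[2]
  # mean at high cutoff within a simulation CI of the overall mean
  n_high <- cvp$n_pairs[2]
  expect_lt(abs(high - overall), 3 * sqrt(overall / n_high) + 0.5)
})

test_that("attribute and score tables round-trip through their TSV formats", {
  path <- write_tsv_fixture(c("# drug\tattribute", "d1\tg1", "d1\tg2", "d2\tg1"))
  tab <- load_attribute_table(path, kind = "targets")
  expect_setequal(tab$sets$d1, c("g1", "g2"))

  spath <- write_tsv_fixture(c("d1\td2\t3.5", "d2\td3\t1.25"))
  st <- load_score_table(spath, kind = "similarity")
  expect_equal(get("d1\td2", envir = st$scores), 3.5)
  expect_error(score_table("d1", "d1", 2), "self-pairs")
})
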