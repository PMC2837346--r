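# 13 nt toy hairpin used for hand-checked training:
#   GGGCA AAC TGCCC  ->  ((((( ... )))))  (no bulges)
TOY_SEQ <- "GGGCAAACTGCCC"
TOY_DB <- "(((((...)))))"

test_that("training on one hairpin with no smoothing gives exact usage fractions", {
  g <- train_grammar(data.frame(sequence = TOY_SEQ, dot_bracket = TOY_DB),
                     smoothing = 0)
  # Stem productions: 5 pair emissions + 1 Stem->Loop = 6 uses
  expect_equal(g$stem_loop, 1 / 6)
  expect_equal(g$stem_pair["G", "C"], 3 / 6)
  expect_equal(g$stem_pair["C", "G"], 1 / 6)
  expect_equal(g$stem_pair["A", "T"], 1 / 6)
  expect_equal(sum(g$stem_pair), 5 / 6)
  # Loop: A A (continue) then C (end)
  expect_equal(unname(g$loop_cont["A"]), 2 / 3)
  expect_equal(unname(g$loop_end["C"]), 1 / 3)
  validate_grammar(g)
})

test_that("heavy smoothing drives probabilities towards uniform", {
  g <- train_grammar(data.frame(sequence = TOY_SEQ, dot_bracket = TOY_DB),
                     smoothing = 1e6)
  # Stem has 41 productions; each should be ~1/41
  expect_equal(g$stem_loop, 1 / 41, tolerance = 1e-3)
  expect_equal(unname(g$stem_pair["A", "A"]), 1 / 41, tolerance = 1e-3)
  validate_grammar(g)
})

test_that("training rejects branched structures, naming the record", {
  expect_error(
    train_grammar(data.frame(id = "bad1",
                             sequence = "GGGGAAAACCCCGGGGAAAACCCC",
                             dot_bracket = "((((....))))((((....))))")),
    "multiloop.*bad1")
})

test_that("a degenerate single-derivation grammar has closed-form probability", {
  counts <- train_grammar(data.frame(sequence = "AAAA", dot_bracket = "...."),
                          smoothing = 0)
  # only productions used: Stem->Loop (prob 1), Loop->A Loop (3/4), Loop->A (1/4)
  expect_equal(counts$stem_loop, 1)
  p3 <- counts$loop_cont[["A"]]
  pe <- counts$loop_end[["A"]]
  sc <- inside_log_probability(counts, "AAA")
  expect_equal(sc$log_probability, log(p3^2 * pe))
  expect_equal(sc$normalized_score, log(p3^2 * pe) / 3)
  expect_equal(inside_log_probability(counts, "G")$log_probability, -Inf)
})

test_that("inside DP equals direct derivation enumeration", {
  g <- train_grammar(data.frame(
    sequence = c(TOY_SEQ, "GCGGATAACTATCCGC"),
    dot_bracket = c(TOY_DB, "((((((....))))))")), smoothing = 0.5)
  withr::with_seed(4, {
    for (r in 1:40) {
      s <- random_dna(sample(2:12, 1))
      lp <- inside_log_probability(g, s)$log_probability
      expect_equal(lp, log(oracle_inside(g, s)), tolerance = 1e-10, info = s)
    }
  })
  # systematically: every length-3 sequence
  all3 <- apply(expand.grid(BASES <- c("A", "C", "G", "T"), BASES, BASES),
                1, paste, collapse = "")
  for (s in all3) {
    expect_equal(inside_log_probability(g, s)$log_probability,
                 log(oracle_inside(g, s)), tolerance = 1e-10, info = s)
  }
})

test_that("inside probabilities form a sub-probability measure", {
  g <- train_grammar(data.frame(sequence = TOY_SEQ, dot_bracket = TOY_DB),
                     smoothing = 1)
  lens <- c(2L, 4L)
  for (n in lens) {
    seqs <- apply(do.call(expand.grid,
                          rep(list(c("A", "C", "G", "T")), n)),
                  1, paste, collapse = "")
    total <- sum(vapply(seqs, function(s)
      exp(inside_log_probability(g, s)$log_probability), numeric(1)))
    expect_lte(total, 1 + 1e-9)
    expect_gt(total, 0)
  }
})

test_that("dinucleotide shuffling preserves composition exactly", {
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  withr::with_seed(6, {
    for (r in 1:15) {
      s <- random_dna(sample(20:60, 1))
      sh <- dinucleotide_shuffle(s)
      expect_equal(nchar(sh), nchar(s))
      expect_identical(dinucs(sh), dinucs(s))
      expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    }
  })
})

test_that("trained hairpins outscore their dinucleotide shuffles", {
  refs <- small_refs()
  seqs <- refs$registry$precursor_seq
  folds <- lapply(seqs, fold_sequence)
  g <- train_grammar(data.frame(
    sequence = seqs, dot_bracket = vapply(folds, `[[`, "", "dot_bracket")))
  withr::with_seed(19, {
    neg <- unlist(lapply(seqs, function(s)
      replicate(2, dinucleotide_shuffle(s))))
  })
  pos_scores <- score_sequences(g, seqs)$normalized_score
  neg_scores <- score_sequences(g, neg)$normalized_score
  expect_gt(mean(pos_scores), mean(neg_scores))
})

test_that("cutoff calibration hits its specificity target and separates planted hairpins", {
  refs <- small_refs()
  train_seqs <- refs$registry$precursor_seq
  folds <- lapply(train_seqs, fold_sequence)
  g <- train_grammar(data.frame(
    sequence = train_seqs,
    dot_bracket = vapply(folds, `[[`, "", "dot_bracket")))
  withr::with_seed(23, {
    neg <- unlist(lapply(train_seqs, function(s)
      replicate(6, dinucleotide_shuffle(s))))
  })
  # held-out positives: planted novel precursors never used in training
  held_out <- refs$manifest[locus_class %in% c("novel_mirna",
                                               "mirtron_typical",
                                               "mirtron_atypical"),
                            precursor_seq]
  cal <- calibrate_cutoff(g, held_out, neg, target_specificity = 0.95)
  expect_gte(cal$specificity, 0.95)
  expect_gte(cal$sensitivity, 0.9)
  # specificity 1 means the cutoff is the maximum negative score
  cal1 <- calibrate_cutoff(g, held_out, neg, target_specificity = 1)
  expect_equal(cal1$cutoff, max(cal$negative_scores$normalized_score))
  expect_error(calibrate_cutoff(g, character(0), neg), "non-empty")
})

test_that("grammar YAML serialisation round-trips losslessly", {
  refs <- small_refs()
  folds <- lapply(refs$registry$precursor_seq[1:5], fold_sequence)
  g <- train_grammar(data.frame(
    sequence = refs$registry$precursor_seq[1:5],
    dot_bracket = vapply(folds, `[[`, "", "dot_bracket")))
  f <- tempfile(fileext = ".yaml")
  write_grammar_yaml(g, f)
  g2 <- read_grammar_yaml(f)
  expect_equal(unclass(g), unclass(g2), tolerance = 0)
  unlink(f)
})
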