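test_that("the subtractive cascade partitions tags in the prescribed order", {
  refs <- small_refs()
  known_idx <- build_index(refs$precursors)
  tx_idx <- build_index(refs$transcriptome)
  gen_idx <- build_index(refs$genome)
  man <- refs$manifest

  known_seq <- man[locus_class == "known_mirna", mature_seq][1]
  decoy_seq <- man[locus_class == "mrna_decoy", mature_seq][1]
  novel_seq <- man[locus_class == "novel_mirna", mature_seq][1]
  withr::with_seed(3, random_seq <- random_dna(22))
  tags <- data.table::data.table(
    sequence = c(known_seq, decoy_seq, novel_seq, random_seq),
    count = c(10L, 8L, 6L, 2L), library_id = "L")
  cs <- subtractive_cascade(tags, known_idx, tx_idx, gen_idx)
  got <- setNames(cs$tags$bucket, cs$tags$sequence)
  expect_equal(unname(got[known_seq]), "known_precursor")
  expect_equal(unname(got[decoy_seq]), "transcriptome")
  expect_equal(unname(got[novel_seq]), "genome_residual")
  expect_equal(unname(got[random_seq]), "unmatched")
  # partition: every tag in exactly one bucket
  expect_equal(nrow(cs$tags), nrow(tags))
  expect_equal(sum(cs$summary$n_tags), nrow(tags))
})

test_that("cascade buckets partition whole simulated libraries", {
  st <- small_study()
  for (lib in names(st$discovery$cascade)) {
    cs <- st$discovery$cascade[[lib]]
    expect_equal(sum(cs$summary$n_tags),
                 nrow(st$processed[[lib]]$tags))
    expect_false(any(duplicated(cs$tags$sequence)))
  }
})

test_that("overlapping isomiR tags merge into a single candidate locus", {
  st <- small_study()
  refs <- small_refs()
  cand <- st$discovery$candidates
  # no two surviving candidates on the same strand overlap
  surv <- cand[order(chrom, strand, start)]
  for (r in seq_len(nrow(surv) - 1L)) {
    if (surv$chrom[r] == surv$chrom[r + 1L] &&
        surv$strand[r] == surv$strand[r + 1L]) {
      expect_lte(surv$end[r], surv$start[r + 1L] + 0L)
    }
  }
  # candidates carrying several isomiR tags exist and merged correctly
  counts_per_locus <- st$discovery$counts[, .N, by = candidate_id]
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand$total_count >= 2L))
})

test_that("post-filters enforce the published boundary rules exactly", {
  refs <- small_refs()
  rrna_idx <- build_index(refs$rrna)
  gm <- refs$gene_models
  m <- gm[[1]]
  exon_end <- m$exon_ends[1]
  mk_called <- function(mature_start, mature_end, seq, total,
                        libcounts = NULL) {
    cand <- data.table::data.table(
      locus = 1L, chrom = m$chrom, strand = "+",
      start = mature_start, end = mature_end,
      mature_seq = seq, mature_start = mature_start,
      mature_end = mature_end, prec_start = mature_start - 10L,
      prec_end = mature_end + 40L, total_count = total,
      n_libraries = 1L, hairpin_ok = TRUE, scfg_ok = TRUE,
      scfg_score = -1, status = "raw")
    counts <- data.table::data.table(locus = 1L, library_id = "L",
                                     count = total)
    list(candidates = cand, counts = counts)
  }
  seq22 <- strrep("A", 22L)

  # 2 nt overhang into an exon: retained; 3 nt: removed
  keep <- apply_post_filters(
    mk_called(exon_end - 2L, exon_end + 20L, seq22, 50L), rrna_idx, gm)
  expect_equal(keep$candidates$exon_overhang_nt, 2L)
  expect_equal(keep$candidates$status, "named")
  drop <- apply_post_filters(
    mk_called(exon_end - 3L, exon_end + 19L, seq22, 50L), rrna_idx, gm)
  expect_equal(drop$candidates$exon_overhang_nt, 3L)
  expect_equal(drop$candidates$status, "filtered_out:exon_overhang")

  # naming threshold: >5 reads required
  far <- refs$manifest[context_label == "intergenic", prec_start][1]
  at5 <- apply_post_filters(
    mk_called(far + 1000L, far + 1022L, seq22, 5L), rrna_idx, gm)
  expect_equal(at5$candidates$status, "candidate")
  at6 <- apply_post_filters(
    mk_called(far + 1000L, far + 1022L, seq22, 6L), rrna_idx, gm)
  expect_equal(at6$candidates$status, "named")

  # 16 nt matures are excluded outright
  len16 <- apply_post_filters(
    mk_called(far + 1000L, far + 1016L, strrep("A", 16L), 50L),
    rrna_idx, gm)
  expect_equal(len16$candidates$status, "filtered_out:length16")

  # rRNA degradation products are removed
  rr <- refs$manifest[locus_class == "rrna"][1]
  frag <- substr(rr$precursor_seq, 20, 41)
  rfilt <- apply_post_filters(
    mk_called(far + 1000L, far + 1022L, frag, 50L), rrna_idx, gm)
  expect_true(rfilt$candidates$rrna_hit)
  expect_equal(rfilt$candidates$status, "filtered_out:rrna")
})

test_that("relaxing a post-filter never shrinks the surviving set", {
  st <- small_study()
  refs <- small_refs()
  called <- list(
    candidates = data.table::copy(
      st$discovery$candidates)[, c("rrna_hit", "exon_overhang_nt",
                                   "length_ok", "abundance_ok",
                                   "candidate_id") := NULL][
                                     , status := "raw"],
    counts = data.table::copy(
      st$discovery$counts)[, candidate_id := NULL])
  rrna_idx <- build_index(refs$rrna)
  strict <- apply_post_filters(called, rrna_idx, refs$gene_models)
  relaxed <- apply_post_filters(called, rrna_idx, refs$gene_models,
                                exon_overhang_max = 10000L,
                                min_total_reads = 0L)
  n_surv <- function(x) sum(x$candidates$status %in% c("candidate", "named"))
  expect_gte(n_surv(relaxed), n_surv(strict))
  expect_gte(sum(relaxed$candidates$status == "named"),
             sum(strict$candidates$status == "named"))
})

test_that("cross-library tallies satisfy the unique + shared = total identity", {
  st <- small_study()
  tally <- st$discovery$tally
  expect_equal(tally$table$unique + tally$table$shared, tally$table$total)

  # constructed case: one candidate in a single library, one in all
  cand <- data.table::data.table(
    candidate_id = c("c1", "c2"), status = "named")
  counts <- data.table::rbindlist(list(
    data.table::data.table(candidate_id = "c1", library_id = "A",
                           count = 10L),
    data.table::data.table(candidate_id = "c2",
                           library_id = c("A", "B", "C"), count = 5L)))
  tl <- cross_library_tally(cand, counts, libraries = c("A", "B", "C"))
  expect_equal(tl$table[library_id == "A", unique], 1L)
  expect_equal(tl$table[library_id == "A", shared], 1L)
  expect_equal(tl$table[library_id == "B", total], 1L)
  expect_equal(tl$present_in_all, "c2")
})

test_that("published novel-candidate tallies obey the column identity", {
  tally <- read.delim(system.file("extdata", "melanoma_novel_tally.tsv",
                                  package = "mircascade"),
                      check.names = FALSE)
  uni <- unlist(tally[tally$row == "unique_to_library", -1])
  sha <- unlist(tally[tally$row == "present_in_2_or_more", -1])
  tot <- unlist(tally[tally$row == "totals", -1])
  expect_equal(uni + sha, tot)
  expect_equal(unname(tot[["QF1160MB"]]), 85L)
  expect_equal(unname(tot[["MM386"]]), 90L)
})
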