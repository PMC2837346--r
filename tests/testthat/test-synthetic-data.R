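test_that("reference generation is deterministic and writes byte-identical output", {
  r1 <- build_reference_set(genome_length = 20000L, n_genes = 3L,
                            n_planted = list(known_mirna = 3L,
                                             novel_mirna = 2L),
                            seed = 42L)
  r2 <- build_reference_set(genome_length = 20000L, n_genes = 3L,
                            n_planted = list(known_mirna = 3L,
                                             novel_mirna = 2L),
                            seed = 42L)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$manifest, r2$manifest)
  d1 <- tempfile(); d2 <- tempfile()
  write_reference_set(r1, d1)
  write_reference_set(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty plant list still yields a valid genome and gene models", {
  r <- build_reference_set(genome_length = 20000L, n_genes = 3L,
                           n_planted = list(), seed = 9L)
  expect_equal(nrow(r$manifest), 0L)
  expect_length(r$gene_models, 3L)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(r$gene_models, gff)
  models <- read_gff3_models(gff)
  expect_length(models, 3L)
  expect_equal(models[[1]]$exon_starts, r$gene_models[[1]]$exon_starts)
  unlink(gff)
})

test_that("planted loci satisfy their structural invariants", {
  refs <- small_refs()
  man <- refs$manifest
  # arm intervals inside the precursor and disjoint
  mir <- man[!is.na(star_start)]
  expect_true(all(mir$mature_start >= mir$prec_start &
                    mir$mature_end <= mir$prec_end))
  expect_true(all(mir$star_start >= mir$prec_start &
                    mir$star_end <= mir$prec_end))
  expect_true(all(pmin(mir$mature_end, mir$star_end) <=
                    pmax(mir$mature_start, mir$star_start)))
  # planted sequence really sits in the genome at its coordinates
  for (r in seq_len(nrow(man))) {
    sq <- substr(refs$genome[[man$chrom[r]]], man$prec_start[r] + 1L,
                 man$prec_end[r])
    if (man$strand[r] == "-") sq <- revcomp(sq)
    expect_equal(sq, man$precursor_seq[r], info = man$locus_id[r])
  }
  # transcriptome holds the spliced sequence of every gene model
  for (m in refs$gene_models) {
    sq <- paste(substring(refs$genome[[m$chrom]], m$exon_starts + 1L,
                          m$exon_ends), collapse = "")
    if (m$strand == "-") sq <- revcomp(sq)
    expect_equal(refs$transcriptome[[m$transcript_id]], sq)
  }
})

test_that("mirtron precursors anchor to intron boundaries per their type", {
  refs <- small_refs()
  gff <- tempfile(fileext = ".gff3")
  write_gff3(refs$gene_models, gff)
  models <- read_gff3_models(gff)
  man <- refs$manifest
  for (r in which(man$locus_class %in% c("mirtron_typical",
                                         "mirtron_atypical"))) {
    m <- models[[man$host_transcript[r]]]
    in_start <- m$exon_ends[-length(m$exon_ends)]
    in_end <- m$exon_starts[-1L]
    # the host intron is the one containing the precursor
    k <- which(in_start <= man$prec_start[r] & man$prec_end[r] <= in_end)
    expect_length(k, 1L)
    at5 <- man$prec_start[r] == in_start[k]
    at3 <- man$prec_end[r] == in_end[k]
    if (man$locus_class[r] == "mirtron_typical") {
      expect_true(at5 && at3)
    } else {
      expect_true(xor(at5, at3))
    }
  }
  unlink(gff)
})

test_that("manifest and registry round-trip losslessly", {
  refs <- small_refs()
  f <- tempfile()
  write_manifest(refs$manifest, f)
  expect_equal(as.data.frame(read_manifest(f)),
               as.data.frame(refs$manifest))
  write_registry(refs$registry, f)
  expect_equal(as.data.frame(read_registry(f)),
               as.data.frame(refs$registry))
  unlink(f)
})

test_that("simulation respects seeds, read counts and origin conservation", {
  refs <- small_refs()
  w <- setNames(rep(1, nrow(refs$manifest)), refs$manifest$locus_id)
  cfg <- read_sim_config("L1", 3000L, w, seed = 12L)
  s1 <- simulate_library(refs, cfg)
  s2 <- simulate_library(refs, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_equal(length(s1$reads), 3000L)
  expect_equal(nrow(s1$ground_truth), 3000L)
  # conservation: locus reads + noise reads = n_reads
  expect_equal(s1$ground_truth[, .N], 3000L)
  expect_equal(sum(s1$ground_truth$locus_id == ".noise") +
                 sum(s1$ground_truth$locus_id != ".noise"), 3000L)

  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  unlink(c(f1, f2))

  empty <- simulate_library(refs, read_sim_config("L0", 0L, w, seed = 1L))
  expect_length(empty$reads, 0L)
  expect_equal(nrow(empty$ground_truth), 0L)

  expect_error(simulate_library(refs, read_sim_config(
    "Lb", 10L, c(nosuch = 1), seed = 1L)), "unknown locus_id")
  expect_error(read_sim_config("Lw", 10L, c(a = 0)), "sum > 0")
})

test_that("arm sampling matches the configured mature:star ratio", {
  refs <- small_refs()
  lid <- refs$manifest[locus_class == "known_mirna", locus_id][1]
  cfg <- read_sim_config("La", 1000L, setNames(1, lid),
                         arm_ratio = setNames(1, lid),
                         isomir_probs = data.table::data.table(
                           five = 0L, three = 0L, prob = 1),
                         error_rate = 0, singleton_noise_fraction = 0,
                         seed = 77L)
  sim <- simulate_library(refs, cfg)
  n_mat <- sum(sim$ground_truth$arm == "mature")
  ci <- qbinom(c(0.005, 0.995), 1000L, 0.5)
  expect_gte(n_mat, ci[1])
  expect_lte(n_mat, ci[2])
})

test_that("isomiR offset frequencies match their configured probabilities", {
  refs <- small_refs()
  lid <- refs$manifest[locus_class == "known_mirna", locus_id][2]
  iso <- data.table::data.table(five = c(0L, 0L, 1L),
                                three = c(0L, 1L, 0L),
                                prob = c(0.65, 0.30, 0.05))
  cfg <- read_sim_config("Li", 2000L, setNames(1, lid),
                         arm_ratio = setNames(1e9, lid),
                         isomir_probs = iso, error_rate = 0,
                         singleton_noise_fraction = 0, seed = 78L)
  sim <- simulate_library(refs, cfg)
  gt <- sim$ground_truth
  n3 <- sum(gt$three_offset != 0L)
  n5 <- sum(gt$five_offset != 0L)
  ci3 <- qbinom(c(0.005, 0.995), 2000L, 0.30)
  ci5 <- qbinom(c(0.005, 0.995), 2000L, 0.05)
  expect_gte(n3, ci3[1]); expect_lte(n3, ci3[2])
  expect_gte(n5, ci5[1]); expect_lte(n5, ci5[2])
})

test_that("default configuration biases heterogeneity to the 3' end", {
  iso <- default_isomir_probs()
  expect_equal(sum(iso$prob), 1)
  expect_gt(iso[three != 0L, sum(prob)], iso[five != 0L, sum(prob)])

  sims <- small_study()$sims
  gt <- data.table::rbindlist(lapply(sims, `[[`, "ground_truth"))
  gt <- gt[arm %in% c("mature", "star")]
  expect_gt(mean(gt$three_offset != 0L), mean(gt$five_offset != 0L))
})
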