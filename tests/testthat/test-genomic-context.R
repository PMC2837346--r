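mk_model <- function(strand = "+", exon_starts = c(1000L, 1500L),
                     exon_ends = c(1200L, 1800L), cds_start = 1100L,
                     cds_end = 1700L, id = "txT") {
  list(transcript_id = id, chrom = "chr1", strand = strand,
       tx_start = exon_starts[1], tx_end = exon_ends[length(exon_ends)],
       cds_start = cds_start, cds_end = cds_end,
       exon_starts = exon_starts, exon_ends = exon_ends)
}

test_that("UTRs derive from transcript and CDS coordinates on the fly", {
  # single-exon coding transcript, plus strand
  m <- mk_model(exon_starts = 100L, exon_ends = 900L,
                cds_start = 250L, cds_end = 700L)
  u <- derive_utrs(m)
  expect_equal(u$five_utr, cbind(start = 100L, end = 250L))
  expect_equal(u$three_utr, cbind(start = 700L, end = 900L))

  # CDS starting in exon 2: 5' UTR spans exon 1 plus the exon-2 prefix
  m2 <- mk_model(cds_start = 1600L, cds_end = 1750L)
  u2 <- derive_utrs(m2)
  expect_equal(u2$five_utr,
               cbind(start = c(1000L, 1500L), end = c(1200L, 1600L)))
  expect_equal(u2$three_utr, cbind(start = 1750L, end = 1800L))

  # minus strand: the 5' UTR lies at higher genomic coordinates
  m3 <- mk_model(strand = "-", cds_start = 1100L, cds_end = 1700L)
  u3 <- derive_utrs(m3)
  expect_equal(u3$five_utr, cbind(start = 1700L, end = 1800L))
  expect_equal(u3$three_utr, cbind(start = 1000L, end = 1100L))

  # non-coding: empty UTRs
  m4 <- mk_model(cds_start = NA_integer_, cds_end = NA_integer_)
  u4 <- derive_utrs(m4)
  expect_equal(nrow(u4$five_utr), 0L)
  expect_equal(nrow(u4$three_utr), 0L)

  # CDS outside the exon union: validation error
  m5 <- mk_model(cds_start = 1300L, cds_end = 1700L)
  expect_error(derive_utrs(m5), "CDS outside")
})

test_that("UTR, coding-exon and intron intervals partition the transcript", {
  for (m in small_refs()$gene_models) {
    u <- derive_utrs(m)
    pieces <- rbind(u$five_utr, u$three_utr)
    if (!is.na(m$cds_start)) {
      s <- pmax(m$exon_starts, m$cds_start)
      e <- pmin(m$exon_ends, m$cds_end)
      pieces <- rbind(pieces, cbind(start = s[s < e], end = e[s < e]))
    } else {
      pieces <- rbind(pieces, cbind(start = m$exon_starts, end = m$exon_ends))
    }
    k <- length(m$exon_starts)
    if (k > 1L) {
      pieces <- rbind(pieces, cbind(start = m$exon_ends[-k],
                                    end = m$exon_starts[-1]))
    }
    pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
    expect_equal(unname(pieces[1, 1]), m$tx_start)
    expect_equal(unname(pieces[nrow(pieces), 2]), m$tx_end)
    expect_true(all(pieces[-1, 1] == pieces[-nrow(pieces), 2]),
                info = m$transcript_id)
  }
})

test_that("location classification follows maximal overlap and precedence", {
  m <- mk_model()   # exons [1000,1200) [1500,1800), CDS [1100,1700)
  models <- list(txT = m)
  # fully inside the intron, ends off the splice sites
  expect_equal(classify_location(1250L, 1320L, "chr1", models)$feature,
               "intron")
  # overlapping coding exon by 10 and intron by 5: exon wins by overlap
  expect_equal(classify_location(1190L, 1205L, "chr1", models)$feature,
               "exon")
  # UTR overlap
  expect_equal(classify_location(1010L, 1040L, "chr1", models)$feature,
               "five_utr")
  # upstream within 1000 nt: promoter (plus strand)
  expect_equal(classify_location(500L, 560L, "chr1", models)$feature,
               "promoter")
  # minus-strand transcript: promoter is genomically right of tx_end
  mm <- mk_model(strand = "-", id = "txM")
  expect_equal(classify_location(1900L, 1960L, "chr1",
                                 list(txM = mm))$feature, "promoter")
  # far away: intergenic
  expect_equal(classify_location(5000L, 5060L, "chr1", models)$feature,
               "intergenic")
  expect_equal(classify_location(1250L, 1320L, "chr2", models)$feature,
               "intergenic")
})

test_that("mirtron typing anchors on splice sites", {
  # intron [1200,1500)
  expect_equal(classify_mirtron(1200L, 1500L, 1200L, 1500L), "typical")
  expect_equal(classify_mirtron(1200L, 1260L, 1200L, 1500L), "atypical")
  expect_equal(classify_mirtron(1440L, 1500L, 1200L, 1500L), "atypical")
  expect_equal(classify_mirtron(1250L, 1320L, 1200L, 1500L), "none")
  expect_equal(classify_mirtron(2000L, 2060L, 1200L, 1500L), "none")
  # tolerance relaxes the anchoring
  expect_equal(classify_mirtron(1201L, 1499L, 1200L, 1500L, tolerance = 1L),
               "typical")
  # splice-site anchored precursors outrank plain intronic in classification
  m <- mk_model()
  expect_equal(classify_location(1200L, 1500L, "chr1",
                                 list(txT = m))$feature, "mirtron_typical")
  expect_equal(classify_location(1200L, 1260L, "chr1",
                                 list(txT = m))$feature, "mirtron_atypical")
})

test_that("every planted locus context is recovered on the synthetic reference", {
  refs <- small_refs()
  man <- refs$manifest
  calls <- classify_locations(
    man[, .(id = locus_id, chrom, start = prec_start, end = prec_end)],
    refs$gene_models, promoter_len = refs$params$promoter_len)
  expected <- ifelse(man$locus_class == "mirtron_typical", "mirtron_typical",
              ifelse(man$locus_class == "mirtron_atypical",
                     "mirtron_atypical", man$context_label))
  expect_equal(calls$feature[match(man$locus_id, calls$id)], expected)
})

test_that("GFF3 round trip preserves gene models through rtracklayer", {
  refs <- small_refs()
  gff <- tempfile(fileext = ".gff3")
  write_gff3(refs$gene_models, gff)
  models <- read_gff3_models(gff)
  expect_setequal(names(models), names(refs$gene_models))
  for (nm in names(models)) {
    a <- models[[nm]]; b <- refs$gene_models[[nm]]
    expect_equal(a[c("strand", "tx_start", "tx_end", "cds_start",
                     "cds_end")],
                 b[c("strand", "tx_start", "tx_end", "cds_start",
                     "cds_end")])
    expect_equal(unname(a$exon_starts), unname(b$exon_starts))
    expect_equal(unname(a$exon_ends), unname(b$exon_ends))
  }
  unlink(gff)
})
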