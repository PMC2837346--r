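## Subtractive cascade and novel-candidate calling.
##
## Filtered tags are classified in a fixed order — known precursors first,
## then the transcriptome (degraded mRNA), then the genome — with a tag
## matching an earlier reference never reaching a later one. Genome-residual
## tags are merged into candidate loci, gated by the hairpin fold and the
## SCFG classifier, and post-filtered on rRNA identity, exon overhang,
## mature length and total abundance before naming.

#' Subtractive classification of tags against the reference cascade
#'
#' @param tags filtered tag table for one library (`sequence`, `count`,
#'   `library_id`).
#' @param known_index `ref_index` over known precursor sequences (searched
#'   sense strand only).
#' @param transcriptome_index `ref_index` over spliced transcripts (sense
#'   strand only).
#' @param genome_index `ref_index` over the genome (both strands).
#' @param max_hits multimapper cap for the genome search.
#' @return list: `tags` (input plus `bucket` column: known_precursor /
#'   transcriptome / genome_residual / unmatched, and `multimapped`),
#'   `genome_hits` (hits of genome_residual tags), `summary` (one row of
#'   bucket sizes).
#' @export
subtractive_cascade <- function(tags, known_index, transcriptome_index,
                                genome_index, max_hits = 10L) {
  tags <- data.table::copy(tags)
  seqs <- unique(tags$sequence)
  bucket <- setNames(rep("unmatched", length(seqs)), seqs)
  multi <- setNames(rep(FALSE, length(seqs)), seqs)

  kn <- find_perfect_matches_many(seqs, known_index,
                                  search_minus_strand = FALSE,
                                  max_hits = max_hits)
  bucket[kn$per_tag[n_hits > 0L, tag]] <- "known_precursor"

  rest <- seqs[bucket == "unmatched"]
  if (length(rest)) {
    tx <- find_perfect_matches_many(rest, transcriptome_index,
                                    search_minus_strand = FALSE,
                                    max_hits = max_hits)
    bucket[tx$per_tag[n_hits > 0L, tag]] <- "transcriptome"
  }
  rest <- seqs[bucket == "unmatched"]
  genome_hits <- data.table::data.table(tag = character(),
                                        ref_name = character(),
                                        start = integer(), end = integer(),
                                        strand = character())
  if (length(rest)) {
    gn <- find_perfect_matches_many(rest, genome_index,
                                    search_minus_strand = TRUE,
                                    max_hits = max_hits)
    hit_tags <- gn$per_tag[n_hits > 0L, tag]
    bucket[hit_tags] <- "genome_residual"
    multi[gn$per_tag[multimapped == TRUE, tag]] <- TRUE
    genome_hits <- gn$hits
  }
  tags[, bucket := bucket[sequence]]
  tags[, multimapped := multi[sequence]]
  summary <- tags[, .(n_tags = .N, n_reads = sum(count)),
                  by = .(library_id, bucket)]
  list(tags = tags[], genome_hits = genome_hits, summary = summary[])
}

# merge same-strand overlapping tag hits into candidate loci
.merge_loci <- function(hits) {
  loci <- list()
  for (key in split(seq_len(nrow(hits)),
                    paste(hits$ref_name, hits$strand))) {
    h <- hits[key]
    ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    h[, locus := S4Vectors::subjectHits(ov)]
    for (l in unique(h$locus)) {
      hh <- h[locus == l]
      loci[[length(loci) + 1L]] <- list(
        chrom = hh$ref_name[1], strand = hh$strand[1],
        start = min(hh$start), end = max(hh$end), hits = hh)
    }
  }
  loci
}

#' Call candidate miRNA loci from genome-residual tags
#'
#' Residual tags from all libraries are pooled; multimapped tags are
#' excluded. Same-strand tags whose genomic hits overlap by at least 1 nt
#' merge into one locus (isomiRs must not spawn several candidates); the
#' most abundant tag defines the mature sequence. Each locus is assessed
#' for hairpin potential in its two candidate windows (see
#' [extract_candidate_windows()] and [assess_hairpin_window()]) and scored
#' by the SCFG classifier on the excised putative precursor.
#'
#' @param residual_tags pooled tag table restricted to genome-residual,
#'   non-multimapped tags (`sequence`, `count`, `library_id`).
#' @param genome_hits hit table for those tags (from
#'   [subtractive_cascade()]).
#' @param genome named chromosome sequences.
#' @param grammar trained `scfg_grammar`.
#' @param cutoff normalized-score cutoff from [calibrate_cutoff()].
#' @param fold_criteria hairpin criteria, see [is_hairpin()].
#' @param flank_long,flank_short window flanks, see
#'   [extract_candidate_windows()].
#' @return list: `candidates` (one row per locus with flags and status
#'   "raw"), `counts` (candidate x library read counts).
#' @export
call_candidates <- function(residual_tags, genome_hits, genome, grammar,
                            cutoff,
                            fold_criteria = list(min_pairs = 16L,
                                                 min_paired_fraction = 0.5,
                                                 max_terminal_loops = 1L),
                            flank_long = 70L, flank_short = 20L) {
  empty <- list(candidates = data.table::data.table(),
                counts = data.table::data.table())
  if (!nrow(residual_tags) || !nrow(genome_hits)) return(empty)
  tag_totals <- residual_tags[, .(total = sum(count)), by = sequence]
  hits <- merge(genome_hits, tag_totals, by.x = "tag", by.y = "sequence")
  if (!nrow(hits)) return(empty)
  loci <- .merge_loci(hits)

  cand_rows <- list()
  count_rows <- list()
  for (i in seq_along(loci)) {
    lc <- loci[[i]]
    hh <- lc$hits
    best <- hh[order(-total, tag)][1]
    mature_seq <- best$tag
    hit <- list(ref_name = best$ref_name, start = best$start,
                end = best$end, strand = best$strand)
    wins <- extract_candidate_windows(genome, hit, flank_long, flank_short)
    hairpin_ok <- FALSE
    prec <- NULL
    for (wr in seq_len(nrow(wins))) {
      w <- wins[wr]
      a <- assess_hairpin_window(w$seq, w$tag_local_start, w$tag_local_end,
                                 fold_criteria)
      if (is.null(prec) && !is.null(a$span)) prec <- list(w = w, a = a)
      if (a$pass) {
        hairpin_ok <- TRUE
        prec <- list(w = w, a = a)
        break
      }
    }
    if (!is.null(prec) && !is.null(prec$a$span)) {
      w <- prec$w; sp <- prec$a$span
      if (w$strand == "+") {
        ps <- w$start + sp[1]; pe <- w$start + sp[2]
      } else {
        ps <- w$end - sp[2]; pe <- w$end - sp[1]
      }
      prec_seq <- prec$a$precursor_seq
    } else {
      ps <- lc$start; pe <- lc$end
      prec_seq <- mature_seq
    }
    sc <- inside_log_probability(grammar, prec_seq)
    scfg_ok <- is.finite(sc$normalized_score) &&
      sc$normalized_score > cutoff

    member_tags <- unique(hh$tag)
    lib_counts <- residual_tags[sequence %in% member_tags,
                                .(count = sum(count)), by = library_id]
    cand_rows[[length(cand_rows) + 1L]] <- data.table::data.table(
      locus = i, chrom = lc$chrom, strand = lc$strand,
      start = lc$start, end = lc$end,
      mature_seq = mature_seq,
      mature_start = best$start, mature_end = best$end,
      prec_start = ps, prec_end = pe,
      total_count = sum(lib_counts$count),
      n_libraries = nrow(lib_counts),
      hairpin_ok = hairpin_ok, scfg_ok = scfg_ok,
      scfg_score = sc$normalized_score,
      status = "raw")
    count_rows[[length(count_rows) + 1L]] <-
      data.table::data.table(locus = i, lib_counts)
  }
  list(candidates = data.table::rbindlist(cand_rows),
       counts = data.table::rbindlist(count_rows))
}

#' Apply the post-filters and assign candidate status and names
#'
#' Removal rules: mature sequence perfectly matching the rRNA reference
#' (likely rRNA degradation), mature overlapping an annotated exon by more
#' than `exon_overhang_max` nt (strand-agnostic, any transcript), mature of
#' exactly `excluded_length` nt. Candidates surviving all removals get
#' status "candidate", and "named" when their summed count across libraries
#' exceeds `min_total_reads`. Names (`prefix_n`) are assigned in discovery
#' order: descending total count, then genomic coordinate.
#'
#' @param called result of [call_candidates()].
#' @param rrna_index `ref_index` over the rRNA reference (searched both
#'   strands).
#' @param gene_models list of gene models (for exon overlap).
#' @param min_total_reads naming threshold: total count must be strictly
#'   greater.
#' @param exon_overhang_max maximum tolerated exon overlap, nt.
#' @param excluded_length mature length excluded outright.
#' @param prefix candidate name prefix.
#' @return `called` with `candidates` gaining `rrna_hit`,
#'   `exon_overhang_nt`, `length_ok`, `abundance_ok`, `status`,
#'   `candidate_id`; counts gain `candidate_id`.
#' @export
apply_post_filters <- function(called, rrna_index, gene_models,
                               min_total_reads = 5L, exon_overhang_max = 2L,
                               excluded_length = 16L, prefix = "MELmiRNA") {
  cand <- called$candidates
  if (!nrow(cand)) return(called)
  cand <- data.table::copy(cand)

  rr <- find_perfect_matches_many(cand$mature_seq, rrna_index,
                                  search_minus_strand = TRUE, max_hits = 50L)
  rr_hit <- setNames(rr$per_tag$n_hits > 0L, rr$per_tag$tag)
  cand[, rrna_hit := unname(rr_hit[mature_seq])]

  exons <- data.table::rbindlist(lapply(gene_models, function(m)
    data.table::data.table(chrom = m$chrom, start = m$exon_starts,
                           end = m$exon_ends)))
  cand[, exon_overhang_nt := vapply(seq_len(.N), function(r) {
    ex <- exons[chrom == cand$chrom[r]]
    if (!nrow(ex)) return(0L)
    as.integer(max(.overlap_width(ex$start, ex$end,
                                  cand$mature_start[r], cand$mature_end[r])))
  }, integer(1))]
  cand[, length_ok := nchar(mature_seq) != excluded_length]
  cand[, abundance_ok := total_count > min_total_reads]

  cand[, status := "candidate"]
  cand[hairpin_ok == FALSE, status := "filtered_out:no_hairpin"]
  cand[hairpin_ok == TRUE & scfg_ok == FALSE, status := "filtered_out:scfg"]
  cand[status == "candidate" & rrna_hit == TRUE,
       status := "filtered_out:rrna"]
  cand[status == "candidate" & exon_overhang_nt > exon_overhang_max,
       status := "filtered_out:exon_overhang"]
  cand[status == "candidate" & length_ok == FALSE,
       status := "filtered_out:length16"]
  cand[status == "candidate" & abundance_ok == TRUE, status := "named"]

  data.table::setorder(cand, -total_count, chrom, start)
  cand[, candidate_id := sprintf("%s_%d", prefix, .I)]
  data.table::setcolorder(cand, "candidate_id")
  counts <- merge(called$counts, cand[, .(locus, candidate_id)], by = "locus")
  list(candidates = cand[], counts = counts[])
}

#' Cross-library tally of surviving candidates
#'
#' For each library: candidates present only there ("unique"), candidates
#' present there and in at least one other library ("shared"), and their sum
#' ("total"); plus the list present in all libraries.
#'
#' @param candidates candidate table after [apply_post_filters()].
#' @param counts candidate x library count table.
#' @param statuses candidate statuses included in the tally.
#' @param libraries optional library ordering for the output.
#' @return list: `table` (data.table: `library_id`, `unique`, `shared`,
#'   `total`), `present_in_all` (candidate ids).
#' @export
cross_library_tally <- function(candidates, counts,
                                statuses = c("candidate", "named"),
                                libraries = NULL) {
  keep <- candidates[status %in% statuses, candidate_id]
  cc <- counts[candidate_id %in% keep & count > 0L]
  if (is.null(libraries)) libraries <- sort(unique(cc$library_id))
  occ <- cc[, .(n_libs = data.table::uniqueN(library_id)), by = candidate_id]
  cc <- merge(cc, occ, by = "candidate_id")
  tab <- data.table::rbindlist(lapply(libraries, function(l) {
    here <- cc[library_id == l]
    data.table::data.table(library_id = l,
                           unique = sum(here$n_libs == 1L),
                           shared = sum(here$n_libs >= 2L),
                           total = nrow(here))
  }))
  in_all <- occ[n_libs == length(libraries), candidate_id]
  list(table = tab[], present_in_all = sort(in_all))
}

#' Run the full novel-miRNA discovery stage over many libraries
#'
#' Builds the reference indexes, trains the SCFG on the folded known
#' precursors, calibrates its cutoff against dinucleotide-shuffled
#' negatives, runs the subtractive cascade per library, pools the residual
#' tags and calls, filters and names candidates.
#'
#' @param tag_tables named list (by library) of filtered tag tables.
#' @param refs a `reference_set`.
#' @param target_specificity SCFG cutoff calibration target.
#' @param shuffles_per_hairpin negatives generated per training hairpin.
#' @param seed RNG seed for shuffling.
#' @param ... passed to [apply_post_filters()].
#' @return list: `cascade` (per-library cascade results), `cascade_summary`,
#'   `candidates`, `counts`, `tally`, `grammar`, `cutoff`.
#' @export
discover_novel <- function(tag_tables, refs, target_specificity = 0.95,
                           shuffles_per_hairpin = 3L, seed = 1L, ...) {
  known_index <- build_index(refs$precursors)
  tx_index <- build_index(refs$transcriptome)
  genome_index <- build_index(refs$genome)
  rrna_index <- build_index(refs$rrna)

  folds <- lapply(refs$precursors, fold_sequence)
  train <- data.table::data.table(
    id = names(folds),
    sequence = vapply(folds, `[[`, character(1), "sequence"),
    dot_bracket = vapply(folds, `[[`, character(1), "dot_bracket"))
  grammar <- train_grammar(train)
  negatives <- withr::with_seed(seed, {
    unlist(lapply(train$sequence, function(s)
      replicate(shuffles_per_hairpin, dinucleotide_shuffle(s))))
  })
  cal <- calibrate_cutoff(grammar, train$sequence, negatives,
                          target_specificity)

  cascades <- lapply(tag_tables, function(tt)
    subtractive_cascade(tt, known_index, tx_index, genome_index))
  residual <- data.table::rbindlist(lapply(cascades, function(cs)
    cs$tags[bucket == "genome_residual" & multimapped == FALSE]))
  genome_hits <- unique(data.table::rbindlist(
    lapply(cascades, function(cs)
      cs$genome_hits[tag %in% residual$sequence])))

  called <- call_candidates(residual, genome_hits, refs$genome, grammar,
                            cal$cutoff)
  filtered <- apply_post_filters(called, rrna_index, refs$gene_models, ...)
  tally <- if (nrow(filtered$candidates)) {
    cross_library_tally(filtered$candidates, filtered$counts,
                        libraries = names(tag_tables))
  } else NULL

  list(cascade = cascades,
       cascade_summary = data.table::rbindlist(
         lapply(cascades, `[[`, "summary")),
       candidates = filtered$candidates, counts = filtered$counts,
       tally = tally, grammar = grammar, cutoff = cal$cutoff,
       calibration = cal[c("cutoff", "sensitivity", "specificity")])
}
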