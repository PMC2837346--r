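## Synthetic reference + read-set generator.
##
## Builds a toy genome with gene models, plants miRNA precursors (known,
## novel, mirtron), rRNA loci and mRNA-decoy windows into defined genomic
## contexts, and simulates small RNA libraries from them with isomiR end
## heterogeneity, mature:star arm ratios, substitution errors, adapter
## read-through and singleton noise — the statistical structure the analysis
## pipeline assumes, with full per-read ground truth.

# Construct one fold-verified precursor: 20-24 nt 5' arm, 8-15 nt loop drawn
# from {A,C} (A/C cannot base-pair with each other, keeping the terminal loop
# unpaired), 3' arm = reverse complement of the 5' arm with 1-2 mismatches.
# The mismatches sit in the middle third of the arm so that every arm-derived
# tag (including end-shifted isomiRs) covers at least one of them — a perfect
# reverse-complement stem would otherwise let each arm tag also match the
# opposite arm on the opposite strand. Rejection-sampled until the fold
# passes the hairpin criteria.
.make_precursor <- function(criteria = list(min_pairs = 16L,
                                            min_paired_fraction = 0.5,
                                            max_terminal_loops = 1L),
                            max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    arm_len <- sample(20:24, 1L)
    loop_len <- sample(8:15, 1L)
    arm5 <- sample(BASES, arm_len, replace = TRUE)
    loop <- sample(c("A", "C"), loop_len, replace = TRUE)
    arm3 <- strsplit(revcomp(paste(arm5, collapse = "")), "")[[1]]
    n_mm <- sample(1:2, 1L)
    mid <- seq.int(ceiling(arm_len / 3), floor(2 * arm_len / 3))
    at <- sample(mid, n_mm)
    for (p in at) arm3[p] <- sample(setdiff(BASES, arm3[p]), 1L)
    seq <- paste(c(arm5, loop, arm3), collapse = "")
    if (is_hairpin(fold_sequence(seq), criteria)) {
      mature_arm <- sample(c("5p", "3p"), 1L)
      plen <- arm_len * 2L + loop_len
      if (mature_arm == "5p") {
        m <- c(0L, arm_len); st <- c(arm_len + loop_len, plen)
      } else {
        m <- c(arm_len + loop_len, plen); st <- c(0L, arm_len)
      }
      return(list(seq = seq, length = plen,
                  mature_local = m, star_local = st, mature_arm = mature_arm))
    }
  }
  stop("failed to construct a fold-verified precursor after ",
       max_tries, " tries")
}

.overlaps_any <- function(start, end, occupied) {
  if (!nrow(occupied)) return(FALSE)
  any(occupied$start < end & start < occupied$end)
}

# local (precursor) half-open interval -> genomic, strand aware
.local_to_genomic <- function(prec_start, prec_end, strand, local) {
  if (strand == "+") c(prec_start + local[1], prec_start + local[2])
  else c(prec_end - local[2], prec_end - local[1])
}

# splice a planted sequence into the genome string (strand aware)
.plant <- function(genome_seq, start, end, seq, strand) {
  if (strand == "-") seq <- revcomp(seq)
  paste0(substr(genome_seq, 1L, start), seq,
         substr(genome_seq, end + 1L, nchar(genome_seq)))
}

# draw a default mature:star ratio spanning the classes seen in real
# libraries: mostly mature-dominant, some equivalent, some star-dominant
.draw_arm_ratio <- function() {
  cls <- sample(c("star_dominant", "equivalent", "mature_dominant"), 1L,
                prob = c(0.15, 0.15, 0.70))
  switch(cls,
         star_dominant = runif(1, 0.05, 0.6),
         equivalent = runif(1, 0.8, 2.0),
         mature_dominant = exp(runif(1, log(3), log(5000))))
}

#' Default isomiR end-offset probability table
#'
#' 3'-end heterogeneity (total mass 0.30) dominates 5'-end heterogeneity
#' (0.08), matching the qualitative behaviour of real small RNA libraries.
#'
#' @return data.table with columns `five`, `three`, `prob` (sums to 1).
#' @export
default_isomir_probs <- function() {
  data.table::data.table(
    five = c(0L, 0L, 0L, 0L, 0L, 1L, -1L),
    three = c(0L, 1L, -1L, 2L, -2L, 0L, 0L),
    prob = c(0.62, 0.13, 0.09, 0.05, 0.03, 0.04, 0.04))
}

#' Build a synthetic reference set with planted loci
#'
#' Generates a uniform-composition ACGT genome, lays out `n_genes` gene
#' models (3-4 exons; the last gene is non-coding), and plants loci of the
#' requested classes into defined genomic contexts: known and novel miRNA
#' precursors (fold-verified stem-loops), typical mirtrons (precursor ends
#' exactly at both intron boundaries), atypical mirtrons (exactly one end at
#' an intron boundary), rRNA loci and mRNA-decoy windows inside coding
#' exons. Known precursors get a registry with mature/star coordinates.
#'
#' @param genome_length genome size in nt (>= 10000).
#' @param n_genes number of gene models.
#' @param n_planted named list of per-class locus counts; classes
#'   `known_mirna`, `novel_mirna`, `mirtron_typical`, `mirtron_atypical`,
#'   `rrna`, `mrna_decoy` (missing classes default to 0).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param promoter_len promoter window length upstream of the TSS.
#' @param chrom chromosome name.
#' @return list of class `reference_set`: `genome` (named character),
#'   `gene_models`, `manifest` (planted-locus table), `registry` (known
#'   miRNAs), `transcriptome`, `rrna`, `precursors` (known precursor FASTA
#'   set) and `params`.
#' @export
build_reference_set <- function(genome_length = 120000L, n_genes = 12L,
                                n_planted = list(known_mirna = 30L,
                                                 novel_mirna = 16L,
                                                 mirtron_typical = 2L,
                                                 mirtron_atypical = 2L,
                                                 rrna = 3L,
                                                 mrna_decoy = 5L),
                                seed = 1L, promoter_len = 1000L,
                                chrom = "chr1") {
  stopifnot(genome_length >= 10000L)
  classes <- c("known_mirna", "novel_mirna", "mirtron_typical",
               "mirtron_atypical", "rrna", "mrna_decoy")
  np <- setNames(rep(0L, length(classes)), classes)
  np[names(n_planted)] <- as.integer(unlist(n_planted))
  if (np[["mirtron_typical"]] + np[["mirtron_atypical"]] > n_genes) {
    stop("generation error (mirtron): more mirtrons requested than genes")
  }
  withr::with_seed(seed, {
    ## mirtron precursors are generated first: their introns are sized to fit
    mt_typ <- replicate(np[["mirtron_typical"]], .make_precursor(),
                        simplify = FALSE)
    mt_atyp <- replicate(np[["mirtron_atypical"]], .make_precursor(),
                         simplify = FALSE)

    ## ---- gene layout ----
    models <- list()
    mirtron_slots <- list()   # locus_id -> list(gene, intron interval, type)
    cursor <- 1200L
    for (g in seq_len(n_genes)) {
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(3:4, 1L)
      ex_lens <- sample(120:250, n_ex, replace = TRUE)
      in_lens <- sample(150:400, n_ex - 1L, replace = TRUE)
      typ_idx <- g
      if (typ_idx <= length(mt_typ)) {
        slot <- sample(n_ex - 1L, 1L)
        in_lens[slot] <- mt_typ[[typ_idx]]$length
        mirtron_slots[[length(mirtron_slots) + 1L]] <-
          list(type = "typical", gene = g, slot = slot, prec = mt_typ[[typ_idx]])
      } else if (typ_idx - length(mt_typ) <= length(mt_atyp)) {
        k <- typ_idx - length(mt_typ)
        slot <- sample(n_ex - 1L, 1L)
        in_lens[slot] <- mt_atyp[[k]]$length + sample(40:120, 1L)
        mirtron_slots[[length(mirtron_slots) + 1L]] <-
          list(type = "atypical", gene = g, slot = slot, prec = mt_atyp[[k]])
      }
      ex_starts <- integer(n_ex)
      ex_ends <- integer(n_ex)
      pos <- cursor
      for (e in seq_len(n_ex)) {
        ex_starts[e] <- pos
        ex_ends[e] <- pos + ex_lens[e]
        pos <- ex_ends[e] + if (e < n_ex) in_lens[e] else 0L
      }
      coding <- g < n_genes   # last gene is non-coding
      models[[g]] <- list(
        transcript_id = sprintf("tx%02d", g),
        chrom = chrom, strand = strand,
        tx_start = ex_starts[1], tx_end = ex_ends[n_ex],
        cds_start = if (coding) ex_starts[1] + sample(20:60, 1L) else NA_integer_,
        cds_end = if (coding) ex_ends[n_ex] - sample(20:60, 1L) else NA_integer_,
        exon_starts = ex_starts, exon_ends = ex_ends)
      cursor <- ex_ends[n_ex] + sample(1100:1600, 1L)
    }
    names(models) <- vapply(models, `[[`, character(1), "transcript_id")
    if (cursor + 500L > genome_length) {
      stop("generation error (gene layout): genome_length too small for ",
           n_genes, " genes")
    }

    genome_seq <- paste(sample(BASES, genome_length, replace = TRUE),
                        collapse = "")

    ## intergenic free space: outside genes and promoter windows
    spans <- data.table::rbindlist(lapply(models, function(m) {
      prom <- if (m$strand == "+") {
        c(m$tx_start - promoter_len, m$tx_start)
      } else c(m$tx_end, m$tx_end + promoter_len)
      data.table::data.table(start = c(m$tx_start, prom[1]),
                             end = c(m$tx_end, prom[2]))
    }))
    blocked <- data.table::copy(spans)
    free_from <- max(spans$end) + 200L

    occupied <- data.table::data.table(start = integer(), end = integer())
    manifest_rows <- list()

    add_locus <- function(locus_id, locus_class, strand, ps, pe, prec,
                          context, host = NA_character_, arm_ratio = NA_real_) {
      genome_seq <<- .plant(genome_seq, ps, pe, prec$seq, strand)
      occupied <<- rbind(occupied,
                         data.table::data.table(start = ps, end = pe))
      mg <- .local_to_genomic(ps, pe, strand, prec$mature_local)
      sg <- if (is.null(prec$star_local)) c(NA_integer_, NA_integer_)
            else .local_to_genomic(ps, pe, strand, prec$star_local)
      sl <- if (is.null(prec$star_local)) c(NA_integer_, NA_integer_)
            else prec$star_local
      manifest_rows[[length(manifest_rows) + 1L]] <<- data.table::data.table(
        locus_id = locus_id, locus_class = locus_class, chrom = chrom,
        strand = strand, prec_start = ps, prec_end = pe,
        mature_start = mg[1], mature_end = mg[2],
        star_start = sg[1], star_end = sg[2],
        context_label = context, host_transcript = host,
        mature_local_start = prec$mature_local[1],
        mature_local_end = prec$mature_local[2],
        star_local_start = sl[1], star_local_end = sl[2],
        arm_ratio = arm_ratio,
        precursor_seq = prec$seq,
        mature_seq = substr(prec$seq, prec$mature_local[1] + 1L,
                            prec$mature_local[2]),
        star_seq = if (is.na(sl[1])) NA_character_
                   else substr(prec$seq, sl[1] + 1L, sl[2]))
    }

    ## ---- mirtrons ----
    for (ms in mirtron_slots) {
      m <- models[[ms$gene]]
      in_start <- m$exon_ends[ms$slot]
      in_end <- m$exon_starts[ms$slot + 1L]
      prec <- ms$prec
      if (ms$type == "typical") {
        ps <- in_start; pe <- in_end
      } else {
        if (sample(c(TRUE, FALSE), 1L)) {
          ps <- in_start; pe <- in_start + prec$length
        } else {
          ps <- in_end - prec$length; pe <- in_end
        }
      }
      lid <- sprintf("%s-%02d",
                     if (ms$type == "typical") "mtT" else "mtA", ms$gene)
      add_locus(lid, paste0("mirtron_", ms$type), m$strand, ps, pe, prec,
                context = "intron", host = m$transcript_id,
                arm_ratio = .draw_arm_ratio())
    }

    ## ---- placement helpers ----
    coding_models <- Filter(function(m) !is.na(m$cds_start), models)
    place_with_retry <- function(gen, locus_class, tries = 60L) {
      for (t in seq_len(tries)) {
        r <- gen()
        if (!is.null(r) && !.overlaps_any(r$ps, r$pe, occupied)) return(r)
      }
      stop("generation error (", locus_class, "): no placement found")
    }
    gen_exon <- function(plen) function() {
      m <- coding_models[[sample(length(coding_models), 1L)]]
      cand <- which(pmin(m$exon_ends, m$cds_end) -
                    pmax(m$exon_starts, m$cds_start) >= plen + 6L)
      if (!length(cand)) return(NULL)
      e <- if (length(cand) == 1L) cand else sample(cand, 1L)
      lo <- max(m$exon_starts[e], m$cds_start) + 3L
      hi <- min(m$exon_ends[e], m$cds_end) - 3L - plen
      if (hi < lo) return(NULL)
      ps <- sample(lo:hi, 1L)
      list(ps = ps, pe = ps + plen, strand = m$strand, host = m$transcript_id)
    }
    gen_intron <- function(plen) function() {
      m <- models[[sample(length(models), 1L)]]
      if (length(m$exon_starts) < 2L) return(NULL)
      k <- sample(length(m$exon_starts) - 1L, 1L)
      in_start <- m$exon_ends[k]; in_end <- m$exon_starts[k + 1L]
      lo <- in_start + 3L; hi <- in_end - 3L - plen
      if (hi < lo) return(NULL)
      ps <- sample(lo:hi, 1L)
      list(ps = ps, pe = ps + plen, strand = m$strand, host = m$transcript_id)
    }
    gen_promoter <- function(plen) function() {
      m <- models[[sample(length(models), 1L)]]
      win <- if (m$strand == "+") {
        c(m$tx_start - promoter_len, m$tx_start)
      } else c(m$tx_end, m$tx_end + promoter_len)
      lo <- win[1] + 5L; hi <- win[2] - 5L - plen
      if (hi < lo || lo < 0L) return(NULL)
      ps <- sample(lo:hi, 1L)
      list(ps = ps, pe = ps + plen, strand = sample(c("+", "-"), 1L),
           host = m$transcript_id)
    }
    gen_intergenic <- function(plen) function() {
      lo <- free_from; hi <- genome_length - 200L - plen
      if (hi < lo) return(NULL)
      ps <- sample(lo:hi, 1L)
      list(ps = ps, pe = ps + plen, strand = sample(c("+", "-"), 1L),
           host = NA_character_)
    }

    context_plan <- function(n, weights) {
      ctx <- rep(names(weights), round(n * weights / sum(weights)))
      if (length(ctx) < n) ctx <- c(ctx, rep("intergenic", n - length(ctx)))
      sample(ctx[seq_len(n)])
    }

    plant_mirna_set <- function(n, prefix, class, contexts) {
      for (i in seq_len(n)) {
        prec <- .make_precursor()
        ctx <- contexts[i]
        gen <- switch(ctx,
                      exon = gen_exon(prec$length),
                      intron = gen_intron(prec$length),
                      promoter = gen_promoter(prec$length),
                      intergenic = gen_intergenic(prec$length))
        r <- place_with_retry(gen, class)
        add_locus(sprintf("%s-%03d", prefix, i), class, r$strand,
                  r$ps, r$pe, prec, context = ctx, host = r$host,
                  arm_ratio = .draw_arm_ratio())
      }
    }

    plant_mirna_set(np[["known_mirna"]], "mir", "known_mirna",
                    context_plan(np[["known_mirna"]],
                                 c(exon = 0.17, intron = 0.23,
                                   promoter = 0.10, intergenic = 0.50)))
    plant_mirna_set(np[["novel_mirna"]], "nov", "novel_mirna",
                    context_plan(np[["novel_mirna"]],
                                 c(intron = 0.31, promoter = 0.19,
                                   intergenic = 0.50)))

    ## ---- rRNA loci (intergenic, not hairpins) ----
    for (i in seq_len(np[["rrna"]])) {
      plen <- 120L
      r <- place_with_retry(gen_intergenic(plen), "rrna")
      sq <- substr(genome_seq, r$ps + 1L, r$pe)
      if (r$strand == "-") sq <- revcomp(sq)
      ms <- sample(10:(plen - 32L), 1L)
      add_locus(sprintf("rrna-%02d", i), "rrna", r$strand, r$ps, r$pe,
                list(seq = sq, length = plen,
                     mature_local = c(ms, ms + 22L), star_local = NULL),
                context = "intergenic", host = NA_character_)
    }

    ## ---- mRNA decoy windows inside coding exons ----
    for (i in seq_len(np[["mrna_decoy"]])) {
      plen <- 60L
      r <- place_with_retry(gen_exon(plen), "mrna_decoy")
      sq <- substr(genome_seq, r$ps + 1L, r$pe)
      if (r$strand == "-") sq <- revcomp(sq)
      ms <- sample(5:(plen - 27L), 1L)
      add_locus(sprintf("decoy-%02d", i), "mrna_decoy", r$strand, r$ps, r$pe,
                list(seq = sq, length = plen,
                     mature_local = c(ms, ms + 22L), star_local = NULL),
                context = "exon", host = r$host)
    }

    manifest <- data.table::rbindlist(manifest_rows)
    if (!nrow(manifest)) {
      manifest <- data.table::data.table(
        locus_id = character(), locus_class = character(),
        chrom = character(), strand = character(),
        prec_start = integer(), prec_end = integer(),
        mature_start = integer(), mature_end = integer(),
        star_start = integer(), star_end = integer(),
        context_label = character(), host_transcript = character(),
        mature_local_start = integer(), mature_local_end = integer(),
        star_local_start = integer(), star_local_end = integer(),
        arm_ratio = numeric(), precursor_seq = character(),
        mature_seq = character(), star_seq = character())
    }

    ## ---- derived references ----
    genome <- setNames(genome_seq, chrom)
    transcriptome <- vapply(models, function(m) {
      sq <- paste(substring(genome_seq, m$exon_starts + 1L, m$exon_ends),
                  collapse = "")
      if (m$strand == "-") revcomp(sq) else sq
    }, character(1))
    rrna_ref <- if (nrow(manifest[locus_class == "rrna"])) {
      with(manifest[locus_class == "rrna"],
           setNames(precursor_seq, locus_id))
    } else setNames(character(0), character(0))
    known <- manifest[locus_class == "known_mirna"]
    registry <- known[, .(mir_id = locus_id, precursor_seq,
                          mature_start = mature_local_start,
                          mature_end = mature_local_end,
                          star_start = star_local_start,
                          star_end = star_local_end)]
    precursors <- setNames(registry$precursor_seq, registry$mir_id)

    structure(list(genome = genome, gene_models = models,
                   manifest = manifest, registry = registry,
                   transcriptome = transcriptome, rrna = rrna_ref,
                   precursors = precursors,
                   params = list(genome_length = genome_length,
                                 n_genes = n_genes, n_planted = as.list(np),
                                 seed = seed, promoter_len = promoter_len)),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", nchar(x$genome[[1]]), "nt genome,",
      length(x$gene_models), "genes,", nrow(x$manifest), "planted loci\n")
  invisible(x)
}

#' Write a reference set to disk
#'
#' Emits genome.fa, transcriptome.fa, rrna.fa, precursors.fa, genes.gff3,
#' registry.tsv and manifest.tsv into `outdir`. Output is byte-deterministic
#' for a given reference set.
#'
#' @param refs a `reference_set`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_reference_set <- function(refs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(refs$genome, file.path(outdir, "genome.fa"))
  write_fasta(refs$transcriptome, file.path(outdir, "transcriptome.fa"))
  if (length(refs$rrna)) write_fasta(refs$rrna, file.path(outdir, "rrna.fa"))
  if (length(refs$precursors)) {
    write_fasta(refs$precursors, file.path(outdir, "precursors.fa"))
  }
  write_gff3(refs$gene_models, file.path(outdir, "genes.gff3"))
  write_registry(refs$registry, file.path(outdir, "registry.tsv"))
  write_manifest(refs$manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

#' Construct a read-simulation configuration
#'
#' @param library_id library name.
#' @param n_reads number of reads to simulate.
#' @param locus_weights named nonnegative sampling weights over planted
#'   locus ids.
#' @param arm_ratio named mature:star expected ratios (defaults to the
#'   manifest's per-locus ratios when simulating).
#' @param isomir_probs probability table over (5', 3') end offsets; must sum
#'   to 1.
#' @param error_rate per-base substitution probability.
#' @param adapter 3' adapter sequence (read-through is simulated).
#' @param singleton_noise_fraction fraction of uniform-random never-repeated
#'   reads.
#' @param read_length sequencing read length.
#' @param seed RNG seed for this library.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(library_id, n_reads, locus_weights,
                            arm_ratio = NULL,
                            isomir_probs = default_isomir_probs(),
                            error_rate = 0.001,
                            adapter = "TCGTATGCCGTCTTCTGCTTG",
                            singleton_noise_fraction = 0.05,
                            read_length = 36L, seed = 1L) {
  isomir_probs <- data.table::as.data.table(isomir_probs)
  if (abs(sum(isomir_probs$prob) - 1) > 1e-9) {
    stop("isomir_probs must sum to 1")
  }
  if (n_reads > 0L && sum(locus_weights) <= 0) {
    stop("locus weights must sum > 0 when n_reads > 0")
  }
  structure(list(library_id = library_id, n_reads = as.integer(n_reads),
                 locus_weights = locus_weights, arm_ratio = arm_ratio,
                 isomir_probs = isomir_probs, error_rate = error_rate,
                 adapter = toupper(adapter),
                 singleton_noise_fraction = singleton_noise_fraction,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate one small RNA library
#'
#' Each non-noise read is a mature/star/decoy arm subsequence with sampled
#' 5'/3' end offsets and per-base substitution errors; the 3' adapter is
#' appended and the read truncated to `read_length` (adapter read-through).
#' Noise reads are uniform-random 18-26-mers. Identical seeds give identical
#' reads.
#'
#' @param refs a `reference_set` from [build_reference_set()].
#' @param config a `read_sim_config`.
#' @return list: `reads` (named character vector), `ground_truth`
#'   (data.table: `read_id`, `locus_id` (".noise" for noise), `arm`,
#'   `five_offset`, `three_offset`), `expected_counts` (per-locus expected
#'   read / mature / star counts) and `config`.
#' @export
simulate_library <- function(refs, config) {
  stopifnot(inherits(refs, "reference_set"),
            inherits(config, "read_sim_config"))
  man <- refs$manifest
  w <- config$locus_weights
  unknown <- setdiff(names(w), man$locus_id)
  if (length(unknown)) {
    stop("unknown locus_id in weights: ", paste(unknown, collapse = ", "))
  }
  n <- config$n_reads
  empty_gt <- data.table::data.table(read_id = character(),
                                     locus_id = character(), arm = character(),
                                     five_offset = integer(),
                                     three_offset = integer())
  if (n == 0L) {
    return(list(reads = setNames(character(0), character(0)),
                ground_truth = empty_gt,
                expected_counts = data.table::data.table(
                  locus_id = names(w), expected_count = 0),
                config = config))
  }
  nf <- config$singleton_noise_fraction
  wn <- w / sum(w)
  ar <- config$arm_ratio
  if (is.null(ar)) ar <- setNames(man$arm_ratio, man$locus_id)[names(w)]
  iso <- config$isomir_probs

  withr::with_seed(config$seed, {
    origin <- sample(c(names(w), ".noise"), n, replace = TRUE,
                     prob = c(wn * (1 - nf), nf))
    idx <- match(origin, man$locus_id)           # NA for noise
    is_noise <- is.na(idx)
    n_loc <- sum(!is_noise)

    inserts <- character(n)
    arm <- rep(NA_character_, n)
    fo <- integer(n); to <- integer(n)

    if (n_loc) {
      li <- idx[!is_noise]
      cls <- man$locus_class[li]
      has_star <- !is.na(man$star_local_start[li])
      r <- ar[origin[!is_noise]]
      p_mat <- ifelse(has_star & is.finite(r), r / (1 + r), 1)
      take_mature <- runif(n_loc) < p_mat
      arm_i <- ifelse(cls %in% c("rrna", "mrna_decoy"), "decoy",
                      ifelse(take_mature, "mature", "star"))
      off_i <- sample(nrow(iso), n_loc, replace = TRUE, prob = iso$prob)
      fo_i <- iso$five[off_i]; to_i <- iso$three[off_i]
      s0 <- ifelse(arm_i == "star", man$star_local_start[li],
                   man$mature_local_start[li])
      e0 <- ifelse(arm_i == "star", man$star_local_end[li],
                   man$mature_local_end[li])
      plen <- nchar(man$precursor_seq[li])
      s <- pmax(0L, s0 + fo_i)
      e <- pmin(plen, e0 + to_i)
      short <- e - s < 15L
      s[short] <- s0[short]; e[short] <- e0[short]
      fo_i[short] <- 0L; to_i[short] <- 0L
      ins <- substr(man$precursor_seq[li], s + 1L, e)
      ## substitution errors
      n_err <- rbinom(n_loc, nchar(ins), config$error_rate)
      for (k in which(n_err > 0L)) {
        ch <- strsplit(ins[k], "")[[1]]
        at <- sample(length(ch), min(n_err[k], length(ch)))
        for (p in at) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
        ins[k] <- paste(ch, collapse = "")
      }
      inserts[!is_noise] <- ins
      arm[!is_noise] <- arm_i
      fo[!is_noise] <- fo_i
      to[!is_noise] <- to_i
    }
    if (any(is_noise)) {
      lens <- sample(18:26, sum(is_noise), replace = TRUE)
      pool <- sample(BASES, sum(lens), replace = TRUE)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      big <- paste(pool, collapse = "")
      inserts[is_noise] <- substring(big, starts, ends)
      arm[is_noise] <- "noise"
    }

    reads <- substr(paste0(inserts, strrep(config$adapter, 3L)),
                    1L, config$read_length)
    names(reads) <- sprintf("%s_read_%07d", config$library_id, seq_len(n))

    gt <- data.table::data.table(
      read_id = names(reads),
      locus_id = ifelse(is_noise, ".noise", origin),
      arm = arm, five_offset = fo, three_offset = to, insert = inserts)

    rr <- ar[names(w)]
    has_star_w <- !is.na(setNames(man$star_local_start,
                                  man$locus_id)[names(w)])
    exp_total <- n * (1 - nf) * wn
    p_m <- ifelse(has_star_w & is.finite(rr), rr / (1 + rr), 1)
    expected <- data.table::data.table(
      locus_id = names(w),
      expected_count = exp_total,
      expected_mature = exp_total * p_m,
      expected_star = exp_total * (1 - p_m))

    list(reads = reads, ground_truth = gt, expected_counts = expected,
         config = config)
  })
}

#' Default multi-library study configuration
#'
#' Twelve libraries by default: six expression profiles, two replicate
#' libraries each. Profile weights are independent log-normal draws per
#' locus; replicates share the profile weights and differ only in their
#' sampling seed, giving the clustering stage a known recoverable structure.
#'
#' @param refs a `reference_set`.
#' @param n_profiles,reps_per_profile library layout.
#' @param n_reads reads per library.
#' @param seed master seed; per-profile and per-library seeds derive from it.
#' @param ... further arguments passed to [read_sim_config()].
#' @return named list of `read_sim_config`, names like "P1r1".
#' @export
default_study_configs <- function(refs, n_profiles = 6L,
                                  reps_per_profile = 2L, n_reads = 50000L,
                                  seed = 1L, ...) {
  loci <- refs$manifest$locus_id
  configs <- list()
  for (p in seq_len(n_profiles)) {
    wts <- withr::with_seed(seed + 1000L * p, {
      setNames(stats::rlnorm(length(loci), meanlog = 0, sdlog = 1.5), loci)
    })
    for (r in seq_len(reps_per_profile)) {
      lid <- sprintf("P%dr%d", p, r)
      configs[[lid]] <- read_sim_config(
        library_id = lid, n_reads = n_reads, locus_weights = wts,
        seed = seed + 100L * p + r, ...)
    }
  }
  configs
}
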