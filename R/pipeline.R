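#' Run the full analysis over a set of (simulated) libraries
#'
#' End-to-end driver: simulate reads for every configuration, trim /
#' collapse / filter tags, annotate known miRNAs, run the subtractive
#' cascade and novel-candidate discovery, build the expression matrix
#' (known miRNAs plus surviving candidates, as relative proportions of
#' total reads) and cluster the libraries.
#'
#' @param refs a `reference_set`.
#' @param configs named list of `read_sim_config` (one per library).
#' @param min_count,min_len,max_len tag admission filters.
#' @param seed RNG seed for the SCFG negative shuffles.
#' @param ... passed to [discover_novel()] (and on to
#'   [apply_post_filters()]).
#' @return list of class `study_result`: `sims`, `processed`, `summaries`,
#'   `known` (per-library annotation), `known_counts`, `presence`,
#'   `discovery`, `expression` (matrix), `clustering`, `top_report`,
#'   `library_totals`.
#' @export
run_study <- function(refs, configs, min_count = 2L, min_len = 17L,
                      max_len = 27L, seed = 1L, ...) {
  sims <- lapply(configs, function(cf) simulate_library(refs, cf))
  processed <- lapply(names(configs), function(l) {
    process_library(sims[[l]]$reads, adapter = configs[[l]]$adapter,
                    library_id = l, min_count = min_count,
                    min_len = min_len, max_len = max_len)
  })
  names(processed) <- names(configs)
  summaries <- data.table::rbindlist(lapply(processed, `[[`, "summary"))

  precursor_index <- build_index(refs$precursors)
  known <- lapply(processed, function(p)
    annotate_known(p$tags, refs$registry, precursor_index))
  known_counts <- data.table::rbindlist(lapply(known, `[[`, "counts"))
  presence <- if (nrow(known_counts)) tally_presence(known_counts) else NULL

  tag_tables <- lapply(processed, `[[`, "tags")
  discovery <- discover_novel(tag_tables, refs, seed = seed, ...)

  expr_counts <- data.table::rbindlist(list(
    known_counts[, .(id = mir_id, library_id, count = total)],
    if (nrow(discovery$candidates)) {
      keep <- discovery$candidates[status %in% c("candidate", "named"),
                                   candidate_id]
      discovery$counts[candidate_id %in% keep,
                       .(id = candidate_id, library_id, count)]
    } else NULL))
  library_totals <- setNames(summaries$total_reads, summaries$library_id)
  expression <- if (nrow(expr_counts)) {
    build_matrix(expr_counts, library_totals)
  } else NULL
  clustering <- if (!is.null(expression) && ncol(expression) >= 2L &&
                    nrow(expression) >= 3L) {
    hierarchical_cluster(expression)
  } else NULL
  top_report <- if (!is.null(expression)) top_n_report(expression) else NULL

  structure(list(sims = sims, processed = processed, summaries = summaries,
                 known = known, known_counts = known_counts,
                 presence = presence, discovery = discovery,
                 expression = expression, clustering = clustering,
                 top_report = top_report, library_totals = library_totals,
                 configs = configs),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  nc <- if (nrow(x$discovery$candidates)) {
    sum(x$discovery$candidates$status == "named")
  } else 0L
  cat("study_result:", length(x$sims), "libraries,",
      length(unique(x$known_counts$mir_id)), "known miRNAs detected,",
      nc, "named novel candidates\n")
  invisible(x)
}

#' Score a study against the generator's ground truth
#'
#' Computes the planted-recovery diagnostics the synthetic design makes
#' possible: which planted novel loci (novel miRNAs and mirtrons) were
#' recovered as named candidates, whether any named candidate originates
#' from an rRNA/mRNA decoy locus, whether every planted locus's genomic
#' context is recovered, arm-ratio class recovery, isomiR 3' vs 5' offset
#' mass, noise elimination, and whether the dendrogram pairs same-profile
#' replicates first.
#'
#' @param refs the `reference_set` the study ran on.
#' @param study a `study_result`.
#' @param naming_threshold the naming read threshold used in the study.
#' @return list of evaluation tables and rates (see details in the
#'   package vignette).
#' @export
evaluate_study <- function(refs, study, naming_threshold = 5) {
  man <- refs$manifest
  cand <- study$discovery$candidates
  named <- if (nrow(cand)) cand[status == "named"] else cand

  ## ---- planted novel recovery ----
  novel <- man[locus_class %in% c("novel_mirna", "mirtron_typical",
                                  "mirtron_atypical")]
  exp_tot <- data.table::rbindlist(
    lapply(study$sims, `[[`, "expected_counts"))[
      , .(expected = sum(expected_count)), by = locus_id]
  novel <- merge(novel, exp_tot, by = "locus_id", all.x = TRUE)
  novel[, recovered := vapply(seq_len(.N), function(r) {
    if (!nrow(named)) return(FALSE)
    any(named$chrom == chrom[r] & named$strand == strand[r] &
          named$mature_start < prec_end[r] & prec_start[r] < named$mature_end)
  }, logical(1))]
  eligible <- novel[expected > naming_threshold]
  recovery_rate <- if (nrow(eligible)) mean(eligible$recovered) else NA_real_

  ## ---- decoy contamination ----
  decoys <- man[locus_class %in% c("rrna", "mrna_decoy")]
  n_decoy_named <- if (!nrow(named) || !nrow(decoys)) 0L else {
    sum(vapply(seq_len(nrow(named)), function(r) {
      any(decoys$chrom == named$chrom[r] &
            decoys$prec_start < named$mature_end[r] &
            named$mature_start[r] < decoys$prec_end)
    }, logical(1)))
  }

  ## ---- context recovery ----
  ctx <- classify_locations(
    man[, .(id = locus_id, chrom, start = prec_start, end = prec_end)],
    refs$gene_models, promoter_len = refs$params$promoter_len)
  expected_feature <- ifelse(man$locus_class == "mirtron_typical",
                             "mirtron_typical",
                      ifelse(man$locus_class == "mirtron_atypical",
                             "mirtron_atypical", man$context_label))
  context <- data.table::data.table(
    locus_id = man$locus_id, locus_class = man$locus_class,
    expected = expected_feature,
    observed = ctx$feature[match(man$locus_id, ctx$id)])
  context[, ok := expected == observed]

  ## ---- arm-ratio class recovery ----
  exp_arms <- data.table::rbindlist(lapply(names(study$sims), function(l) {
    ec <- study$sims[[l]]$expected_counts
    data.table::data.table(library_id = l, ec)
  }))
  truth_ratio <- setNames(man$arm_ratio, man$locus_id)
  arm_eval <- merge(
    exp_arms[expected_mature >= 50 & expected_star >= 50,
             .(library_id, locus_id)],
    study$known_counts[, .(locus_id = mir_id, library_id, ratio_class)],
    by = c("library_id", "locus_id"))
  if (nrow(arm_eval)) {
    arm_eval[, truth_class := vapply(locus_id, function(l) {
      r <- truth_ratio[[l]]
      if (r < 0.75) "star_dominant" else if (r <= 2.2) "equivalent"
      else "mature_dominant"
    }, character(1))]
    arm_eval[, ok := ratio_class == truth_class]
  }
  arm_rate <- if (nrow(arm_eval)) mean(arm_eval$ok) else NA_real_

  ## ---- isomiR offset mass ----
  iso <- data.table::rbindlist(lapply(study$known, `[[`, "isomirs"))
  iso_mass <- if (nrow(iso)) {
    list(three = iso[three_offset != 0L, sum(count)] / sum(iso$count),
         five = iso[five_offset != 0L, sum(count)] / sum(iso$count))
  } else list(three = NA_real_, five = NA_real_)

  ## ---- singleton-noise elimination ----
  noise_elim <- vapply(names(study$sims), function(l) {
    gt <- study$sims[[l]]$ground_truth
    noise <- gt[locus_id == ".noise"]
    if (!nrow(noise)) return(NA_real_)
    kept <- study$processed[[l]]$tags$sequence
    1 - sum(noise$insert %in% kept) / nrow(noise)
  }, numeric(1))

  ## ---- replicate pairing in the dendrogram ----
  replicate_pairing <- NA
  if (!is.null(study$clustering)) {
    hc <- study$clustering$hclust
    prof <- sub("r[0-9]+$", "", hc$labels)
    n_prof <- length(unique(prof))
    first <- hc$merge[seq_len(min(n_prof, nrow(hc$merge))), , drop = FALSE]
    replicate_pairing <- all(first < 0) &&
      all(prof[-first[, 1]] == prof[-first[, 2]])
  }

  list(novel = novel[], recovery_rate = recovery_rate,
       n_eligible = nrow(eligible), n_decoy_named = n_decoy_named,
       context = context[], context_rate = mean(context$ok),
       arm_eval = if (nrow(arm_eval)) arm_eval[] else arm_eval,
       arm_rate = arm_rate, isomir_mass = iso_mass,
       noise_elimination = noise_elim,
       replicate_pairing = replicate_pairing)
}

#' Write the study's tabular outputs
#'
#' Emits the library summary, known-miRNA counts, presence tallies, isomiR
#' spectra, candidate table, cascade summary, cross-library tally matrix,
#' expression matrix and Newick dendrogram as plain-text files.
#'
#' @param study a `study_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_study_outputs <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(study$summaries, "library_summary.tsv")
  w(study$known_counts, "known_counts.tsv")
  if (!is.null(study$presence)) {
    w(study$presence$per_library, "known_presence.tsv")
  }
  iso <- data.table::rbindlist(lapply(study$known, `[[`, "isomirs"))
  if (nrow(iso)) w(iso, "isomirs.tsv")
  if (nrow(study$discovery$candidates)) {
    w(study$discovery$candidates, "candidates.tsv")
    w(study$discovery$counts, "candidate_counts.tsv")
  }
  w(study$discovery$cascade_summary, "cascade_summary.tsv")
  if (!is.null(study$discovery$tally)) {
    w(study$discovery$tally$table, "novel_tally.tsv")
  }
  if (!is.null(study$expression)) {
    em <- data.table::data.table(id = rownames(study$expression),
                                 study$expression)
    w(em, "expression_matrix.tsv")
  }
  if (!is.null(study$clustering)) {
    writeLines(study$clustering$newick, file.path(outdir, "dendrogram.nwk"))
  }
  invisible(outdir)
}
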