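## Gene-structure mapping: UTRs derived on the fly from transcript + CDS
## coordinates, feature classification with a fixed precedence, and mirtron
## typing against intron boundaries. All internal coordinates are 0-based
## half-open; GFF3 I/O converts to/from 1-based closed (see io.R).

.FEATURE_PRECEDENCE <- c("mirtron_typical", "mirtron_atypical", "exon",
                         "five_utr", "three_utr", "intron", "promoter",
                         "intergenic")

.validate_model <- function(model) {
  es <- model$exon_starts; ee <- model$exon_ends
  stopifnot(length(es) == length(ee), all(es < ee))
  if (length(es) > 1L && any(ee[-length(ee)] > es[-1L])) {
    stop("exons overlap or are unsorted in ", model$transcript_id)
  }
  if (!is.na(model$cds_start)) {
    cds_cov <- sum(.overlap_width(es, ee, model$cds_start, model$cds_end))
    # CDS ends must fall inside the exon union
    in_exon <- function(p) any(es <= p & p <= ee)
    if (!in_exon(model$cds_start) || !in_exon(model$cds_end) || cds_cov <= 0) {
      stop("CDS outside exon union in ", model$transcript_id)
    }
  }
  invisible(model)
}

#' Derive 5' and 3' UTR intervals from a gene model
#'
#' On the plus strand the 5' UTR is the exonic sequence left of the CDS
#' start and the 3' UTR the exonic sequence right of the CDS end; mirrored
#' on the minus strand. Non-coding models yield empty UTR lists.
#'
#' @param model a gene model: list with `transcript_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end` (NA when non-coding),
#'   `exon_starts`, `exon_ends` (0-based half-open).
#' @return list with `five_utr` and `three_utr`, each a two-column matrix of
#'   half-open intervals (possibly zero rows).
#' @export
derive_utrs <- function(model) {
  .validate_model(model)
  none <- matrix(integer(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  if (is.na(model$cds_start)) {
    return(list(five_utr = none, three_utr = none))
  }
  es <- model$exon_starts; ee <- model$exon_ends
  clip <- function(lo, hi) {
    s <- pmax(es, lo); e <- pmin(ee, hi)
    keep <- s < e
    cbind(start = s[keep], end = e[keep])
  }
  left <- clip(model$tx_start, model$cds_start)
  right <- clip(model$cds_end, model$tx_end)
  if (model$strand == "+") {
    list(five_utr = left, three_utr = right)
  } else {
    list(five_utr = right, three_utr = left)
  }
}

# intron intervals of a model (possibly zero rows)
.introns <- function(model) {
  es <- model$exon_starts; ee <- model$exon_ends
  k <- length(es)
  if (k < 2L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ee[-k], end = es[-1L])
}

#' Type a precursor against an intron's splice sites
#'
#' Typical mirtrons are anchored to splice sites at both the 5' and 3' ends
#' (the precursor is the whole intron); atypical mirtrons are flanked by
#' exactly one splice site.
#'
#' @param prec_start,prec_end precursor interval (0-based half-open).
#' @param intron_start,intron_end intron interval.
#' @param tolerance allowed boundary offset in nt (0 = exact anchoring).
#' @return "typical", "atypical" or "none".
#' @export
classify_mirtron <- function(prec_start, prec_end, intron_start, intron_end,
                             tolerance = 0L) {
  if (.overlap_width(prec_start, prec_end, intron_start, intron_end) == 0L) {
    return("none")
  }
  at5 <- abs(prec_start - intron_start) <= tolerance
  at3 <- abs(prec_end - intron_end) <= tolerance
  if (at5 && at3) "typical" else if (at5 || at3) "atypical" else "none"
}

#' Classify the genomic context of a precursor interval
#'
#' For every transcript the precursor overlaps (or whose promoter window it
#' overlaps), the transcript-level feature is the maximal-overlap region
#' among coding exon / 5' UTR / 3' UTR / intron, upgraded to
#' mirtron_typical/mirtron_atypical when the precursor is splice-site
#' anchored within its best-overlapping intron. Across transcripts the
#' highest-precedence feature wins (mirtron_typical > mirtron_atypical >
#' exon > five_utr > three_utr > intron > promoter > intergenic); ties break
#' by transcript_id. No overlapping transcript at all gives intergenic.
#'
#' @param prec_start,prec_end precursor interval (0-based half-open).
#' @param chrom chromosome name.
#' @param models list of gene models.
#' @param promoter_len promoter window length upstream of the TSS
#'   (strand-aware).
#' @param mirtron_tolerance splice-site anchoring tolerance, nt.
#' @return list: `feature`, `transcript_id` (NA for intergenic),
#'   `overlap_nt`.
#' @export
classify_location <- function(prec_start, prec_end, chrom, models,
                              promoter_len = 1000L, mirtron_tolerance = 0L) {
  calls <- list()
  for (m in models) {
    if (!identical(m$chrom, chrom)) next
    regions <- list()
    utrs <- derive_utrs(m)
    if (nrow(utrs$five_utr)) regions$five_utr <- utrs$five_utr
    if (nrow(utrs$three_utr)) regions$three_utr <- utrs$three_utr
    # coding exon portion for coding models; whole exons for non-coding
    es <- m$exon_starts; ee <- m$exon_ends
    if (!is.na(m$cds_start)) {
      s <- pmax(es, m$cds_start); e <- pmin(ee, m$cds_end)
      keep <- s < e
      if (any(keep)) regions$exon <- cbind(start = s[keep], end = e[keep])
    } else {
      regions$exon <- cbind(start = es, end = ee)
    }
    intr <- .introns(m)
    if (nrow(intr)) regions$intron <- intr
    prom <- if (m$strand == "+") {
      c(m$tx_start - promoter_len, m$tx_start)
    } else c(m$tx_end, m$tx_end + promoter_len)
    regions$promoter <- cbind(start = prom[1], end = prom[2])

    ov <- vapply(regions, function(iv)
      sum(.overlap_width(iv[, "start"], iv[, "end"], prec_start, prec_end)),
      numeric(1))
    if (all(ov == 0)) next
    feat <- names(regions)[which.max(ov)]
    best_ov <- max(ov)
    if (feat == "intron") {
      iov <- .overlap_width(intr[, "start"], intr[, "end"],
                            prec_start, prec_end)
      bi <- which.max(iov)
      mt <- classify_mirtron(prec_start, prec_end,
                             intr[bi, "start"], intr[bi, "end"],
                             mirtron_tolerance)
      if (mt != "none") feat <- paste0("mirtron_", mt)
    }
    calls[[length(calls) + 1L]] <- list(feature = feat,
                                        transcript_id = m$transcript_id,
                                        overlap_nt = best_ov)
  }
  if (!length(calls)) {
    return(list(feature = "intergenic", transcript_id = NA_character_,
                overlap_nt = 0))
  }
  prec_rank <- vapply(calls, function(cl)
    match(cl$feature, .FEATURE_PRECEDENCE), numeric(1))
  tids <- vapply(calls, `[[`, character(1), "transcript_id")
  best <- order(prec_rank, tids)[1]
  calls[[best]]
}

#' Classify the genomic context of many candidates
#'
#' @param intervals data.table/data.frame with columns `id`, `chrom`,
#'   `start`, `end` (0-based half-open precursor intervals).
#' @inheritParams classify_location
#' @return data.table: `id`, `feature`, `transcript_id`, `overlap_nt`.
#' @export
classify_locations <- function(intervals, models, promoter_len = 1000L,
                               mirtron_tolerance = 0L) {
  rows <- lapply(seq_len(nrow(intervals)), function(r) {
    cl <- classify_location(intervals$start[r], intervals$end[r],
                            intervals$chrom[r], models, promoter_len,
                            mirtron_tolerance)
    data.table::data.table(id = intervals$id[r], feature = cl$feature,
                           transcript_id = cl$transcript_id,
                           overlap_nt = cl$overlap_nt)
  })
  data.table::rbindlist(rows)
}
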