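#' Assign a precursor-mapped tag to mature, star or hairpin region
#'
#' A tag is called mature (or star) when both of its ends lie within
#' `arm_tolerance` nt of the corresponding annotated arm ends; otherwise it
#' is a hairpin-region read (loop-spanning or arm-overhanging). End offsets
#' are reported signed, tag end minus reference arm end, separately for the
#' 5' and 3' ends — the isomiR coordinates.
#'
#' If a tag fits both arm windows (tiny precursors), the arm with the
#' smaller total absolute end offset wins; ties go to mature.
#'
#' @param tag_start,tag_end tag interval on the precursor (0-based
#'   half-open, precursor-local).
#' @param mature_start,mature_end annotated mature arm interval.
#' @param star_start,star_end annotated star arm interval (NA when the
#'   precursor has no star annotation; such tags can only be mature or
#'   hairpin_region).
#' @param arm_tolerance maximum absolute end offset for an arm call, nt.
#' @return list: `assignment` ("mature", "star" or "hairpin_region"),
#'   `five_offset`, `three_offset` (NA for hairpin_region).
#' @export
assign_tag <- function(tag_start, tag_end, mature_start, mature_end,
                       star_start = NA_integer_, star_end = NA_integer_,
                       arm_tolerance = 4L) {
  off_m <- c(tag_start - mature_start, tag_end - mature_end)
  fits_m <- all(abs(off_m) <= arm_tolerance)
  fits_s <- FALSE
  off_s <- c(NA_integer_, NA_integer_)
  if (!is.na(star_start)) {
    off_s <- c(tag_start - star_start, tag_end - star_end)
    fits_s <- all(abs(off_s) <= arm_tolerance)
  }
  if (fits_m && fits_s) {
    if (sum(abs(off_s)) < sum(abs(off_m))) fits_m <- FALSE else fits_s <- FALSE
  }
  if (fits_m) {
    list(assignment = "mature", five_offset = off_m[1], three_offset = off_m[2])
  } else if (fits_s) {
    list(assignment = "star", five_offset = off_s[1], three_offset = off_s[2])
  } else {
    list(assignment = "hairpin_region", five_offset = NA_integer_,
         three_offset = NA_integer_)
  }
}

#' Classify a mature:star count ratio
#'
#' Bins: star_dominant below 0.75, equivalent within [0.75, 2.2],
#' mature_dominant above 2.2; undefined when the star count is zero (no
#' pseudocount is applied).
#'
#' @param mature_count,star_count nonnegative read counts.
#' @return list: `mature_count`, `star_count`, `ratio` (NA when undefined),
#'   `ratio_class`.
#' @export
compute_arm_ratio <- function(mature_count, star_count) {
  stopifnot(mature_count >= 0, star_count >= 0)
  if (star_count == 0) {
    return(list(mature_count = mature_count, star_count = star_count,
                ratio = NA_real_, ratio_class = "undefined"))
  }
  ratio <- mature_count / star_count
  cls <- if (ratio < 0.75) "star_dominant"
         else if (ratio <= 2.2) "equivalent"
         else "mature_dominant"
  list(mature_count = mature_count, star_count = star_count,
       ratio = ratio, ratio_class = cls)
}

#' Annotate known-miRNA tags for one library
#'
#' Maps retained unique tags onto the known precursors (perfect match, sense
#' strand) and aggregates per-precursor mature / star / hairpin-region
#' counts, isomiR spectra and arm ratios. A tag matching several precursors
#' contributes its count to each (multi-precursor families).
#'
#' @param tags tag data.table (`sequence`, `count`, `library_id`).
#' @param registry known-miRNA registry (see [write_registry()]).
#' @param precursor_index optional prebuilt `ref_index` over the precursor
#'   sequences; built on the fly when NULL.
#' @param arm_tolerance see [assign_tag()].
#' @param max_hits multimapper cap for the precursor search.
#' @return list with data.tables `counts` (per mir_id: `mature`, `star`,
#'   `hairpin_region`, `total`, `ratio`, `ratio_class`), `isomirs` (per
#'   mir_id x offset pair: `count`), and `assigned_tags` (tag-level detail).
#' @export
annotate_known <- function(tags, registry, precursor_index = NULL,
                           arm_tolerance = 4L, max_hits = 10L) {
  if (is.null(precursor_index)) {
    precursor_index <- build_index(
      setNames(registry$precursor_seq, registry$mir_id))
  }
  lib <- if (nrow(tags)) tags$library_id[1] else NA_character_
  empty_counts <- data.table::data.table(
    mir_id = character(), library_id = character(), mature = numeric(),
    star = numeric(), hairpin_region = numeric(), total = numeric(),
    ratio = numeric(), ratio_class = character())
  empty_iso <- data.table::data.table(
    mir_id = character(), library_id = character(), arm = character(),
    five_offset = integer(), three_offset = integer(), count = numeric())
  if (!nrow(tags)) {
    return(list(counts = empty_counts, isomirs = empty_iso,
                assigned_tags = data.table::data.table()))
  }
  res <- find_perfect_matches_many(tags$sequence, precursor_index,
                                   search_minus_strand = FALSE,
                                   max_hits = max_hits)
  hits <- res$hits
  if (!nrow(hits)) {
    return(list(counts = empty_counts, isomirs = empty_iso,
                assigned_tags = data.table::data.table()))
  }
  hits <- merge(hits, tags[, .(sequence, count)],
                by.x = "tag", by.y = "sequence")
  hits <- merge(hits, registry, by.x = "ref_name", by.y = "mir_id")
  asg <- lapply(seq_len(nrow(hits)), function(r) {
    assign_tag(hits$start[r], hits$end[r],
               hits$mature_start[r], hits$mature_end[r],
               hits$star_start[r], hits$star_end[r], arm_tolerance)
  })
  hits[, assignment := vapply(asg, `[[`, character(1), "assignment")]
  hits[, five_offset := vapply(asg, function(a)
    as.integer(a$five_offset), integer(1))]
  hits[, three_offset := vapply(asg, function(a)
    as.integer(a$three_offset), integer(1))]
  hits[, mir_id := ref_name]

  counts <- hits[, .(mature = sum(count[assignment == "mature"]),
                     star = sum(count[assignment == "star"]),
                     hairpin_region = sum(count[assignment == "hairpin_region"]),
                     total = sum(count)),
                 by = mir_id]
  rat <- lapply(seq_len(nrow(counts)), function(r)
    compute_arm_ratio(counts$mature[r], counts$star[r]))
  counts[, ratio := vapply(rat, function(x) as.numeric(x$ratio), numeric(1))]
  counts[, ratio_class := vapply(rat, `[[`, character(1), "ratio_class")]
  counts[, library_id := lib]
  data.table::setcolorder(counts, c("mir_id", "library_id"))
  data.table::setorder(counts, mir_id)

  isomirs <- hits[assignment != "hairpin_region",
                  .(count = sum(count)),
                  by = .(mir_id, arm = assignment, five_offset, three_offset)]
  isomirs[, library_id := lib]
  data.table::setcolorder(isomirs,
                          c("mir_id", "library_id", "arm",
                            "five_offset", "three_offset", "count"))
  data.table::setorder(isomirs, mir_id, arm, five_offset, three_offset)

  list(counts = counts[], isomirs = isomirs[],
       assigned_tags = hits[, .(tag, mir_id, start, end, count,
                                assignment, five_offset, three_offset)])
}

#' Cross-library presence tallies for known miRNAs
#'
#' A miRNA is present in a library when its mature or star count is at least
#' `min_reads` after tag filtering.
#'
#' @param counts_list list of per-library `counts` tables from
#'   [annotate_known()] (or one rbind-ed table).
#' @param min_reads presence threshold.
#' @return list: `per_library` (data.table: `library_id`, `n_present`),
#'   `present_sets` (named list of mir_id vectors), `common_to_all`,
#'   `unique_to_one` (data.table: `mir_id`, `library_id`).
#' @export
tally_presence <- function(counts_list, min_reads = 1L) {
  counts <- if (data.table::is.data.table(counts_list)) counts_list
            else data.table::rbindlist(counts_list)
  if (!nrow(counts)) stop("no known-miRNA counts supplied")
  libs <- unique(counts$library_id)
  present <- counts[mature + star >= min_reads, .(library_id, mir_id)]
  sets <- lapply(setNames(libs, libs), function(l)
    sort(present[library_id == l, mir_id]))
  per_library <- data.table::data.table(
    library_id = libs, n_present = vapply(sets, length, integer(1)))
  common <- Reduce(intersect, sets)
  occ <- present[, .(n_libs = .N), by = mir_id]
  uniq_ids <- occ[n_libs == 1L, mir_id]
  unique_to_one <- present[mir_id %in% uniq_ids][order(mir_id)]
  list(per_library = per_library, present_sets = sets,
       common_to_all = sort(common),
       unique_to_one = unique_to_one[, .(mir_id, library_id)])
}
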