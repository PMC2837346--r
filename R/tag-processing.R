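#' Trim the 3' adapter from reads
#'
#' Sequencing of an 18–26 nt insert on a 36-cycle run reads through into the
#' 3' adapter; the insert is the read prefix preceding the leftmost exact
#' occurrence of an adapter prefix of length >= `min_overlap`. Reads without
#' such an occurrence are returned unchanged. Matching is exact (no error
#' model), keeping the behaviour auditable.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length to accept (>= 5).
#' @return character vector of trimmed sequences (possibly empty strings when
#'   the adapter starts at position 1).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  stopifnot(min_overlap >= 5L, nchar(adapter) >= min_overlap)
  if (!length(reads)) return(character(0))
  probe <- substr(toupper(adapter), 1L, min_overlap)
  reads <- toupper(reads)
  p <- regexpr(probe, reads, fixed = TRUE)
  ifelse(p > 0L, substr(reads, 1L, p - 1L), reads)
}

#' Collapse trimmed reads into counted unique tags
#'
#' Each distinct sequence becomes one tag carrying its copy number, the
#' "unique sequence tag" unit on which the whole downstream analysis operates.
#' Reads containing N are dropped first (everything downstream is
#' perfect-match only). Output order is deterministic: descending count, then
#' lexicographic sequence.
#'
#' @param reads character vector of trimmed read sequences.
#' @param library_id library identifier attached to every tag.
#' @return list with `tags` (data.table: `sequence`, `count`, `library_id`)
#'   and `n_collapsed` (number of reads represented).
#' @export
collapse_reads <- function(reads, library_id = "lib") {
  reads <- toupper(reads)
  reads <- reads[!grepl("N", reads, fixed = TRUE) & nzchar(reads)]
  if (!length(reads)) {
    return(list(tags = data.table::data.table(sequence = character(),
                                              count = integer(),
                                              library_id = character()),
                n_collapsed = 0L))
  }
  dt <- data.table::data.table(sequence = reads)
  tags <- dt[, .(count = .N), by = sequence]
  data.table::setorder(tags, -count, sequence)
  tags[, library_id := library_id]
  list(tags = tags[], n_collapsed = length(reads))
}

#' Abundance and length admission filter for unique tags
#'
#' Retains tags seen at least `min_count` times (default 2: singletons are
#' presumed sequencing errors) with lengths within `[min_len, max_len]`.
#'
#' @param tags data.table from [collapse_reads()].
#' @param min_count minimum copy number (>= 1).
#' @param min_len,max_len inclusive tag length bounds in nt.
#' @return filtered tag data.table (same columns, same ordering rule).
#' @export
filter_tags <- function(tags, min_count = 2L, min_len = 17L, max_len = 27L) {
  stopifnot(min_count >= 1L)
  if (min_len > max_len) stop("min_len must not exceed max_len")
  len <- nchar(tags$sequence)
  tags[tags$count >= min_count & len >= min_len & len <= max_len]
}

#' Trim, collapse and filter one small RNA library
#'
#' @param reads raw read sequences (or a file path to a FASTQ/FASTA file,
#'   read with Biostrings).
#' @param adapter 3' adapter sequence.
#' @param library_id library identifier.
#' @param min_overlap adapter match length, see [trim_adapter()].
#' @param min_count,min_len,max_len see [filter_tags()].
#' @return list with `tags` (retained tags), `all_tags` (pre-filter tags) and
#'   `summary` (one-row data.table: `library_id`, `total_reads`,
#'   `reads_after_trim`, `reads_in_retained_tags`, `unique_tag_count`).
#' @export
process_library <- function(reads, adapter, library_id = "lib",
                            min_overlap = 6L, min_count = 2L,
                            min_len = 17L, max_len = 27L) {
  if (length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  total <- length(reads)
  trimmed <- trim_adapter(reads, adapter, min_overlap)
  trimmed <- trimmed[nchar(trimmed) >= min_len]
  col <- collapse_reads(trimmed, library_id)
  kept <- filter_tags(col$tags, min_count, min_len, max_len)
  summary <- data.table::data.table(
    library_id = library_id,
    total_reads = total,
    reads_after_trim = col$n_collapsed,
    reads_in_retained_tags = sum(kept$count),
    unique_tag_count = nrow(kept))
  list(tags = kept, all_tags = col$tags, summary = summary)
}

#' Write a tag table as TSV
#'
#' @param tags tag data.table.
#' @param path output file.
#' @export
write_tag_table <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
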