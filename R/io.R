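#' Write named sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads as Phred+33 FASTQ (constant 'I' qualities)
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  names(quals) <- names(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features; internal 0-based half-open
#' coordinates are converted to the 1-based closed GFF3 convention.
#'
#' @param models list of gene models (see [build_reference_set()]).
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    g <- function(type, start, end, id, parent = NULL) {
      attr <- paste0("ID=", id)
      if (!is.null(parent)) attr <- paste0(attr, ";Parent=", parent)
      sprintf("%s\tmircascade\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, type, start + 1L, end, m$strand, attr)
    }
    gid <- paste0("gene:", m$transcript_id)
    tid <- m$transcript_id
    lines <- c(lines,
               g("gene", m$tx_start, m$tx_end, gid),
               g("mRNA", m$tx_start, m$tx_end, tid, gid))
    for (e in seq_along(m$exon_starts)) {
      lines <- c(lines, g("exon", m$exon_starts[e], m$exon_ends[e],
                          sprintf("%s.exon%d", tid, e), tid))
    }
    if (!is.na(m$cds_start)) {
      for (e in seq_along(m$exon_starts)) {
        cs <- max(m$exon_starts[e], m$cds_start)
        ce <- min(m$exon_ends[e], m$cds_end)
        if (cs < ce) {
          lines <- c(lines, g("CDS", cs, ce,
                              sprintf("%s.cds%d", tid, e), tid))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Uses rtracklayer for parsing; reconstructs the package's gene-model list
#' (0-based half-open coordinates).
#'
#' @param path GFF3 file.
#' @return list of gene models.
#' @export
read_gff3_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  mrna <- df[df$type == "mRNA", ]
  models <- lapply(seq_len(nrow(mrna)), function(r) {
    tid <- mrna$ID[r]
    ex <- df[df$type == "exon" & df$Parent == tid, ]
    ex <- ex[order(ex$start), ]
    cds <- df[df$type == "CDS" & df$Parent == tid, ]
    list(transcript_id = tid,
         chrom = as.character(mrna$seqnames[r]),
         strand = as.character(mrna$strand[r]),
         tx_start = mrna$start[r] - 1L,
         tx_end = mrna$end[r],
         cds_start = if (nrow(cds)) min(cds$start) - 1L else NA_integer_,
         cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
         exon_starts = ex$start - 1L,
         exon_ends = ex$end)
  })
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  models
}

#' Write / read the planted-locus manifest
#'
#' Plain TSV; the round trip is lossless.
#'
#' @param manifest data.table of planted loci.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(character = "chrom"))
  dt[]
}

#' Write / read the known-miRNA registry
#'
#' Columns: `mir_id`, `precursor_seq`, `mature_start`, `mature_end`,
#' `star_start`, `star_end` (0-based half-open, precursor-local).
#'
#' @param registry data.table registry.
#' @param path file path.
#' @export
write_registry <- function(registry, path) {
  write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")[]
}
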