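#' Build a k-mer seed index over a set of reference sequences
#'
#' Perfect-match placement of short tags is done seed-and-verify style: every
#' k-mer of every reference is recorded, a query is seeded by its first k-mer,
#' and each seeded location is verified by full substring comparison. Because
#' every occurrence of a query contains its first k-mer, verification
#' guarantees exactness (every hit a naive scan finds is found).
#'
#' @param sequences named character vector of reference sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param k seed length in nt; must not exceed the shortest query searched.
#' @return an object of class `ref_index`.
#' @export
build_index <- function(sequences, k = 12L) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) && (is.null(names(sequences)) ||
      anyDuplicated(names(sequences)))) {
    stop("reference sequences must have unique names")
  }
  k <- as.integer(k)
  stopifnot(k >= 4L)
  tabs <- lapply(names(sequences), function(nm) {
    sq <- toupper(sequences[[nm]])
    n <- nchar(sq)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(sq, starts, starts + k - 1L),
                           ref_name = nm, pos = starts)
  })
  idx <- data.table::rbindlist(tabs)
  if (nrow(idx)) data.table::setkey(idx, kmer)
  structure(list(seeds = idx, sequences = setNames(toupper(sequences),
                                                   names(sequences)),
                 k = k),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat("ref_index:", length(x$sequences), "reference(s),",
      nrow(x$seeds), "seeds, k =", x$k, "\n")
  invisible(x)
}

#' Find all perfect matches of one tag in an index
#'
#' @param tag query sequence (ACGT; tags containing other characters return
#'   no hits, with a warning).
#' @param index a `ref_index` from [build_index()].
#' @param search_minus_strand also search the reverse complement (genomic
#'   references); plus-strand only for sense references such as precursors
#'   and the transcriptome.
#' @param max_hits hit-count cap; tags exceeding it are flagged multimapped
#'   and their hit list truncated.
#' @return data.table with columns `ref_name`, `start`, `end` (0-based
#'   half-open), `strand`, plus attribute `multimapped` (logical). Hits are
#'   ordered by (ref_name, start, strand).
#' @export
find_perfect_matches <- function(tag, index, search_minus_strand = TRUE,
                                 max_hits = 10L) {
  stopifnot(inherits(index, "ref_index"))
  res <- find_perfect_matches_many(tag, index, search_minus_strand, max_hits,
                                   warn_bad = TRUE)
  hits <- res$hits[, c("ref_name", "start", "end", "strand")]
  attr(hits, "multimapped") <- res$per_tag$multimapped[1]
  hits
}

#' Vectorised perfect matching of many tags
#'
#' @param tags character vector of query sequences.
#' @inheritParams find_perfect_matches
#' @param warn_bad warn on tags containing non-ACGT characters.
#' @return list with `hits` (data.table: `tag`, `ref_name`, `start`, `end`,
#'   `strand`) and `per_tag` (data.table: `tag`, `n_hits`, `multimapped`).
#' @export
find_perfect_matches_many <- function(tags, index, search_minus_strand = TRUE,
                                      max_hits = 10L, warn_bad = FALSE) {
  stopifnot(inherits(index, "ref_index"))
  tags <- toupper(tags)
  bad <- grepl("[^ACGT]", tags)
  if (any(bad) && warn_bad) {
    warning(sum(bad), " tag(s) contain non-ACGT characters; no hits returned")
  }
  empty <- data.table::data.table(tag = character(), ref_name = character(),
                                  start = integer(), end = integer(),
                                  strand = character())
  queries <- unique(tags[!bad & nchar(tags) >= index$k])
  hit_list <- list(empty)
  if (length(queries) && nrow(index$seeds)) {
    strands <- if (search_minus_strand) c("+", "-") else "+"
    for (std in strands) {
      q <- if (std == "+") queries else revcomp(queries)
      seeds <- data.table::data.table(tag = queries, q = q,
                                      kmer = substr(q, 1L, index$k))
      m <- index$seeds[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(m)) {
        m[, len := nchar(q)]
        m[, refseq := unname(index$sequences[ref_name])]
        m <- m[pos + len - 1L <= nchar(refseq)]
        if (nrow(m)) {
          m <- m[substr(refseq, pos, pos + len - 1L) == q]
        }
        if (nrow(m)) {
          hit_list[[length(hit_list) + 1L]] <- m[, .(
            tag, ref_name, start = pos - 1L, end = pos + len - 1L,
            strand = std)]
        }
      }
    }
  }
  hits <- data.table::rbindlist(hit_list)
  data.table::setorder(hits, tag, ref_name, start, strand)
  per_tag <- data.table::data.table(tag = tags)
  cnt <- hits[, .N, by = tag]
  per_tag <- cnt[per_tag, on = "tag"]
  per_tag[is.na(N), N := 0L]
  data.table::setnames(per_tag, "N", "n_hits")
  per_tag[, multimapped := n_hits > max_hits]
  # truncate hit lists of multimapped tags at max_hits
  if (any(per_tag$multimapped)) {
    hits <- hits[, head(.SD, max_hits), by = tag]
    data.table::setcolorder(hits, c("tag", "ref_name", "start", "end", "strand"))
  }
  list(hits = hits[], per_tag = per_tag[, .(tag, n_hits, multimapped)])
}

#' Naive both-strand perfect-match scan (reference oracle)
#'
#' Literal quadratic scan used as the independent correctness oracle for the
#' seeded index.
#'
#' @inheritParams find_perfect_matches
#' @param sequences named character vector of references.
#' @return data.table like [find_perfect_matches()] (untruncated).
#' @export
naive_scan <- function(tag, sequences, search_minus_strand = TRUE) {
  tag <- toupper(tag)
  out <- list(data.table::data.table(ref_name = character(), start = integer(),
                                     end = integer(), strand = character()))
  strands <- if (search_minus_strand) c("+", "-") else "+"
  for (nm in names(sequences)) {
    sq <- toupper(sequences[[nm]])
    for (std in strands) {
      q <- if (std == "+") tag else revcomp(tag)
      found <- integer(0)
      from <- 1L
      repeat {
        p <- regexpr(q, substr(sq, from, nchar(sq)), fixed = TRUE)
        if (p < 0) break
        found <- c(found, from + p - 1L)
        from <- from + p
      }
      if (length(found)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          ref_name = nm, start = found - 1L,
          end = found - 1L + nchar(tag), strand = std)
      }
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, ref_name, start, strand)
  res[]
}

#' Write hits as BED6
#'
#' @param hits data.table with `ref_name`, `start`, `end`, `strand`, plus a
#'   `tag` and optional `score` column.
#' @param path output file.
#' @param scores optional numeric scores (e.g. tag counts); defaults to 0.
#' @export
write_hits_bed <- function(hits, path, scores = NULL) {
  bed <- data.frame(chrom = hits$ref_name, start = hits$start, end = hits$end,
                    name = if ("tag" %in% names(hits)) hits$tag else ".",
                    score = if (is.null(scores)) 0L else scores,
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
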