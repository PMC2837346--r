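#' Fold a short RNA/DNA sequence into its maximum-weight nested structure
#'
#' Computes the secondary structure maximising the weighted number of nested
#' base pairs (GC = 3, AU = 2, GU wobble = 1 by default) subject to a minimum
#' hairpin-loop length, by Nussinov-style dynamic programming. This is the
#' binary hairpin gate of the discovery pipeline: it asks whether a candidate
#' precursor can form a stem-loop at all, not what its folding free energy is.
#'
#' The traceback is deterministic: where several structures achieve the
#' optimal score, pairing the current base is preferred over leaving it
#' unpaired, closing the full interval (partner = right end) is preferred over
#' a bifurcating pairing, and remaining ties go to the smallest partner index.
#'
#' @param sequence a single ACGU/ACGT string, 1 to 200 nt.
#' @param pair_weights named numeric vector with elements `GC`, `AU`, `GU`.
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @return an object of class `fold_result`: a list with elements
#'   `sequence`, `dot_bracket`, `score`, `pairs` (partner index per position,
#'   `NA` when unpaired), `n_pairs`, `paired_fraction`, `n_terminal_loops`
#'   and `max_stem_run`.
#' @export
fold_sequence <- function(sequence,
                          pair_weights = c(GC = 3, AU = 2, GU = 1),
                          min_loop = 3L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  seq_in <- toupper(sequence)
  .check_dna(seq_in)
  seq_dna <- chartr("U", "T", seq_in)
  n <- nchar(seq_dna)
  if (n < 1L || n > 200L) stop("sequence length must be between 1 and 200 nt")
  s <- match(strsplit(seq_dna, "")[[1]], BASES)

  W <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  W["G", "C"] <- W["C", "G"] <- pair_weights[["GC"]]
  W["A", "T"] <- W["T", "A"] <- pair_weights[["AU"]]
  W["G", "T"] <- W["T", "G"] <- pair_weights[["GU"]]

  # Mp[(i)+1, (j)+1] holds the optimum for span i..j; zero padding covers
  # empty spans (j = i - 1) and out-of-range accesses.
  Mp <- matrix(0, n + 2L, n + 2L)
  min_span <- min_loop + 2L
  if (n >= min_span) {
    for (L in min_span:n) {
      for (i in 1:(n - L + 1L)) {
        j <- i + L - 1L
        best <- Mp[i + 2L, j + 1L]                    # i unpaired
        ks <- (i + min_loop + 1L):j
        w <- W[s[i], s[ks]]
        hit <- which(w > 0)
        if (length(hit)) {
          kk <- ks[hit]
          vals <- w[hit] + Mp[i + 2L, kk] + Mp[kk + 2L, j + 1L]
          vbest <- max(vals)
          if (vbest > best) best <- vbest
        }
        Mp[i + 1L, j + 1L] <- best
      }
    }
  }
  score <- Mp[2L, n + 1L]

  pairs <- rep(NA_integer_, n)
  trace <- function(i, j) {
    while (i <= j - min_loop - 1L) {
      target <- Mp[i + 1L, j + 1L]
      if (target <= 0) return(invisible(NULL))
      ks <- (i + min_loop + 1L):j
      w <- W[s[i], s[ks]]
      ok <- w > 0
      cand <- ks[ok][w[ok] + Mp[i + 2L, ks[ok]] + Mp[ks[ok] + 2L, j + 1L] == target]
      if (length(cand)) {
        k <- if (j %in% cand) j else min(cand)
        pairs[i] <<- k
        pairs[k] <<- i
        trace(i + 1L, k - 1L)
        i <- k + 1L
      } else {
        i <- i + 1L
      }
    }
    invisible(NULL)
  }
  trace(1L, n)

  db <- rep(".", n)
  db[!is.na(pairs) & seq_len(n) < pairs] <- "("
  db[!is.na(pairs) & seq_len(n) > pairs] <- ")"
  dot_bracket <- paste(db, collapse = "")

  n_pairs <- sum(!is.na(pairs)) %/% 2L
  res <- structure(list(
    sequence = seq_in,
    dot_bracket = dot_bracket,
    score = score,
    pairs = pairs,
    n_pairs = n_pairs,
    paired_fraction = if (n > 0) 2 * n_pairs / n else 0,
    n_terminal_loops = .count_terminal_loops(dot_bracket),
    max_stem_run = .max_stem_run(pairs)
  ), class = "fold_result")
  res
}

# number of hairpin (terminal) loops: innermost pairs enclosing only dots
.count_terminal_loops <- function(dot_bracket) {
  length(gregexpr("\\(\\.*\\)", dot_bracket)[[1]][
    gregexpr("\\(\\.*\\)", dot_bracket)[[1]] > 0])
}

# longest run of directly stacked pairs (i,j),(i+1,j-1),...
.max_stem_run <- function(pairs) {
  n <- length(pairs)
  best <- 0L
  run <- 0L
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (!is.na(j) && j > i) {
      if (i > 1L && !is.na(pairs[i - 1L]) && pairs[i - 1L] == j + 1L) {
        run <- run + 1L
      } else {
        run <- 1L
      }
      if (run > best) best <- run
    }
  }
  best
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "  (score ", x$score, ", ",
      x$n_pairs, " pairs, ", x$n_terminal_loops, " terminal loop(s))\n",
      sep = "")
  invisible(x)
}

#' Decide whether a fold looks like a pre-miRNA hairpin
#'
#' A structure qualifies when it has at least `min_pairs` base pairs, at least
#' `min_paired_fraction` of its bases paired, and exactly one terminal loop
#' (no bifurcation), up to `max_terminal_loops`.
#'
#' @param fold a `fold_result` from [fold_sequence()].
#' @param criteria list with `min_pairs`, `min_paired_fraction`,
#'   `max_terminal_loops`.
#' @return logical scalar.
#' @export
is_hairpin <- function(fold,
                       criteria = list(min_pairs = 16L,
                                       min_paired_fraction = 0.5,
                                       max_terminal_loops = 1L)) {
  stopifnot(inherits(fold, "fold_result"))
  fold$n_pairs >= criteria$min_pairs &&
    fold$paired_fraction >= criteria$min_paired_fraction &&
    fold$n_terminal_loops >= 1L &&
    fold$n_terminal_loops <= criteria$max_terminal_loops
}

#' Candidate precursor windows around a genomic tag hit
#'
#' A mature miRNA sits on one arm of its precursor, so the precursor extends
#' mostly to one side of the tag. Two windows are returned: one assuming the
#' tag is the 5' arm (short flank on its 5' side, long flank on its 3' side)
#' and one assuming the 3' arm. Flanks are taken in the transcription
#' direction, so they flip genomically for minus-strand hits, and window
#' sequences are reverse-complemented for minus-strand hits.
#'
#' @param genome named character vector of chromosome sequences.
#' @param hit list or one-row data.frame with `ref_name`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param flank_long,flank_short flank lengths in nt.
#' @param min_width windows shorter than this after clipping are dropped.
#' @return a data.table with columns `which` ("5p"/"3p"), `chrom`, `start`,
#'   `end`, `strand`, `seq`, and the tag's 0-based half-open coordinates
#'   within the window sequence (`tag_local_start`, `tag_local_end`).
#' @export
extract_candidate_windows <- function(genome, hit, flank_long = 70L,
                                      flank_short = 20L, min_width = 40L) {
  chrom <- hit$ref_name
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  chrlen <- nchar(genome[[chrom]])
  plus <- identical(hit$strand, "+")
  # flanks in genomic coordinates: (left of start, right of end)
  cfg <- if (plus) {
    list("5p" = c(flank_short, flank_long), "3p" = c(flank_long, flank_short))
  } else {
    list("5p" = c(flank_long, flank_short), "3p" = c(flank_short, flank_long))
  }
  rows <- lapply(names(cfg), function(wh) {
    fl <- cfg[[wh]]
    ws <- max(0L, hit$start - fl[1])
    we <- min(chrlen, hit$end + fl[2])
    if (we - ws < min_width) return(NULL)
    sq <- substr(genome[[chrom]], ws + 1L, we)
    if (plus) {
      tls <- hit$start - ws
      tle <- hit$end - ws
    } else {
      sq <- revcomp(sq)
      tls <- we - hit$end
      tle <- we - hit$start
    }
    data.table::data.table(which = wh, chrom = chrom, start = ws, end = we,
                           strand = hit$strand, seq = sq,
                           tag_local_start = tls, tag_local_end = tle)
  })
  data.table::rbindlist(rows)
}

# Stem-loop components of a fold: chains of single-child nested pairs around
# one terminal loop. Returns a list of components, each with `chain` (a
# matrix of pair coordinates, outermost first) and `span` (outer i, j).
.stem_loop_components <- function(fold) {
  pairs <- fold$pairs
  n <- length(pairs)
  opens <- which(!is.na(pairs) & seq_len(n) < pairs)
  if (!length(opens)) return(list())
  # immediate parent of each pair: the closest enclosing pair
  parent <- rep(NA_integer_, n)   # indexed by the opening position
  n_child <- integer(n)
  stack <- integer(0)
  for (pos in seq_len(n)) {
    if (pos %in% opens) {
      if (length(stack)) {
        parent[pos] <- stack[length(stack)]
        n_child[stack[length(stack)]] <- n_child[stack[length(stack)]] + 1L
      }
      stack <- c(stack, pos)
    } else if (!is.na(pairs[pos]) && pairs[pos] < pos) {
      stack <- stack[-length(stack)]
    }
  }
  terminals <- opens[n_child[opens] == 0L]
  lapply(terminals, function(t) {
    chain <- t
    p <- parent[t]
    while (!is.na(p) && n_child[p] == 1L) {
      chain <- c(p, chain)
      p <- parent[p]
    }
    list(chain = cbind(i = chain, j = pairs[chain]),
         span = c(chain[1], pairs[chain[1]]))
  })
}

# Judge one folded subsequence: find the stem-loop component overlapping the
# tag, trim outer chain pairs as needed, apply the hairpin criteria.
# Coordinates in the returned span are 0-based half-open, local to `seq`.
.assess_fold <- function(seq, tag_lo, tag_hi, criteria, pair_weights,
                         min_loop) {
  fold <- fold_sequence(seq, pair_weights, min_loop)
  comps <- .stem_loop_components(fold)
  if (!length(comps)) {
    return(list(pass = FALSE, span = NULL, n_pairs = 0L,
                paired_fraction = 0, precursor_seq = NA_character_))
  }
  ov <- vapply(comps, function(cp)
    .overlap_width(cp$span[1] - 1L, cp$span[2], tag_lo, tag_hi), numeric(1))
  sizes <- vapply(comps, function(cp) nrow(cp$chain), numeric(1))
  lefts <- vapply(comps, function(cp) cp$span[1], numeric(1))
  best <- order(-ov, -sizes, lefts)[1]
  if (ov[best] == 0) {
    return(list(pass = FALSE, span = NULL, n_pairs = 0L,
                paired_fraction = 0, precursor_seq = NA_character_))
  }
  chain <- comps[[best]]$chain
  L <- nrow(chain)
  for (srt in seq_len(L)) {     # trim outer chain pairs one at a time
    np <- L - srt + 1L
    if (np < criteria$min_pairs) break
    i0 <- chain[srt, "i"]
    j0 <- chain[srt, "j"]
    frac <- 2 * np / (j0 - i0 + 1L)
    if (frac >= criteria$min_paired_fraction) {
      return(list(pass = TRUE, span = c(i0 - 1L, j0), n_pairs = np,
                  paired_fraction = frac,
                  precursor_seq = substr(seq, i0, j0)))
    }
  }
  i0 <- chain[1, "i"]
  j0 <- chain[1, "j"]
  list(pass = FALSE, span = c(i0 - 1L, j0), n_pairs = L,
       paired_fraction = 2 * L / (j0 - i0 + 1L),
       precursor_seq = substr(seq, i0, j0))
}

#' Assess whether a candidate window harbours a single stem-loop
#'
#' Folding a full candidate window maximises pairing globally, so random
#' flanking sequence can both fold into secondary hairpins of its own and
#' lure precursor bases into long-range pairs that break up a genuine stem.
#' This therefore scans putative precursor spans anchored on the mature tag
#' — from tight (tag plus one loop-and-arm length) to the full window,
#' extending towards the side of the window with more room — folds each,
#' extracts the stem-loop component (an unbranched chain of nested pairs
#' around one terminal loop) overlapping the tag, optionally trims outer
#' chain pairs, and accepts the first span whose component meets the
#' hairpin criteria: the in-silico analogue of excising the putative
#' precursor before judging it.
#'
#' @param window_seq window sequence (transcription orientation).
#' @param tag_local_start,tag_local_end 0-based half-open tag coordinates
#'   within `window_seq`.
#' @param criteria hairpin criteria, see [is_hairpin()].
#' @param pair_weights,min_loop passed to [fold_sequence()].
#' @return list with `pass` (logical), `span` (0-based half-open component
#'   coordinates in the window, NULL when no component overlaps the tag),
#'   `n_pairs`, `paired_fraction` and `precursor_seq` of the passing (or
#'   best-seen) component.
#' @export
assess_hairpin_window <- function(window_seq, tag_local_start, tag_local_end,
                                  criteria = list(min_pairs = 16L,
                                                  min_paired_fraction = 0.5,
                                                  max_terminal_loops = 1L),
                                  pair_weights = c(GC = 3, AU = 2, GU = 1),
                                  min_loop = 3L) {
  n <- nchar(window_seq)
  left_room <- tag_local_start
  right_room <- n - tag_local_end
  # candidate precursor spans: short flank behind the tag, stepped extension
  # ahead of it (the precursor continues across the loop into the other arm)
  behind <- c(4L, 12L)
  ahead <- c(30L, 38L, 46L, 56L, 70L)
  spans <- list()
  for (b in behind) for (a in ahead) {
    if (right_room >= left_room) {
      lo <- max(0L, tag_local_start - b); hi <- min(n, tag_local_end + a)
    } else {
      lo <- max(0L, tag_local_start - a); hi <- min(n, tag_local_end + b)
    }
    spans[[length(spans) + 1L]] <- c(lo, hi)
  }
  spans[[length(spans) + 1L]] <- c(0L, n)
  spans <- unique(spans)

  best <- list(pass = FALSE, span = NULL, n_pairs = 0L,
               paired_fraction = 0, precursor_seq = NA_character_)
  for (sp in spans) {
    if (sp[2] - sp[1] < 2L * criteria$min_pairs) next
    a <- .assess_fold(substr(window_seq, sp[1] + 1L, sp[2]),
                      tag_local_start - sp[1], tag_local_end - sp[1],
                      criteria, pair_weights, min_loop)
    if (!is.null(a$span)) a$span <- a$span + sp[1]
    if (a$pass) return(a)
    if (a$n_pairs > best$n_pairs) best <- a
  }
  best
}
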