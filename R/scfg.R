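## Stochastic context-free grammar over pre-miRNA hairpin anatomy.
##
## Nonterminals: S, Stem, SymBulge, AsymBulge, Loop. A hairpin derivation
## walks down the stem emitting base pairs, may step into symmetric or
## asymmetric bulge states (which emit unpaired flanks and return to Stem),
## and terminates in a Loop that emits the terminal-loop bases. Bulge entry
## emits at least one base, so no unary production cycle can derive the empty
## string and the inside dynamic program is exact.
##
## Productions (probabilities per left-hand side sum to 1):
##   S        -> Stem                          (fixed, probability 1)
##   Stem     -> a Stem b     (16)  stem_pair
##   Stem     -> a SymBulge b (16)  stem_sym   (enter symmetric bulge)
##   Stem     -> a AsymBulge  (4)   stem_asym_l
##   Stem     -> AsymBulge a  (4)   stem_asym_r
##   Stem     -> Loop         (1)   stem_loop
##   SymBulge -> a SymBulge b (16)  sym_pair
##   SymBulge -> Stem         (1)   sym_exit
##   AsymBulge-> a AsymBulge  (4)   asym_l
##   AsymBulge-> AsymBulge a  (4)   asym_r
##   AsymBulge-> Stem         (1)   asym_exit
##   Loop     -> a Loop       (4)   loop_cont
##   Loop     -> a            (4)   loop_end

.new_grammar <- function(tabs) {
  g <- structure(tabs, class = "scfg_grammar")
  validate_grammar(g)
  g
}

#' Validate a hairpin SCFG
#'
#' Checks that the probability tables have the right shapes and that the
#' productions of each nonterminal sum to one (within 1e-9).
#'
#' @param grammar an `scfg_grammar`.
#' @return the grammar, invisibly; errors otherwise.
#' @export
validate_grammar <- function(grammar) {
  stopifnot(inherits(grammar, "scfg_grammar"))
  sums <- c(
    Stem = sum(grammar$stem_pair) + sum(grammar$stem_sym) +
      sum(grammar$stem_asym_l) + sum(grammar$stem_asym_r) + grammar$stem_loop,
    SymBulge = sum(grammar$sym_pair) + grammar$sym_exit,
    AsymBulge = sum(grammar$asym_l) + sum(grammar$asym_r) + grammar$asym_exit,
    Loop = sum(grammar$loop_cont) + sum(grammar$loop_end))
  if (any(abs(sums - 1) > 1e-9)) {
    stop("production probabilities do not sum to 1 for: ",
         paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", "))
  }
  invisible(grammar)
}

#' @export
print.scfg_grammar <- function(x, ...) {
  cat("hairpin SCFG: P(Stem->pair) =", round(sum(x$stem_pair), 3),
      " P(Stem->Loop) =", round(x$stem_loop, 3), "\n")
  invisible(x)
}

# Deterministic parse of one (sequence, dot_bracket) into production counts.
# Paired columns -> Stem, unpaired-both-sides -> SymBulge, unpaired opposite
# paired -> AsymBulge, terminal unpaired run -> Loop.
.count_productions <- function(sequence, dot_bracket, record = "?") {
  s <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  db <- strsplit(dot_bracket, "")[[1]]
  n <- length(s)
  if (length(db) != n) stop("structure length mismatch in record ", record)
  # partner table from the bracket string
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (p in seq_len(n)) {
    if (db[p] == "(") stack <- c(stack, p)
    else if (db[p] == ")") {
      if (!length(stack)) stop("unbalanced structure in record ", record)
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[q] <- p
      partner[p] <- q
    }
  }
  if (length(stack)) stop("unbalanced structure in record ", record)

  cnt <- list(stem_pair = matrix(0, 4, 4, dimnames = list(BASES, BASES)),
              stem_sym = matrix(0, 4, 4, dimnames = list(BASES, BASES)),
              stem_asym_l = setNames(numeric(4), BASES),
              stem_asym_r = setNames(numeric(4), BASES),
              stem_loop = 0,
              sym_pair = matrix(0, 4, 4, dimnames = list(BASES, BASES)),
              sym_exit = 0,
              asym_l = setNames(numeric(4), BASES),
              asym_r = setNames(numeric(4), BASES),
              asym_exit = 0,
              loop_cont = setNames(numeric(4), BASES),
              loop_end = setNames(numeric(4), BASES))
  exit_to_stem <- function(state) {
    if (state == "SymBulge") cnt$sym_exit <<- cnt$sym_exit + 1
    if (state == "AsymBulge") cnt$asym_exit <<- cnt$asym_exit + 1
    "Stem"
  }
  i <- 1L; j <- n; state <- "Stem"
  repeat {
    if (i > j) stop("structure without a terminal loop in record ", record)
    paired_inside <- !is.na(partner[i:j])
    if (!any(paired_inside)) {
      state <- exit_to_stem(state)
      cnt$stem_loop <- cnt$stem_loop + 1
      if (i < j) for (p in i:(j - 1L)) {
        cnt$loop_cont[s[p]] <- cnt$loop_cont[s[p]] + 1
      }
      cnt$loop_end[s[j]] <- cnt$loop_end[s[j]] + 1
      break
    }
    pi <- partner[i]; pj <- partner[j]
    if (!is.na(pi) && (pi < i || pi > j) || !is.na(pj) && (pj < i || pj > j)) {
      stop("crossing base pairs in record ", record)
    }
    if (!is.na(pi) && pi == j) {
      state <- exit_to_stem(state)
      cnt$stem_pair[s[i], s[j]] <- cnt$stem_pair[s[i], s[j]] + 1
      i <- i + 1L; j <- j - 1L
    } else if (is.na(pi) && is.na(pj)) {
      if (state == "SymBulge") {
        cnt$sym_pair[s[i], s[j]] <- cnt$sym_pair[s[i], s[j]] + 1
      } else {
        state <- exit_to_stem(state)
        cnt$stem_sym[s[i], s[j]] <- cnt$stem_sym[s[i], s[j]] + 1
        state <- "SymBulge"
      }
      i <- i + 1L; j <- j - 1L
    } else if (is.na(pi)) {
      if (state == "AsymBulge") {
        cnt$asym_l[s[i]] <- cnt$asym_l[s[i]] + 1
      } else {
        state <- exit_to_stem(state)
        cnt$stem_asym_l[s[i]] <- cnt$stem_asym_l[s[i]] + 1
        state <- "AsymBulge"
      }
      i <- i + 1L
    } else if (is.na(pj)) {
      if (state == "AsymBulge") {
        cnt$asym_r[s[j]] <- cnt$asym_r[s[j]] + 1
      } else {
        state <- exit_to_stem(state)
        cnt$stem_asym_r[s[j]] <- cnt$stem_asym_r[s[j]] + 1
        state <- "AsymBulge"
      }
      j <- j - 1L
    } else {
      stop("multiloop (bifurcating) structure in record ", record)
    }
  }
  cnt
}

#' Train the hairpin SCFG on annotated stem-loop structures
#'
#' Each (sequence, dot-bracket) pair is parsed deterministically into the
#' grammar's state path; production probabilities are pseudocount-smoothed
#' relative usage frequencies. Training structures must be single-terminal-
#' loop (unbranched) hairpins; a multiloop structure raises an error naming
#' the offending record.
#'
#' @param hairpins data.frame/data.table with columns `sequence` and
#'   `dot_bracket` (optionally `id` for error messages), or a list of such
#'   pairs.
#' @param smoothing pseudocount added to every production.
#' @return an `scfg_grammar`.
#' @export
train_grammar <- function(hairpins, smoothing = 1) {
  if (is.list(hairpins) && !is.data.frame(hairpins)) {
    hairpins <- data.table::rbindlist(lapply(hairpins, as.list))
  }
  hairpins <- as.data.frame(hairpins)
  if (!nrow(hairpins)) stop("no training hairpins supplied")
  ids <- if ("id" %in% names(hairpins)) hairpins$id else seq_len(nrow(hairpins))
  total <- NULL
  for (r in seq_len(nrow(hairpins))) {
    cnt <- .count_productions(hairpins$sequence[r], hairpins$dot_bracket[r],
                              record = ids[r])
    total <- if (is.null(total)) cnt else {
      Map(`+`, total, cnt)
    }
  }
  total <- lapply(total, function(x) x + smoothing)
  # normalise each nonterminal; an entirely unobserved nonterminal (possible
  # with smoothing 0) falls back to a uniform distribution over its rules
  norm <- function(parts) {
    z <- sum(vapply(parts, sum, numeric(1)))
    if (z > 0) return(lapply(parts, function(x) x / z))
    k <- sum(vapply(parts, length, numeric(1)))
    lapply(parts, function(x) x * 0 + 1 / k)
  }
  stem <- norm(total[c("stem_pair", "stem_sym", "stem_asym_l",
                       "stem_asym_r", "stem_loop")])
  sym <- norm(total[c("sym_pair", "sym_exit")])
  asym <- norm(total[c("asym_l", "asym_r", "asym_exit")])
  loop <- norm(total[c("loop_cont", "loop_end")])
  .new_grammar(c(stem, sym, asym, loop))
}

# parallel log-sum-exp over aligned vectors
.plse <- function(...) {
  xs <- list(...)
  m <- do.call(pmax, xs)
  acc <- rep(0, length(m))
  for (x in xs) acc <- acc + ifelse(is.finite(m), exp(x - m), 0)
  out <- m + log(acc)
  out[!is.finite(m)] <- -Inf
  out
}

#' Inside log-probability of a sequence under the hairpin SCFG
#'
#' Sums the probability of every derivation of the sequence by the inside
#' dynamic program over subintervals (natural-log arithmetic with
#' log-sum-exp). The score used for classification is the length-normalised
#' log-probability.
#'
#' @param grammar an `scfg_grammar`.
#' @param sequence ACGU/ACGT string, length 1..200.
#' @return list of class `scfg_score`: `log_probability` (natural log; `-Inf`
#'   when no derivation exists), `normalized_score` (per-nucleotide), and
#'   `length`.
#' @export
inside_log_probability <- function(grammar, sequence) {
  validate_grammar(grammar)
  stopifnot(length(sequence) == 1L)
  seq_dna <- chartr("U", "T", toupper(sequence))
  .check_dna(seq_dna)
  n <- nchar(seq_dna)
  if (n < 1L || n > 200L) stop("sequence length must be between 1 and 200 nt")
  s <- match(strsplit(seq_dna, "")[[1]], BASES)

  lg <- lapply(grammar, log)
  NEG <- -Inf
  Lm <- matrix(NEG, n, n)  # Loop
  St <- matrix(NEG, n, n)  # Stem
  Sy <- matrix(NEG, n, n)  # SymBulge
  As <- matrix(NEG, n, n)  # AsymBulge
  for (l in seq_len(n)) {
    i <- 1:(n - l + 1L)
    j <- i + l - 1L
    ij <- cbind(i, j)
    si <- s[i]; sj <- s[j]
    Lm[ij] <- if (l == 1L) lg$loop_end[si]
              else lg$loop_cont[si] + Lm[cbind(i + 1L, j)]
    t1 <- lg$stem_loop + Lm[ij]
    t2 <- if (l >= 3L) lg$stem_pair[cbind(si, sj)] + St[cbind(i + 1L, j - 1L)] else NEG
    t3 <- if (l >= 3L) lg$stem_sym[cbind(si, sj)] + Sy[cbind(i + 1L, j - 1L)] else NEG
    t4 <- if (l >= 2L) lg$stem_asym_l[si] + As[cbind(i + 1L, j)] else NEG
    t5 <- if (l >= 2L) lg$stem_asym_r[sj] + As[cbind(i, j - 1L)] else NEG
    St[ij] <- .plse(t1, t2, t3, t4, t5)
    u1 <- if (l >= 3L) lg$sym_pair[cbind(si, sj)] + Sy[cbind(i + 1L, j - 1L)] else NEG
    Sy[ij] <- .plse(u1, lg$sym_exit + St[ij])
    v1 <- if (l >= 2L) lg$asym_l[si] + As[cbind(i + 1L, j)] else NEG
    v2 <- if (l >= 2L) lg$asym_r[sj] + As[cbind(i, j - 1L)] else NEG
    As[ij] <- .plse(v1, v2, lg$asym_exit + St[ij])
  }
  lp <- St[1L, n]   # S -> Stem with probability 1
  structure(list(log_probability = lp, normalized_score = lp / n, length = n),
            class = "scfg_score")
}

#' Score many sequences under the grammar
#'
#' @param grammar an `scfg_grammar`.
#' @param sequences named (or unnamed) character vector.
#' @param cutoff optional normalized-score cutoff; when given, a `pass`
#'   column (`normalized_score > cutoff`) is added.
#' @return data.table: `id`, `log_probability`, `normalized_score`
#'   (and `pass`).
#' @export
score_sequences <- function(grammar, sequences, cutoff = NULL) {
  ids <- if (is.null(names(sequences))) as.character(seq_along(sequences))
         else names(sequences)
  sc <- lapply(sequences, function(x) inside_log_probability(grammar, x))
  out <- data.table::data.table(
    id = ids,
    log_probability = vapply(sc, `[[`, numeric(1), "log_probability"),
    normalized_score = vapply(sc, `[[`, numeric(1), "normalized_score"))
  if (!is.null(cutoff)) out[, pass := normalized_score > cutoff]
  out[]
}

#' Dinucleotide-preserving shuffle
#'
#' Generates a random sequence with exactly the same dinucleotide (and hence
#' mononucleotide) composition, same first and last base, by the
#' Altschul–Erickson construction: a random Eulerian path over the
#' dinucleotide multigraph, realised by drawing random last-out-edges that
#' form an arborescence into the end vertex.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param sequence ACGT/ACGU string, length >= 3.
#' @return shuffled sequence (same length, DNA alphabet).
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  .check_dna(paste(s, collapse = ""))
  n <- length(s)
  if (n < 3L) return(paste(s, collapse = ""))
  verts <- unique(s)
  edges <- data.frame(from = s[-n], to = s[-1], stringsAsFactors = FALSE)
  last_vertex <- s[n]
  out_edges <- split(edges$to, edges$from)
  # draw last-out-edges forming an arborescence into last_vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last_vertex || is.null(out_edges[[v]])) NA_character_
      else sample(out_edges[[v]], 1L)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last_vertex || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last_vertex) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # per-vertex randomly permuted out-edge lists with the last edge saved for last
  pools <- lapply(setNames(verts, verts), function(v) {
    outs <- out_edges[[v]]
    if (is.null(outs)) return(character(0))
    le <- last_edge[[v]]
    if (!is.na(le)) {
      k <- match(le, outs)
      outs <- outs[-k]
    }
    perm <- if (length(outs) > 1L) sample(outs) else outs
    if (!is.na(le)) c(perm, le) else perm
  })
  used <- setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- s[1]
  cur <- s[1]
  for (t in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- pools[[cur]][used[cur]]
    res[t] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Calibrate the classification cutoff at a target specificity
#'
#' The cutoff is the `target_specificity` quantile of the negative
#' (e.g. dinucleotide-shuffled) normalized scores; a sequence passes when its
#' normalized score strictly exceeds the cutoff.
#'
#' @param grammar an `scfg_grammar`.
#' @param positives,negatives character vectors of sequences.
#' @param target_specificity fraction of negatives that must fail.
#' @return list: `cutoff`, `sensitivity` (fraction of positives passing),
#'   `specificity` (fraction of negatives failing), and the score tables
#'   `positive_scores` / `negative_scores`.
#' @export
calibrate_cutoff <- function(grammar, positives, negatives,
                             target_specificity = 0.95) {
  if (!length(positives) || !length(negatives)) {
    stop("positive and negative sets must be non-empty")
  }
  pos <- score_sequences(grammar, positives)
  neg <- score_sequences(grammar, negatives)
  cutoff <- unname(quantile(neg$normalized_score, target_specificity, type = 7))
  list(cutoff = cutoff,
       sensitivity = mean(pos$normalized_score > cutoff),
       specificity = mean(neg$normalized_score <= cutoff),
       positive_scores = pos, negative_scores = neg)
}

#' Write / read a grammar as YAML
#'
#' Probabilities are serialised as 17-significant-digit strings so the
#' round-trip is lossless.
#'
#' @param grammar an `scfg_grammar`.
#' @param path file path.
#' @return `write_grammar_yaml`: the path, invisibly.
#'   `read_grammar_yaml`: the grammar.
#' @export
write_grammar_yaml <- function(grammar, path) {
  validate_grammar(grammar)
  fmt <- function(x) {
    if (is.matrix(x)) {
      out <- lapply(seq_len(nrow(x)), function(r)
        as.list(setNames(sprintf("%.17g", x[r, ]), colnames(x))))
      setNames(out, rownames(x))
    } else if (length(x) > 1L) {
      as.list(setNames(sprintf("%.17g", x), names(x)))
    } else sprintf("%.17g", x)
  }
  yaml::write_yaml(lapply(unclass(grammar), fmt), path)
  invisible(path)
}

#' @rdname write_grammar_yaml
#' @export
read_grammar_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  unfmt <- function(x) {
    if (is.list(x) && is.list(x[[1]])) {
      m <- do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
      dimnames(m) <- list(names(x), names(x[[1]]))
      m
    } else if (is.list(x)) {
      setNames(as.numeric(unlist(x)), names(x))
    } else as.numeric(x)
  }
  .new_grammar(lapply(raw, unfmt))
}
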