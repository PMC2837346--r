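# Independent reference implementations used only to check the package's
# dynamic programs. They deliberately use different recursions/arithmetic
# than the implementations they verify.

# hit tables as bare data.frames (drops the multimapped attribute)
strip_hits <- function(h) {
  attr(h, "multimapped") <- NULL
  as.data.frame(h)
}

ORACLE_W <- local({
  w <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  w["G", "C"] <- w["C", "G"] <- 3
  w["A", "T"] <- w["T", "A"] <- 2
  w["G", "T"] <- w["T", "G"] <- 1
  w
})

# exhaustive enumeration of all nested structures (leftmost-base recursion,
# no memoisation): maximum weighted pair score
oracle_fold_enum <- function(seq, min_loop = 3) {
  s <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      w <- ORACLE_W[s[i], s[k]]
      if (w > 0) {
        v <- w + rec(i + 1, k - 1) + rec(k + 1, j)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1, length(s))
}

# derivation-enumeration value of the inside probability: direct recursive
# sum over the grammar's productions in probability space
oracle_inside <- function(grammar, seq) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  g <- grammar
  loop_p <- function(i, j) {
    if (i > j) return(0)
    if (i == j) return(g$loop_end[[s[i]]])
    g$loop_cont[[s[i]]] * loop_p(i + 1, j)
  }
  stem_p <- function(i, j) {
    if (i > j) return(0)
    p <- g$stem_loop * loop_p(i, j)
    if (j - i >= 2) {
      p <- p + g$stem_pair[s[i], s[j]] * stem_p(i + 1, j - 1) +
        g$stem_sym[s[i], s[j]] * sym_p(i + 1, j - 1)
    }
    if (j - i >= 1) {
      p <- p + g$stem_asym_l[[s[i]]] * asym_p(i + 1, j) +
        g$stem_asym_r[[s[j]]] * asym_p(i, j - 1)
    }
    p
  }
  sym_p <- function(i, j) {
    if (i > j) return(0)
    p <- g$sym_exit * stem_p(i, j)
    if (j - i >= 2) p <- p + g$sym_pair[s[i], s[j]] * sym_p(i + 1, j - 1)
    p
  }
  asym_p <- function(i, j) {
    if (i > j) return(0)
    p <- g$asym_exit * stem_p(i, j)
    if (j - i >= 1) {
      p <- p + g$asym_l[[s[i]]] * asym_p(i + 1, j) +
        g$asym_r[[s[j]]] * asym_p(i, j - 1)
    }
    p
  }
  stem_p(1, length(s))
}

# brute-force average-linkage agglomeration: cluster-to-cluster distance is
# recomputed each step as the mean over all member pairs
oracle_average_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}
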