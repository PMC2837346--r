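#' @import data.table
#' @importFrom methods is
#' @importFrom stats quantile rbinom runif cor setNames sd rlnorm
#' @importFrom utils head write.table
NULL

BASES <- c("A", "C", "G", "T")

# complement lookup used throughout; U is accepted on input and mapped like T
.COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Reverse complement of DNA/RNA strings
#'
#' Vectorised over `x`; always returns DNA alphabet (U treated as T).
#'
#' @param x character vector of sequences (ACGTUN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(strsplit(toupper(x), ""), function(ch) {
    cc <- .COMP[ch]
    if (anyNA(cc)) stop("non-nucleotide character in sequence")
    paste(rev(cc), collapse = "")
  }, character(1))
}

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTU]", toupper(x))
  if (any(bad)) stop(sprintf("%s contains non-nucleotide characters", what))
  invisible(TRUE)
}

# TRUE for bases that can pair (AU, GC, GU wobble), DNA alphabet
.can_pair <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})

# pair weights: GC 3, AU 2, GU 1 (0 = cannot pair)
.pair_weight <- local({
  m <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "T"] <- m["T", "A"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
})

# random DNA string(s)
.random_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# numerically stable log(sum(exp(x))) for vectors possibly containing -Inf
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 0-based half-open interval overlap width
.overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
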