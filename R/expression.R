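#' Build the miRNA x library relative-proportion matrix
#'
#' Values are read counts divided by the library's total read count —
#' dimensionless relative proportions, the expression unit used for
#' clustering and the top-N reports. Rows that are zero everywhere are
#' dropped; libraries with zero total reads are excluded with a warning.
#'
#' @param counts long count table: `id`, `library_id`, `count` (known
#'   miRNAs and named candidates combined).
#' @param library_totals named numeric vector of total reads per library.
#' @return numeric matrix, rows = miRNA/candidate ids (sorted), columns =
#'   libraries (in `names(library_totals)` order).
#' @export
build_matrix <- function(counts, library_totals) {
  bad <- names(library_totals)[library_totals <= 0]
  if (length(bad)) {
    warning("excluding zero-total libraries: ", paste(bad, collapse = ", "))
    library_totals <- library_totals[library_totals > 0]
  }
  libs <- names(library_totals)
  ids <- sort(unique(counts$id))
  m <- matrix(0, length(ids), length(libs), dimnames = list(ids, libs))
  cc <- counts[counts$library_id %in% libs, ]
  m[cbind(match(cc$id, ids), match(cc$library_id, libs))] <- cc$count
  m <- sweep(m, 2, library_totals, "/")
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Pearson-correlation distance
#'
#' `d = 1 - r`, in [0, 2]. A zero-variance vector has no defined
#' correlation; the distance is set to 1 (uninformative) with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return distance scalar.
#' @export
pearson_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector; Pearson distance set to 1")
    return(1)
  }
  1 - cor(x, y)
}

#' Average-linkage hierarchical clustering of libraries
#'
#' Agglomerative clustering of the matrix columns under the Pearson
#' distance with average (UPGMA) linkage. Tie-breaking is deterministic:
#' among pairs at the minimal distance, the lexicographically smallest
#' (label-sorted) pair merges first. Returns an `hclust` object (so the
#' standard dendrogram tooling applies) plus a Newick string via ape.
#'
#' @param mat expression matrix from [build_matrix()] (>= 2 columns).
#' @return list: `hclust`, `newick`, `merge_heights`.
#' @export
hierarchical_cluster <- function(mat) {
  labels <- colnames(mat)
  n <- length(labels)
  if (n < 2L) stop("clustering needs at least 2 libraries")
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- pearson_distance(mat[, i], mat[, j])
    }
  }
  # active clusters: list of member leaf indices; names track merge ids
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)                 # hclust convention: negatives = leaves
  key <- labels                      # sort key = smallest member label
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  Dc <- D                            # cluster-level distances
  for (s in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        pr <- sort(c(key[i], key[j]))
        cand <- list(d = Dc[i, j], pair = c(i, j), pr = pr)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (cand$pr[1] < best$pr[1] ||
              (cand$pr[1] == best$pr[1] && cand$pr[2] < best$pr[2])))) {
          best <- cand
        }
      }
    }
    i <- best$pair[1]; j <- best$pair[2]
    merge[s, ] <- c(ids[i], ids[j])
    height[s] <- best$d
    ni <- length(members[[i]]); nj <- length(members[[j]])
    # average linkage update against every other cluster
    newd <- (Dc[i, ] * ni + Dc[j, ] * nj) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    Dc <- rbind(cbind(Dc[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    ids <- c(ids[keep], s)
    key <- c(key[keep], min(key[c(i, j)]))
  }
  hc <- structure(list(merge = merge, height = height,
                       order = .hclust_order(merge, n),
                       labels = labels, method = "average",
                       dist.method = "pearson"),
                  class = "hclust")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy), merge_heights = height)
}

# leaf order for plotting: left-to-right traversal of the merge tree
.hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Per-library top-N expression report
#'
#' Ranks rows per library by descending proportion (ties by row id) and
#' reports the union of all listed names.
#'
#' @param mat expression matrix.
#' @param n list depth per library.
#' @return list: `ranks` (data.table: `id`, `library_id`, `rank`,
#'   `proportion`), `union` (sorted ids appearing in any list),
#'   `union_size`.
#' @export
top_n_report <- function(mat, n = 10L) {
  stopifnot(n >= 1L)
  rows <- lapply(colnames(mat), function(l) {
    p <- mat[, l]
    ord <- order(-p, names(p))
    top <- head(ord[p[ord] > 0], n)
    if (!length(top)) return(NULL)
    data.table::data.table(id = names(p)[top], library_id = l,
                           rank = seq_along(top), proportion = p[top])
  })
  ranks <- data.table::rbindlist(rows)
  un <- sort(unique(ranks$id))
  list(ranks = ranks[], union = un, union_size = length(un))
}

#' Union size of an already-ranked top-N table
#'
#' For rank tables transcribed from published reports (miRNA name x library
#' rank): counts the distinct names holding a rank <= n in at least one
#' library.
#'
#' @param rank_table data.frame, first column miRNA names, remaining
#'   columns per-library ranks (NA = not in that library's list).
#' @param n rank cutoff.
#' @return list: `union` (sorted names), `union_size`.
#' @export
rank_table_union <- function(rank_table, n = 10L) {
  nm <- rank_table[[1]]
  rk <- as.matrix(rank_table[, -1, drop = FALSE])
  keep <- apply(rk, 1L, function(r) any(!is.na(r) & r <= n))
  un <- sort(unique(nm[keep]))
  list(union = un, union_size = length(un))
}
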