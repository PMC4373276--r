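#' Cosine similarity
#'
#' `sum(a * b) / (||a|| ||b||)`.  A zero-norm vector (an author map with
#' no significant voxels, say) makes the angle undefined; the score is
#' then 0, with a warning.
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
cosine <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm vector in cosine similarity; returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Match matrix: authors x lattice nodes
#'
#' `C[a, b]` is the cosine similarity between author `a`'s z-map vector
#' and node `b`'s weight vector.  `Z` standardizes C over *all* its
#' entries (pooled mean and sd — the "top 2.5% of all match scores"
#' convention); with `per_node = TRUE` each node's column is
#' standardized separately instead.  Authors whose map has no nonzero
#' voxel get an all-zero row and are listed in the `flagged` field.
#'
#' @param author_maps named list of `label_map`s, or a numeric matrix
#'   with one author z-vector per row.
#' @param lattice a trained `som_lattice` on the same grid.
#' @param per_node standardize per node column instead of pooled.
#' @return a `match_matrix`: list with `authors`, `C`, `Z`, `flagged`.
#' @export
match_matrix <- function(author_maps, lattice, per_node = FALSE) {
  A <- if (is.matrix(author_maps)) author_maps else map_matrix(author_maps)
  if (ncol(A) != ncol(lattice$weights))
    stop("author maps and lattice weights are on different grids")
  authors <- rownames(A) %||% sprintf("author_%03d", seq_len(nrow(A)))
  an <- sqrt(rowSums(A^2))
  wn <- sqrt(rowSums(lattice$weights^2))
  flagged <- authors[an == 0]
  if (length(flagged))
    warning(sprintf("author map(s) with no nonzero voxels: %s",
                    paste(flagged, collapse = ", ")))
  C <- tcrossprod(A, lattice$weights) /
    (ifelse(an == 0, 1, an) %o% ifelse(wn == 0, 1, wn))
  C[an == 0, ] <- 0
  C[, wn == 0] <- 0
  dimnames(C) <- list(authors, NULL)
  Z <- if (per_node) {
    apply(C, 2, function(col) {
      s <- sd(col)
      if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
  } else {
    s <- sd(as.vector(C))
    if (is.na(s) || s == 0) C * 0 else (C - mean(C)) / s
  }
  dimnames(Z) <- dimnames(C)
  structure(list(authors = authors, C = C, Z = Z, flagged = flagged),
            class = "match_matrix")
}

#' Authors most highly matched to a lattice node
#'
#' Authors whose standardized match score at the node exceeds `z_cut`
#' (default 1.96, the top 2.5% of all match scores), ranked by
#' descending raw cosine score and truncated to `cap` (default 50).
#'
#' @param mm a [match_matrix()].
#' @param node node index.
#' @param z_cut standardized-score threshold.
#' @param cap maximum number of matches returned.
#' @return data frame with `author`, `score` (cosine), `z`.
#' @export
top_authors_for_node <- function(mm, node, z_cut = 1.96, cap = 50L) {
  stopifnot(node >= 1, node <= ncol(mm$C))
  hit <- which(mm$Z[, node] > z_cut)
  hit <- hit[order(-mm$C[hit, node], mm$authors[hit])]
  hit <- head(hit, cap)
  data.frame(author = mm$authors[hit], score = unname(mm$C[hit, node]),
             z = unname(mm$Z[hit, node]), stringsAsFactors = FALSE)
}

#' Author-by-author distance matrix
#'
#' Euclidean distances between the rows of C: two authors are close
#' when their whole profiles of node match scores — hence their brain
#' lattices, hence their published activation coordinates — are alike.
#'
#' @param mm a [match_matrix()].
#' @return symmetric numeric matrix with zero diagonal, author
#'   dimnames; class `c("distance_matrix", "matrix")`.
#' @export
distance_matrix <- function(mm) {
  if (length(mm$authors) < 2L) stop("need at least 2 authors")
  M <- as.matrix(dist(mm$C, method = "euclidean"))
  dimnames(M) <- list(mm$authors, mm$authors)
  class(M) <- c("distance_matrix", class(M))
  M
}

#' Ranked list of similar authors
#'
#' The author in question heads the list at distance 0, followed by all
#' other authors in ascending distance (most to least similar); ties
#' break on author id.
#'
#' @param M a [distance_matrix()].
#' @param author author id (must be a row of M).
#' @return data frame with `author` and `distance`.
#' @export
ranked_list <- function(M, author) {
  if (!author %in% rownames(M)) stop(sprintf("unknown author: %s", author))
  d <- M[author, ]
  others <- setdiff(rownames(M), author)
  ord <- others[order(d[others], others)]
  data.frame(author = c(author, ord),
             distance = unname(c(0, d[ord])), stringsAsFactors = FALSE)
}

#' Hierarchical clustering of authors
#'
#' Agglomerative clustering (complete linkage by default) on the
#' author distance matrix, and tree cuts at the interactive thresholds
#' used downstream: a set of heights and a set of group counts.
#'
#' @param M a [distance_matrix()].
#' @param method linkage passed to [stats::hclust()].
#' @return an `hclust` tree.
#' @export
hcluster_authors <- function(M, method = "complete") {
  hclust(stats::as.dist(M), method = method)
}

#' @rdname hcluster_authors
#' @param tree an `hclust` tree.
#' @param heights numeric cut heights (keys `"h:<height>"`).
#' @param ks integer group counts (keys `"k:<k>"`); each must be
#'   at most the number of authors.
#' @return named list of cuts; each cut is a named integer vector
#'   mapping author to group.
#' @export
cut_groups <- function(tree, heights = c(1, 2, 2.5, 3, 3.5, 4),
                       ks = c(5, 10, 15, 20, 25, 30, 50, 60, 70, 80, 90, 100)) {
  n <- length(tree$order)
  if (any(ks > n)) stop(sprintf("k larger than the %d authors in the tree", n))
  cuts <- c(
    stats::setNames(lapply(heights, function(h) cutree(tree, h = h)),
                    sprintf("h:%g", heights)),
    stats::setNames(lapply(ks, function(k) cutree(tree, k = k)),
                    sprintf("k:%d", ks)))
  cuts
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (together in
#' both or apart in both); 1 means identical grouping.  Used to score
#' recovery of planted author cohorts.
#'
#' @param a,b partition labels over the same items (equal length).
#' @return scalar in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
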