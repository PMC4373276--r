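#' Joint-paper counts over PI pairs
#'
#' Counts, for every unordered pair of roster PIs, the number of
#' studies on which both appear.  Single-author papers and pairs
#' involving non-PIs contribute nothing.
#'
#' @param tables a [corpus_tables()] object.
#' @param roster a [extract_pis()] roster.
#' @return data frame with `pi_a`, `pi_b` (with `pi_a < pi_b`) and
#'   `n_joint`, sorted by pair; pairs with zero joint papers omitted.
#' @export
pair_counts <- function(tables, roster) {
  if (!length(roster$pis)) stop("empty PI roster")
  au <- tables$authorship
  au <- au[au$author %in% roster$pis, , drop = FALSE]
  pair_key <- character(0)
  for (ids in split(au$author, au$study_id)) {
    ids <- sort(unique(ids))
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2L)
    pair_key <- c(pair_key, paste(cmb[1, ], cmb[2, ], sep = "\r"))
  }
  if (!length(pair_key))
    return(data.frame(pi_a = character(0), pi_b = character(0),
                      n_joint = integer(0), stringsAsFactors = FALSE))
  tab <- table(pair_key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(pi_a = vapply(parts, `[`, "", 1L),
                    pi_b = vapply(parts, `[`, "", 2L),
                    n_joint = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$pi_a, out$pi_b), , drop = FALSE]
}

#' Build the PI collaboration network
#'
#' One node per roster PI (isolates retained); an edge between two PIs
#' whenever their joint-paper count reaches `threshold` (default 2 —
#' "two or more publications together").  Similarity-group labels, if
#' supplied, are attached to nodes; PIs without a group get the
#' sentinel group 0.
#'
#' @param counts output of [pair_counts()].
#' @param roster a [extract_pis()] roster.
#' @param threshold minimum joint-paper count for an edge (>= 1).
#' @param groups optional named vector mapping author to group id (e.g.
#'   one cut from [cut_groups()]).
#' @return a `collab_network`: list with `nodes` (data frame `id`,
#'   `group`) and `edges` (data frame `pi_a`, `pi_b`, `n_joint`).
#' @export
build_network <- function(counts, roster, threshold = 2L, groups = NULL) {
  stopifnot(threshold >= 1)
  grp <- function(ids) {
    if (is.null(groups)) rep(0L, length(ids))
    else {
      g <- groups[ids]
      ifelse(is.na(g), 0L, as.integer(g))
    }
  }
  nodes <- data.frame(id = sort(roster$pis), stringsAsFactors = FALSE)
  nodes$group <- grp(nodes$id)
  edges <- counts[counts$n_joint >= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = as.integer(threshold)),
            class = "collab_network")
}

#' @export
print.collab_network <- function(x, ...) {
  cat(sprintf("<collab_network> %d PI nodes, %d edges (>= %d joint papers)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Collaboration score along a ranked similarity list
#'
#' At rank r of an author's ranked similar-author list (the author
#' itself, rank 0, excluded), the percentage of the top r entries the
#' author has actually co-published with.
#'
#' @param ranked a [ranked_list()] data frame (self in row 1) or a
#'   character vector of ranked authors with self first.
#' @param collaborators character vector of the focal author's actual
#'   collaborators.
#' @param rank position(s) at which to evaluate (1-based, excluding
#'   self); rank 0 is an error.
#' @return percentage(s) in \[0, 100\].
#' @export
collaboration_score <- function(ranked, collaborators, rank) {
  authors <- if (is.data.frame(ranked)) ranked$author else as.character(ranked)
  others <- authors[-1]                       # drop self at the top
  if (any(rank < 1) || any(rank > length(others)))
    stop(sprintf("rank must be in 1..%d (0 is the author itself)", length(others)))
  flags <- others %in% collaborators
  cum <- cumsum(flags)
  100 * cum[rank] / rank
}

#' Collaborators of one PI at the network's edge rule
#' @param net a [build_network()] network.
#' @param author PI id.
#' @return character vector of PIs sharing an edge with `author`.
#' @export
collaborators_of <- function(net, author) {
  e <- net$edges
  sort(unique(c(e$pi_b[e$pi_a == author], e$pi_a[e$pi_b == author])))
}

#' Fraction of edges whose endpoints share a similarity group
#'
#' A diagnostic for the "small same-color connected cluster" reading of
#' the colored network: high values mean researchers with similar
#' published work are actually working together.
#'
#' @param net a [build_network()] network with group labels attached.
#' @return scalar in \[0, 1\]; `NA` if the network has no edges.
#' @export
same_group_edge_fraction <- function(net) {
  if (!nrow(net$edges)) return(NA_real_)
  g <- stats::setNames(net$nodes$group, net$nodes$id)
  mean(g[net$edges$pi_a] == g[net$edges$pi_b])
}

#' Export / import the network as force-directed-graph JSON
#'
#' The d3 force-layout dialect: `{"nodes": [{"id", "group"}],
#' "links": [{"source", "target", "value"}]}` with stable (sorted)
#' ordering; `value` is the joint-paper count.  `read_d3()` inverts it.
#'
#' @param net a `collab_network`.
#' @param path output JSON path.
#' @export
export_d3 <- function(net, path) {
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i)
    list(id = net$nodes$id[i], group = net$nodes$group[i]))
  links <- lapply(seq_len(nrow(net$edges)), function(i)
    list(source = net$edges$pi_a[i], target = net$edges$pi_b[i],
         value = net$edges$n_joint[i]))
  jsonlite::write_json(list(nodes = nodes, links = links), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_d3
#' @export
read_d3 <- function(path) {
  x <- jsonlite::read_json(path)
  nodes <- data.frame(
    id = vapply(x$nodes, function(n) n$id, ""),
    group = vapply(x$nodes, function(n) as.integer(n$group), 0L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    pi_a = vapply(x$links, function(l) l$source, ""),
    pi_b = vapply(x$links, function(l) l$target, ""),
    n_joint = vapply(x$links, function(l) as.integer(l$value), 0L),
    stringsAsFactors = FALSE)
  if (!nrow(nodes)) nodes <- data.frame(id = character(0), group = integer(0))
  if (!nrow(edges)) edges <- data.frame(pi_a = character(0), pi_b = character(0),
                                        n_joint = integer(0))
  structure(list(nodes = nodes, edges = edges, threshold = NA_integer_),
            class = "collab_network")
}

#' Write the edge list as TSV
#' @param net a `collab_network`.
#' @param path output TSV path.
#' @export
write_edgelist <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
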