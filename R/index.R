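#' Build the generalized pair index
#'
#' Indexes a reference sequence together with an (optionally extended)
#' target: a generalized suffix array over the integer-coded concatenation,
#' its lcp-interval tree (the internal nodes of the generalized suffix
#' tree), per-node colors (which host sequences reach the node), matching
#' statistics per position, the lowest both-colored ancestor of every
#' suffix, irredundancy flags and `prec` links to the closest irredundant
#' ancestor.  All discovery and selection stages query this object.
#'
#' @param s1 Reference `genome_sequence`.
#' @param s2x Target: a `genome_sequence` (direct matching only) or an
#'   `extended_sequence` from [build_extended()].
#' @return An object of class `pair_index`.
#' @examples
#' idx <- build_index(genome_sequence("a", "ACACGTAC"),
#'                    genome_sequence("b", "TACGTGTA"))
#' length(bicolor_nodes(idx))
#' @export
build_index <- function(s1, s2x) {
  ap <- .assemble_pair(s1, s2x)
  core <- cpp_pair_index(ap$x, ap$n1)
  structure(
    c(core,
      list(x = ap$x, chars = ap$chars, s1 = s1, s2x = ap$s2x,
           off2 = ap$off2)),
    class = "pair_index")
}

#' @export
print.pair_index <- function(x, ...) {
  cat(sprintf(
    "<pair_index> %s (n=%d) vs %s (extended length %d); %d nodes, %d irredundant\n",
    x$s1$label, x$n1, x$s2x$source$label, x$s2x$n,
    length(x$node_depth), sum(x$node_irred)))
  invisible(x)
}

#' Nodes colored by both input sequences
#'
#' @param idx A `pair_index`.
#' @return Integer vector of node ids (0-based) with string depth >= 1 whose
#'   suffix-array interval contains suffixes of both hosts; each spells a
#'   common subword of the pair.
#' @export
bicolor_nodes <- function(idx) {
  stopifnot(inherits(idx, "pair_index"))
  which(idx$node_bicolor & idx$node_depth >= 1L) - 1L
}

#' Word spelled by an index node
#'
#' @param idx A `pair_index`.
#' @param node Node id (0-based).
#' @return Character scalar.
#' @export
node_word <- function(idx, node) {
  stopifnot(inherits(idx, "pair_index"))
  d <- idx$node_depth[node + 1L]
  if (d == 0L) return("")
  p <- idx$sa[idx$node_lb[node + 1L] + 1L]  # witness suffix
  paste(idx$chars[(p + 1L):(p + d)], collapse = "")
}

#' Find the index node spelling a given word
#'
#' @param idx A `pair_index`.
#' @param word Character scalar.
#' @return Node id (0-based) or `NA` if no node spells `word`.
#' @export
find_node <- function(idx, word) {
  stopifnot(inherits(idx, "pair_index"))
  len <- nchar(word)
  cand <- which(idx$node_depth == len) - 1L
  for (v in cand) if (node_word(idx, v) == word) return(v)
  NA_integer_
}

#' Deepest ancestor with bounded string depth
#'
#' Walks the parent links from `node` until the string depth is at most
#' `d`.  This answers the weighted-ancestor queries of the selection stage;
#' a simple parent walk is exact and sufficient at desk scale.
#'
#' @param idx A `pair_index`.
#' @param node Node id (0-based).
#' @param d Maximum string depth.
#' @return Node id of the deepest ancestor (possibly `node` itself, possibly
#'   the root, id 0) whose depth is `<= d`.
#' @export
ancestor_with_depth_at_most <- function(idx, node, d) {
  stopifnot(inherits(idx, "pair_index"))
  v <- node
  while (idx$node_depth[v + 1L] > d) {
    v <- idx$node_parent[v + 1L]
    if (v < 0L) return(0L)
  }
  v
}

#' Lowest both-colored ancestor of a suffix
#'
#' @param idx A `pair_index`.
#' @param host `"s1"` or `"s2"` (the extended target).
#' @param pos 0-based start coordinate of the suffix within the host.
#' @return List with `node` (id, or `NA` when the suffix shares no prefix
#'   with the other host) and `length` (its string depth, the matching
#'   statistic at `pos`).
#' @export
lowest_bicolor_ancestor <- function(idx, host = c("s1", "s2"), pos) {
  stopifnot(inherits(idx, "pair_index"))
  host <- match.arg(host)
  p <- if (host == "s1") pos else idx$off2 + pos
  v <- idx$leaf_node[p + 1L]
  list(node = if (v < 0L) NA_integer_ else v, length = idx$ms[p + 1L])
}

# all occurrences (0-based start positions) of the word spelled by `node`,
# split by host; occurrences are the leaves of the node's subtree interval
.node_occurrences <- function(idx, node) {
  lb <- idx$node_lb[node + 1L]
  rb <- idx$node_rb[node + 1L]
  pos <- idx$sa[(lb + 1L):(rb + 1L)]
  occ1 <- sort(pos[pos < idx$n1])
  occ2 <- sort(pos[pos >= idx$off2 & pos < idx$N - 1L]) - idx$off2
  list(s1 = occ1, s2 = occ2)
}
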