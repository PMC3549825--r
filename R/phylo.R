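#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration, made deterministic: ties in the
#' Q-criterion are broken by the lowest index pair (row-major over the
#' current matrix, merged nodes appended last), and negative branch-length
#' estimates are clamped to zero with the deficit transferred to the sibling
#' branch, mirroring the behavior of the PHYLIP neighbor program.
#'
#' @param D Square symmetric numeric matrix with zero diagonal, dimnames set,
#'   at least 3 taxa, no missing values.
#' @return An unrooted `phylo` tree (package \pkg{ape}) with branch lengths.
#' @examples
#' D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' neighbor_joining(D)
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (anyNA(D) || any(!is.finite(D))) stop("D contains NA/NaN/Inf")
  if (max(abs(D - t(D))) > 1e-8) stop("D is not symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("D must carry taxon names as dimnames")

  frag <- labels  # newick fragment per active node
  d <- D
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Q[i, j] < qmin - 1e-12) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[[1L]]; j <- best[[2L]]
    li <- d[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[[i]], li, frag[[j]], lj)
    others <- setdiff(seq_len(m), c(i, j))
    dn <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d2 <- rbind(cbind(d[others, others, drop = FALSE], dn), c(dn, 0))
    d <- d2
    frag <- c(frag[others], newfrag)
  }
  # final three nodes: the unique star resolution
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[[1L]], l1, frag[[2L]], l2, frag[[3L]], l3)
  ape::read.tree(text = nwk)
}

# non-trivial bipartitions of an unrooted tree as canonical label strings
.tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  tips <- vector("list", n + nnode)
  for (i in seq_len(n)) tips[[i]] <- tree$tip.label[[i]]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    pa <- edges[e, 1L]; ch <- edges[e, 2L]
    tips[[pa]] <- c(tips[[pa]], tips[[ch]])
  }
  ref <- min(tree$tip.label)  # canonical side: the one without `ref`
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    ch <- edges[e, 2L]
    if (ch <= n) next  # trivial split
    side <- sort(tips[[ch]])
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds symmetric difference between two unrooted trees
#'
#' Number of non-trivial bipartitions present in exactly one of the trees.
#' 0 means the topologies are isomorphic; for binary trees on n leaves the
#' maximum is 2n - 6.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return Integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- .tree_splits(t1)
  s2 <- .tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# depth (edges from the root) of every node of a rooted tree
.node_depths <- function(tree) {
  n <- length(tree$tip.label)
  depth <- integer(n + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord)))
    depth[ord[e, 2L]] <- depth[ord[e, 1L]] + 1L
  depth
}

# rooted resolution of each leaf triple: 1 = ab|c, 2 = ac|b, 3 = bc|a,
# 0 = unresolved (star)
.triplet_classes <- function(tree, labels) {
  M <- ape::mrca(tree)
  M <- M[labels, labels]
  depth <- .node_depths(tree)
  combs <- utils::combn(length(labels), 3L)
  cls <- integer(ncol(combs))
  for (t in seq_len(ncol(combs))) {
    a <- combs[1L, t]; b <- combs[2L, t]; c <- combs[3L, t]
    dd <- c(depth[M[a, b]], depth[M[a, c]], depth[M[b, c]])
    mx <- max(dd)
    cls[[t]] <- if (sum(dd == mx) == 1L) which.max(dd) else 0L
  }
  cls
}

#' Triplet distance between two trees
#'
#' Fraction of 3-leaf subsets whose rooted resolution differs, computed by
#' explicit enumeration of all C(n, 3) triples.  Unrooted inputs are rooted
#' first by the chosen policy (applied identically to both trees); a triple
#' left unresolved in one tree but resolved in the other counts as
#' different.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @param rooting `"midpoint"` (default; requires branch lengths),
#'   `"outgroup"` (requires `outgroup`), or `"asis"` (trees already rooted).
#' @param outgroup Tip label used when `rooting = "outgroup"`.
#' @return Numeric in \[0, 1\].
#' @export
triplet_distance <- function(t1, t2,
                             rooting = c("midpoint", "outgroup", "asis"),
                             outgroup = NULL) {
  rooting <- match.arg(rooting)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  root1 <- function(tr) {
    switch(rooting,
           midpoint = {
             if (is.null(tr$edge.length))
               stop("midpoint rooting needs branch lengths")
             phangorn::midpoint(tr)
           },
           outgroup = ape::root(tr, outgroup = outgroup,
                                resolve.root = TRUE),
           asis = {
             if (!ape::is.rooted(tr)) stop("tree is not rooted")
             tr
           })
  }
  r1 <- root1(t1)
  r2 <- root1(t2)
  labels <- sort(t1$tip.label)
  mean(.triplet_classes(r1, labels) != .triplet_classes(r2, labels))
}
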