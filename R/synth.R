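# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-genome generator
#'
#' Describes a family of genomes evolved along a known tree: a root sequence
#' drawn i.i.d. at the requested GC content, per-site substitutions applied
#' on every branch, and segmental inversion / complement events planted so
#' the extended matching mode has true signal to find.  Defaults emulate a
#' small bacterial-scale test family: 8 taxa, 5 kb genomes, 2% per-branch
#' substitution rate, one inversion and one complement event of 100-500 bp
#' per branch.
#'
#' @param seed Integer; identical seed + config gives identical output.
#' @param n_leaves Number of taxa (>= 3 for phylogeny use).
#' @param tree_shape `"random"`, `"balanced"` (n_leaves a power of 2) or
#'   `"caterpillar"`.
#' @param root_length Root genome length in bases.
#' @param substitution_rate Per-site substitution probability per branch,
#'   in \[0, 1\].
#' @param inversions Number of segmental inversion events per branch.
#' @param inversion_length Length range (min, max) of inversion events.
#' @param complements Number of segmental complement events per branch.
#' @param complement_length Length range of complement events.
#' @param gc_content GC fraction of the root sequence, in \[0, 1\].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_leaves = 8L,
                              tree_shape = c("random", "balanced",
                                             "caterpillar"),
                              root_length = 5000L,
                              substitution_rate = 0.02,
                              inversions = 1L,
                              inversion_length = c(100L, 500L),
                              complements = 1L,
                              complement_length = c(100L, 500L),
                              gc_content = 0.5) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            gc_content >= 0, gc_content <= 1,
            root_length >= 1, n_leaves >= 2,
            inversions >= 0, complements >= 0,
            length(inversion_length) == 2L, all(inversion_length >= 1L),
            length(complement_length) == 2L, all(complement_length >= 1L))
  structure(list(seed = as.integer(seed), n_leaves = as.integer(n_leaves),
                 tree_shape = tree_shape,
                 root_length = as.integer(root_length),
                 substitution_rate = substitution_rate,
                 inversions = as.integer(inversions),
                 inversion_length = as.integer(inversion_length),
                 complements = as.integer(complements),
                 complement_length = as.integer(complement_length),
                 gc_content = gc_content),
            class = "simulation_config")
}

.caterpillar_newick <- function(labels) {
  nwk <- sprintf("(%s,%s)", labels[[1L]], labels[[2L]])
  for (i in seq_along(labels)[-(1:2)]) nwk <- sprintf("(%s,%s)", nwk,
                                                      labels[[i]])
  paste0(nwk, ";")
}

.balanced_newick <- function(labels) {
  k <- length(labels)
  if (bitwAnd(k, k - 1L) != 0L)
    stop("balanced shape needs a power-of-two leaf count")
  build <- function(lab) {
    if (length(lab) == 1L) return(lab)
    h <- length(lab) / 2L
    sprintf("(%s,%s)", build(lab[seq_len(h)]), build(lab[-seq_len(h)]))
  }
  paste0(build(labels), ";")
}

.make_topology <- function(cfg) {
  labels <- paste0("t", seq_len(cfg$n_leaves))
  switch(cfg$tree_shape,
         random = {
           tr <- ape::rtree(cfg$n_leaves, tip.label = labels, br = NULL)
           tr
         },
         balanced = ape::read.tree(text = .balanced_newick(labels)),
         caterpillar = ape::read.tree(text = .caterpillar_newick(labels)))
}

.mutate_codes <- function(codes, rate) {
  if (rate <= 0) return(codes)
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit) > 0L) {
    # replacement drawn uniformly from the three alternative bases
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
  }
  codes
}

.segment_event <- function(codes, len_range, kind) {
  n <- length(codes)
  len <- if (len_range[[1L]] == len_range[[2L]]) len_range[[1L]]
         else sample(seq.int(len_range[[1L]], len_range[[2L]]), 1L)
  len <- min(n, len)
  start <- sample.int(n - len + 1L, 1L)
  seg <- codes[start:(start + len - 1L)]
  seg <- switch(kind,
                inversion = rev(seg),
                complement = .COMP[seg])
  codes[start:(start + len - 1L)] <- seg
  codes
}

#' Evolve a genome family along a tree
#'
#' Draws a root sequence and walks the tree in preorder: each child copies
#' its parent, applies per-site substitutions at the branch rate, then the
#' configured segmental inversion and complement events.  Only leaf
#' sequences are returned, together with the generating topology.
#'
#' @param cfg A [simulation_config()].
#' @return List with `sequences` (named list of `genome_sequence`), `tree`
#'   (the rooted true topology, no branch lengths) and `config`.
#' @examples
#' fam <- evolve_along_tree(simulation_config(seed = 1, n_leaves = 4,
#'                                            root_length = 200))
#' names(fam$sequences)
#' @export
evolve_along_tree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    tree <- .make_topology(cfg)
    n <- length(tree$tip.label)
    probs <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
               cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
    root_codes <- sample.int(4L, cfg$root_length, replace = TRUE,
                             prob = probs)
    nodeseq <- vector("list", n + tree$Nnode)
    root <- n + 1L
    nodeseq[[root]] <- root_codes
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    for (e in seq_len(nrow(ord))) {
      pa <- ord[e, 1L]; ch <- ord[e, 2L]
      codes <- .mutate_codes(nodeseq[[pa]], cfg$substitution_rate)
      for (k in seq_len(cfg$inversions))
        codes <- .segment_event(codes, cfg$inversion_length, "inversion")
      for (k in seq_len(cfg$complements))
        codes <- .segment_event(codes, cfg$complement_length, "complement")
      nodeseq[[ch]] <- codes
    }
    seqs <- vector("list", n)
    bases <- names(.BASES)
    for (i in seq_len(n)) {
      seqs[[i]] <- genome_sequence(tree$tip.label[[i]],
                                   paste(bases[nodeseq[[i]]], collapse = ""))
    }
    names(seqs) <- tree$tip.label
    list(sequences = seqs, tree = tree, config = cfg)
  })
}
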