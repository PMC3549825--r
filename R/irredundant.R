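#' Discover the irredundant common subwords of a pair
#'
#' A common subword is irredundant when at least one of its occurrences (in
#' either sequence) is not covered by an occurrence of another common
#' subword.  Discovery runs in two phases on the pair index: first, every
#' suffix contributes its lowest both-colored ancestor as a right-maximal
#' occurrence; second, an occurrence at position i is also left-maximal when
#' the matching statistic does not drop from position i - 1 (position 1 is
#' always left-maximal).  Words retaining at least one occurrence that is
#' both right- and left-maximal form the irredundant set; its cardinality is
#' bounded by n + m.  The rule is applied symmetrically to occurrences in
#' both hosts.
#'
#' @param s1 Reference `genome_sequence`, or a prebuilt `pair_index` (in
#'   which case `s2x` is ignored).
#' @param s2x Target `genome_sequence` or `extended_sequence`.
#' @param detail Materialize the word string, full occurrence lists and
#'   match classes of every member (the default).  Distance computations
#'   only need lengths and node ids; they pass `FALSE` to skip this work on
#'   genome-sized inputs.
#' @return An object of class `common_subwords`: a list of members, each
#'   with `word`, `length`, `node` (index node id), `occ_s1` / `occ_s2`
#'   (all 0-based occurrence starts per host, target occurrences in extended
#'   coordinates), `class_s2` (match class per target occurrence) and
#'   `first_occ` (priority tie-break key).  The `pair_index` is attached as
#'   attribute `index`.
#' @examples
#' irr <- find_irredundant(genome_sequence("a", "ACGT"),
#'                         genome_sequence("b", "ACGT"))
#' vapply(irr, `[[`, "", "word")
#' @export
find_irredundant <- function(s1, s2x = NULL, detail = TRUE) {
  idx <- if (inherits(s1, "pair_index")) s1 else build_index(s1, s2x)
  nodes <- which(idx$node_irred) - 1L
  lens <- idx$node_depth[nodes + 1L]
  firsts <- idx$node_first[nodes + 1L]
  members <- vector("list", length(nodes))
  if (detail) {
    text <- paste(idx$chars, collapse = "")
    wit <- idx$sa[idx$node_lb[nodes + 1L] + 1L]  # witness suffix per node
    words <- substring(text, wit + 1L, wit + lens)
    for (i in seq_along(nodes)) {
      v <- nodes[[i]]
      occ <- .node_occurrences(idx, v)
      members[[i]] <- list(
        word = words[[i]],
        length = lens[[i]],
        node = v,
        occ_s1 = occ$s1,
        occ_s2 = occ$s2,
        class_s2 = classify_position(idx$s2x, occ$s2),
        first_occ = firsts[[i]])
    }
  } else {
    for (i in seq_along(nodes)) {
      members[[i]] <- list(word = NULL, length = lens[[i]],
                           node = nodes[[i]], first_occ = firsts[[i]])
    }
  }
  structure(members, class = "common_subwords", index = idx, sorted = FALSE)
}

#' @export
print.common_subwords <- function(x, ...) {
  cat(sprintf("<common_subwords> %d irredundant members\n", length(x)))
  if (length(x) > 0L) {
    show <- utils::head(x, 5L)
    for (w in show)
      cat(sprintf("  %-20s len=%d occ_s1=%d occ_s2=%d\n",
                  if (nchar(w$word) > 20L) paste0(substr(w$word, 1, 17), "...")
                  else w$word,
                  w$length, length(w$occ_s1), length(w$occ_s2)))
    if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  }
  invisible(x)
}
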