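#' Rank common subwords by the selection priority
#'
#' A word `w` has priority over `w'` when it is strictly longer, or when
#' both have the same length and the earliest occurrence of `w` (scanning
#' the reference first, then the extended target) comes first.  Two distinct
#' words can never share both keys, so the order is total and the selection
#' below is deterministic.
#'
#' @param subwords A `common_subwords` set.
#' @return The same set, reordered, with attribute `sorted = TRUE`.
#' @export
priority_sort <- function(subwords) {
  stopifnot(inherits(subwords, "common_subwords"))
  lens <- vapply(subwords, `[[`, integer(1), "length")
  firsts <- vapply(subwords, `[[`, integer(1), "first_occ")
  ord <- order(-lens, firsts)
  structure(unclass(subwords)[ord], class = "common_subwords",
            index = attr(subwords, "index"), sorted = TRUE)
}

.priority_is_sorted <- function(subwords) {
  lens <- vapply(subwords, `[[`, integer(1), "length")
  firsts <- vapply(subwords, `[[`, integer(1), "first_occ")
  key <- order(-lens, firsts)
  all(key == seq_along(subwords))
}

#' Select the underlying subwords
#'
#' Walks the priority-sorted irredundant subwords and keeps, for each, the
#' occurrences untied from (non-overlapping with) every untied occurrence of
#' previously accepted words; a word enters the underlying set only if it
#' retains at least one untied occurrence in each sequence (quorum 2, one
#' per sequence).  Coverage is tracked per host with a boolean vector Gamma
#' and a length table chi; because words are processed longest-first, an
#' occurrence only needs to be tested at its two endpoints.  Occurrences
#' whose start is free but whose end is already covered are re-queued for
#' the longest irredundant ancestor prefix of length at most
#' d = |w| - chi\[i + |w| - 1\].  Untied occurrences of accepted words are
#' pairwise disjoint within each host, and their total length cannot exceed
#' the host length.
#'
#' @param subwords A priority-sorted `common_subwords` set (see
#'   [priority_sort()]); unsorted input is an error.
#' @return An object of class `underlying_set`: a list of members in
#'   selection order, each with `word`, `length`, `rank`, untied occurrence
#'   starts `untied_s1` / `untied_s2` (0-based; target in extended
#'   coordinates), `class_s2` (match class per target occurrence) and the
#'   counts `h_s1`, `h_s2` of untied occurrences per host.  Attributes:
#'   `n1`, `n2_source`, `labels`, `mode`.
#' @examples
#' s <- genome_sequence("a", "ACGTACGTAC")
#' u <- select_underlying(priority_sort(find_irredundant(s, s)))
#' u[[1]]$word
#' @export
select_underlying <- function(subwords) {
  stopifnot(inherits(subwords, "common_subwords"))
  idx <- attr(subwords, "index")
  if (is.null(idx)) stop("subwords carry no pair index")
  if (!.priority_is_sorted(subwords))
    stop("subwords are not priority-sorted; call priority_sort() first")
  ord <- vapply(subwords, `[[`, integer(1), "node")
  sel <- cpp_select_underlying(idx$node_depth, idx$node_prec, idx$leaf_prec,
                               idx$n1, idx$N, ord)
  text <- paste(idx$chars, collapse = "")
  members <- vector("list", length(sel$sel))
  for (m in seq_along(sel$sel)) {
    v <- sel$sel[[m]]
    pos <- sel$untied[[m]]
    u1 <- pos[pos < idx$n1]
    u2 <- pos[pos >= idx$off2] - idx$off2
    wit <- idx$sa[idx$node_lb[v + 1L] + 1L]
    members[[m]] <- list(
      word = substring(text, wit + 1L, wit + idx$node_depth[v + 1L]),
      length = idx$node_depth[v + 1L],
      node = v,
      rank = m,
      untied_s1 = u1,
      untied_s2 = u2,
      class_s2 = classify_position(idx$s2x, u2),
      h_s1 = length(u1),
      h_s2 = length(u2))
  }
  structure(members,
            class = "underlying_set",
            n1 = idx$n1,
            n2_source = idx$s2x$n_source,
            labels = c(idx$s1$label, idx$s2x$source$label),
            mode = if (nrow(idx$s2x$segments) > 1L) "extended" else "direct")
}

#' Compute the underlying set of a sequence pair in one call
#'
#' Convenience wrapper: builds the (optionally extended) target, the pair
#' index, discovers the irredundant common subwords, ranks them and selects
#' the underlying subwords.
#'
#' @param s1 Reference `genome_sequence`.
#' @param s2 Target `genome_sequence`.
#' @param mode `"extended"` (direct + inversion + complement matches, the
#'   default) or `"direct"`.
#' @param include_revcomp Forwarded to [build_extended()] in extended mode.
#' @return An `underlying_set`.
#' @export
underlying_set <- function(s1, s2, mode = c("extended", "direct"),
                           include_revcomp = FALSE) {
  mode <- match.arg(mode)
  s2x <- if (mode == "extended") build_extended(s2, include_revcomp) else s2
  select_underlying(priority_sort(find_irredundant(s1, s2x,
                                                   detail = FALSE)))
}

#' @export
print.underlying_set <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("<underlying_set> U(%s, %s), %s mode: %d members\n",
              lab[[1L]], lab[[2L]], attr(x, "mode"), length(x)))
  for (w in utils::head(x, 5L))
    cat(sprintf("  #%d %-20s len=%d h_s1=%d h_s2=%d\n", w$rank,
                if (nchar(w$word) > 20L) paste0(substr(w$word, 1, 17), "...")
                else w$word,
                w$length, w$h_s1, w$h_s2))
  if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}
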