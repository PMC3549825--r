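#' Matching statistics of a reference against a target
#'
#' For every position `i` of the reference, the length of the longest
#' subword starting at `i` that occurs anywhere in the target (within a
#' single segment when the target is extended).  Positions holding a
#' sentinel (ambiguity character) get 0 by construction.
#'
#' @param s1 Reference `genome_sequence`.
#' @param s2 Target `genome_sequence` or `extended_sequence`.
#' @return An object of class `matching_stats`: list with `label` and
#'   integer `values` (1-based positions along the reference).
#' @examples
#' ms <- matching_statistics(genome_sequence("s1", "ACACGTAC"),
#'                           genome_sequence("s2", "TACGTGTA"))
#' ms$values  # 2 1 4 3 3 3 2 1
#' @export
matching_statistics <- function(s1, s2) {
  ap <- .assemble_pair(s1, s2)
  ms <- cpp_ms_only(ap$x, ap$n1)
  structure(list(label = s1$label, values = ms[seq_len(ap$n1)]),
            class = "matching_stats")
}

#' @export
print.matching_stats <- function(x, ...) {
  cat(sprintf("<matching_stats> %s: ", x$label))
  cat(x$values, sep = " ")
  cat("\n")
  invisible(x)
}

#' Reconstruct matching statistics from irredundant common subwords
#'
#' Superimposes, over every reference occurrence of every subword, the
#' suffix-length score vector l_w\[j\] = |w| - j + 1 and takes the
#' per-position maximum.  When `subwords` is the full irredundant set of the
#' pair this reproduces [matching_statistics()] exactly; the identity is the
#' structural property the discovery stage is built on.
#'
#' @param subwords A `common_subwords` set (see [find_irredundant()]).
#' @param s1 The reference `genome_sequence` the set was computed for.
#' @return A `matching_stats` object.
#' @export
ms_from_subwords <- function(subwords, s1) {
  stopifnot(inherits(subwords, "common_subwords"),
            inherits(s1, "genome_sequence"))
  vals <- integer(s1$n)
  for (w in subwords) {
    L <- w$length
    score <- L:1L
    for (k in w$occ_s1) {  # 0-based starts
      rng <- (k + 1L):(k + L)
      vals[rng] <- pmax(vals[rng], score)
    }
  }
  structure(list(label = s1$label, values = vals), class = "matching_stats")
}

#' Average common subword similarity
#'
#' Mean of the matching-statistics vector of `s1` against `s2` (the ACS
#' similarity).  For a self-comparison of a sequence of length n this equals
#' (n + 1) / 2.
#'
#' @inheritParams matching_statistics
#' @return Numeric scalar.
#' @export
acs_similarity <- function(s1, s2) {
  mean(matching_statistics(s1, s2)$values)
}
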