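#' UA similarity of an underlying set
#'
#' Each member contributes h_w * |w| * (|w| + 1) / 2, where h_w counts its
#' untied occurrences in the reference; the sum is averaged over the
#' reference length.  For a self-comparison the underlying set is the
#' sequence itself, giving UA(s, s) = (|s| + 1) / 2.
#'
#' @param U An `underlying_set`.
#' @return Numeric scalar.
#' @export
ua_similarity <- function(U) {
  stopifnot(inherits(U, "underlying_set"))
  n1 <- attr(U, "n1")
  if (length(U) == 0L) return(0)
  h <- vapply(U, `[[`, integer(1), "h_s1")
  L <- vapply(U, `[[`, numeric(1), "length")
  sum(h * L * (L + 1) / 2) / n1
}

.log4 <- function(x) log(x) / log(4)

#' Directed, normalized UA dissimilarity
#'
#' log4(|s2|) / UA(s1, s2) - 2 log4(|s1|) / (|s1| + 1).  The base-4
#' logarithm reflects the four-letter DNA alphabet; the correction term is
#' log4(|s1|) / UA(s1, s1) and makes the self-dissimilarity exactly zero.
#' `|s2|` is the original (not extended) target length.
#'
#' @param s1,s2 `genome_sequence` objects.
#' @param mode Matching mode, see [underlying_set()].
#' @param U Optional precomputed `underlying_set` for (`s1`, `s2`).
#' @return Numeric scalar; `NA` when the pair shares no underlying subword
#'   (incomparable pair) -- [distance_matrix()] substitutes a finite ceiling.
#' @export
ua_normalized <- function(s1, s2, mode = c("extended", "direct"), U = NULL) {
  mode <- match.arg(mode)
  if (is.null(U)) U <- underlying_set(s1, s2, mode)
  stopifnot(attr(U, "n1") == s1$n)
  ua <- ua_similarity(U)
  if (ua == 0) return(NA_real_)
  .log4(s2$n) / ua - 2 * .log4(s1$n) / (s1$n + 1)
}

#' Symmetric UA distance between two genomes
#'
#' Arithmetic mean of the two directed dissimilarities; symmetric by
#' construction and exactly zero on identical inputs.
#'
#' @inheritParams ua_normalized
#' @return Numeric scalar (`NA` for incomparable pairs).
#' @examples
#' a <- genome_sequence("a", strrep("ACGT", 10))
#' d_ua(a, a)  # 0
#' @export
d_ua <- function(s1, s2, mode = c("extended", "direct")) {
  mode <- match.arg(mode)
  (ua_normalized(s1, s2, mode) + ua_normalized(s2, s1, mode)) / 2
}

#' All-pairs UA distance matrix
#'
#' @param seqs List of at least two `genome_sequence` objects with distinct
#'   labels.
#' @param mode Matching mode, see [underlying_set()].
#' @param incomparable_ceiling Distance substituted for pairs with no shared
#'   underlying subword; default twice the largest finite pairwise value
#'   (1 if no pair is comparable), keeping neighbor joining well defined.
#' @return Symmetric numeric matrix with zero diagonal, labels as dimnames.
#' @export
distance_matrix <- function(seqs, mode = c("extended", "direct"),
                            incomparable_ceiling = NULL) {
  mode <- match.arg(mode)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  labels <- vapply(seqs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate sequence labels")
  k <- length(seqs)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      D[i, j] <- D[j, i] <- d_ua(seqs[[i]], seqs[[j]], mode)
    }
  }
  if (anyNA(D)) {
    ceil <- incomparable_ceiling
    if (is.null(ceil)) {
      finite <- D[upper.tri(D)]
      finite <- finite[is.finite(finite)]
      ceil <- if (length(finite) > 0L) 2 * max(finite) else 1
    }
    D[is.na(D)] <- ceil
  }
  D
}

#' Match-class composition of an underlying set
#'
#' Table-style summary of the selected subwords: member count, length
#' range/mean, and the fraction of untied occurrences (both hosts pooled;
#' reference occurrences are direct by definition) that fall in the direct,
#' inversion and complement segments of the extended target.
#'
#' @param U An `underlying_set`.
#' @return List with `n_members`, `min_length`, `max_length`, `mean_length`,
#'   per-class untied occurrence `counts` and `fractions`.
#' @export
match_class_stats <- function(U) {
  stopifnot(inherits(U, "underlying_set"))
  classes <- c("direct", "inversion", "complement", "revcomp")
  counts <- stats::setNames(numeric(length(classes)), classes)
  lens <- vapply(U, `[[`, numeric(1), "length")
  for (w in U) {
    counts[["direct"]] <- counts[["direct"]] + w$h_s1
    if (length(w$class_s2) > 0L) {
      tb <- table(w$class_s2)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  tot <- sum(counts)
  list(n_members = length(U),
       min_length = if (length(U)) min(lens) else NA_real_,
       max_length = if (length(U)) max(lens) else NA_real_,
       mean_length = if (length(U)) mean(lens) else NA_real_,
       counts = counts,
       fractions = if (tot > 0) counts / tot else counts)
}

#' Write a distance matrix in square PHYLIP format
#'
#' Taxon-count line, then one row per taxon with the name padded to 10
#' characters -- the layout consumed by the PHYLIP neighbor program.
#'
#' @param D Square symmetric matrix with dimnames.
#' @param path Output path.
#' @param digits Significant digits for the values.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(D, path, digits = 6L) {
  labels <- rownames(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    name <- sprintf("%-10s", substr(labels[[i]], 1L, 10L))
    vals <- paste(formatC(D[i, ], digits = digits, format = "g"),
                  collapse = "  ")
    writeLines(paste0(name, vals), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to a file written by [write_phylip()] (or PHYLIP's own
#'   square format with whitespace-delimited names).
#' @return Numeric matrix with dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  k <- as.integer(trimws(lines[[1L]]))
  labels <- character(k)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    toks <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1L]]
    labels[[i]] <- toks[[1L]]
    D[i, ] <- as.numeric(toks[-1L])
  }
  dimnames(D) <- list(labels, labels)
  D
}
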