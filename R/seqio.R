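#' @useDynLib uasub, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# residue codes: A=1 C=2 G=3 T=4; every other symbol (ambiguity codes,
# separators) receives a globally unique sentinel code >= 5 so that it can
# never take part in a common subword
.BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.COMP <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
.COMP_CHAR <- c(A = "T", C = "G", G = "C", T = "A")

.encode_residues <- function(chars, sentinel_start) {
  codes <- unname(.BASES[chars])
  bad <- is.na(codes)
  if (any(bad)) {
    codes[bad] <- seq.int(sentinel_start, length.out = sum(bad))
  }
  list(codes = as.integer(codes),
       next_sentinel = as.integer(sentinel_start + sum(bad)))
}

#' Construct a genome sequence
#'
#' Normalizes a nucleotide string to uppercase and encodes it over the
#' alphabet \{A, C, G, T\}.  Any other character (ambiguity codes such as N,
#' R, Y, ...) is kept for display but encoded as a per-position unique
#' sentinel, so it can never match anything -- in particular it can never be
#' part of a common subword.
#'
#' @param label Character scalar naming the sequence (taxon).
#' @param sequence Character scalar with the residues.
#' @param sentinel_start First integer code available for sentinels; callers
#'   that build collections (e.g. [read_fasta()]) thread this counter through
#'   all records so that sentinels are unique across the whole collection.
#' @return An object of class `genome_sequence` with fields `label`,
#'   `residues` (normalized character string), `codes` (integer encoding) and
#'   `n` (length).
#' @examples
#' gs <- genome_sequence("a", "acgtn")
#' gs$n
#' @export
genome_sequence <- function(label, sequence, sentinel_start = 5L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L)
    stop("zero-length record: '", label, "'")
  enc <- .encode_residues(chars, sentinel_start)
  structure(
    list(label = label,
         residues = paste(chars, collapse = ""),
         chars = chars,
         codes = enc$codes,
         n = length(chars)),
    next_sentinel = enc$next_sentinel,
    class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<genome_sequence> %s (%d bp)\n  %s%s\n", x$label, x$n, head,
              if (x$n > 60L) "..." else ""))
  invisible(x)
}

#' Read a multi-FASTA file of nucleotide sequences
#'
#' One [genome_sequence()] per record.  Labels are taken from the header up
#' to the first whitespace.  Residues are uppercased; every non-ACGT
#' character is replaced (in the encoding) by a sentinel unique across the
#' whole collection, so ambiguity characters never produce spurious matches.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named list of `genome_sequence` objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  labels <- sub("\\s.*$", "", names(recs))
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L)
    stop("duplicate FASTA label: '", dup[[1L]], "'")
  out <- vector("list", length(recs))
  counter <- 5L
  for (i in seq_along(recs)) {
    s <- as.character(recs[[i]])
    if (nchar(s) == 0L) stop("zero-length record: '", labels[[i]], "'")
    gs <- genome_sequence(labels[[i]], s, sentinel_start = counter)
    counter <- attr(gs, "next_sentinel")
    out[[i]] <- gs
  }
  names(out) <- labels
  out
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs List of `genome_sequence` objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$label), con)
    starts <- seq.int(1L, s$n, by = width)
    writeLines(substring(s$residues, starts,
                         pmin(starts + width - 1L, s$n)), con)
  }
  invisible(path)
}

.reverse_codes <- function(codes) rev(codes)

.complement_codes <- function(codes, next_sentinel) {
  out <- codes
  base <- codes >= 1L & codes <= 4L
  out[base] <- .COMP[codes[base]]
  nb <- sum(!base)
  if (nb > 0L) {
    out[!base] <- seq.int(next_sentinel, length.out = nb)
    next_sentinel <- next_sentinel + nb
  }
  list(codes = as.integer(out), next_sentinel = as.integer(next_sentinel))
}

#' Build the extended target sequence (direct + inversion + complement)
#'
#' Concatenates a sequence with its inverse (plain reversal) and its base
#' complement (A<->T, C<->G substitution, not reversed), in this exact
#' order, joined by unique separator symbols.  Matching against the extended
#' sequence detects inversion and complement matches in addition to direct
#' ones; the segment an occurrence falls in determines its match class.
#' Optionally a fourth reverse-complement segment can be appended.
#'
#' @param seq A `genome_sequence`.
#' @param include_revcomp Add the biological reverse complement as a fourth
#'   segment (off by default; inverse and complement are listed as the two
#'   extra match classes of the method).
#' @return An object of class `extended_sequence` with fields `source`,
#'   `codes`, `chars`, `n` (extended length), `n_source` and a `segments`
#'   data frame (`class`, `start`, `end`, 0-based half-open).
#' @examples
#' ext <- build_extended(genome_sequence("x", "ACGT"))
#' ext$segments
#' @export
build_extended <- function(seq, include_revcomp = FALSE) {
  stopifnot(inherits(seq, "genome_sequence"))
  n <- seq$n
  nxt <- max(4L, max(seq$codes)) + 1L

  segs <- list(list(class = "direct", codes = seq$codes, chars = seq$chars))

  inv_codes <- .reverse_codes(seq$codes)
  sent <- inv_codes >= 5L
  if (any(sent)) {
    inv_codes[sent] <- seq.int(nxt, length.out = sum(sent))
    nxt <- nxt + sum(sent)
  }
  segs <- c(segs, list(list(class = "inversion", codes = as.integer(inv_codes),
                            chars = rev(seq$chars))))

  cc <- .complement_codes(seq$codes, nxt)
  nxt <- cc$next_sentinel
  comp_chars <- seq$chars
  known <- comp_chars %in% names(.COMP_CHAR)
  comp_chars[known] <- .COMP_CHAR[comp_chars[known]]
  segs <- c(segs, list(list(class = "complement", codes = cc$codes,
                            chars = comp_chars)))

  if (include_revcomp) {
    rc <- .complement_codes(.reverse_codes(seq$codes), nxt)
    nxt <- rc$next_sentinel
    rc_chars <- rev(comp_chars)
    segs <- c(segs, list(list(class = "revcomp", codes = rc$codes,
                              chars = rc_chars)))
  }

  codes <- integer(0)
  chars <- character(0)
  cls <- character(0)
  start <- integer(0)
  end <- integer(0)
  for (i in seq_along(segs)) {
    if (i > 1L) {  # separator
      codes <- c(codes, nxt)
      nxt <- nxt + 1L
      chars <- c(chars, "|")
    }
    cls <- c(cls, segs[[i]]$class)
    start <- c(start, length(codes))
    codes <- c(codes, segs[[i]]$codes)
    end <- c(end, length(codes))
    chars <- c(chars, segs[[i]]$chars)
  }

  structure(
    list(source = seq,
         codes = as.integer(codes),
         chars = chars,
         n = length(codes),
         n_source = n,
         segments = data.frame(class = cls, start = start, end = end,
                               stringsAsFactors = FALSE)),
    next_sentinel = nxt,
    class = "extended_sequence")
}

#' @export
print.extended_sequence <- function(x, ...) {
  cat(sprintf("<extended_sequence> of %s (%d bp source, %d total)\n",
              x$source$label, x$n_source, x$n))
  print(x$segments)
  invisible(x)
}

# plain sequence viewed as a single-segment (direct) extended sequence; lets
# every downstream stage treat "direct-only" and "extended" uniformly
.as_extended <- function(s2) {
  if (inherits(s2, "extended_sequence")) return(s2)
  stopifnot(inherits(s2, "genome_sequence"))
  structure(
    list(source = s2, codes = s2$codes, chars = s2$chars, n = s2$n,
         n_source = s2$n,
         segments = data.frame(class = "direct", start = 0L, end = s2$n,
                               stringsAsFactors = FALSE)),
    next_sentinel = attr(s2, "next_sentinel"),
    class = "extended_sequence")
}

#' Match class of a coordinate in an extended sequence
#'
#' @param ext An `extended_sequence`.
#' @param pos Integer vector of coordinates (0-based by default).
#' @param base Coordinate base, `"0"` or `"1"`.
#' @return Character vector: `"direct"`, `"inversion"`, `"complement"`,
#'   `"revcomp"` or `"separator"`.
#' @export
classify_position <- function(ext, pos, base = c("0", "1")) {
  stopifnot(inherits(ext, "extended_sequence"))
  base <- match.arg(base)
  if (base == "1") pos <- pos - 1L
  out <- rep("separator", length(pos))
  for (i in seq_len(nrow(ext$segments))) {
    hit <- pos >= ext$segments$start[i] & pos < ext$segments$end[i]
    out[hit] <- ext$segments$class[i]
  }
  out
}

# Assemble the generalized integer string s1 + sep + s2ext + sep for the
# engine.  Sentinel codes of the target are shifted above the reference's so
# they stay globally unique within the concatenation.
.assemble_pair <- function(s1, s2x) {
  stopifnot(inherits(s1, "genome_sequence"))
  s2x <- .as_extended(s2x)
  c2 <- s2x$codes
  shift <- max(4L, max(s1$codes))
  sent <- c2 >= 5L
  if (any(sent)) c2[sent] <- c2[sent] + shift
  sepA <- max(4L, max(s1$codes), max(c2)) + 1L
  x <- c(s1$codes, sepA, c2, sepA + 1L)
  list(x = as.integer(x), n1 = s1$n, off2 = s1$n + 1L, s2x = s2x,
       chars = c(s1$chars, "#", s2x$chars, "#"))
}
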