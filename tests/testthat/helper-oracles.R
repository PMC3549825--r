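# Independent brute-force oracles used to validate the suffix-structure
# implementation.  Everything here works on plain integer code vectors
# (A=1, C=2, G=3, T=4, sentinels >= 5) and never touches the package's
# index machinery.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

rand_gs <- function(label, n, gc = 0.5) genome_sequence(label, rand_dna(n, gc))

decode_word <- function(codes) paste(BASES[codes], collapse = "")

# mimic the package's pair concatenation: s1 + sep + s2ext + terminal, with
# the target's sentinel codes shifted above the reference's
concat_pair <- function(s1, s2x) {
  c1 <- s1$codes
  c2 <- s2x$codes
  shift <- max(4L, max(c1))
  c2[c2 >= 5L] <- c2[c2 >= 5L] + shift
  sep <- max(4L, max(c1), max(c2)) + 1L
  list(x = c(c1, sep, c2, sep + 1L), n1 = s1$n, off2 = s1$n + 1L,
       c1 = c1, c2 = c2)
}

# matching statistics of x against y by exhaustive diagonal extension
oracle_ms <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  best <- integer(nx)
  for (s in (1L - nx):(ny - 1L)) {
    i0 <- max(1L, 1L - s)
    i1 <- min(nx, ny - s)
    if (i0 > i1) next
    idx <- i0:i1
    v <- x[idx] == y[idx + s]
    L <- length(v)
    nxt <- rev(cummin(rev(ifelse(v, Inf, seq_len(L)))))
    r <- ifelse(is.finite(nxt), nxt - seq_len(L), L - seq_len(L) + 1)
    best[idx] <- pmax(best[idx], as.integer(r))
  }
  best
}

# all start positions (0-based) of word w in x, by successive filtering
find_occ0 <- function(x, w) {
  L <- length(w)
  if (L == 0L || L > length(x)) return(integer(0))
  idx <- which(x == w[[1L]])
  idx <- idx[idx + L - 1L <= length(x)]
  for (t in seq_len(L - 1L)) {
    if (length(idx) == 0L) break
    idx <- idx[x[idx + t] == w[[t + 1L]]]
  }
  sort(idx) - 1L
}

# Irredundant common subwords straight from the definition: a common
# subword is irredundant iff it has at least one occurrence (in either
# host) not covered by an occurrence of another common subword.  At
# position i the longest common word has length ms[i]; a cover of the
# occurrence (i, L) is either a longer common word starting at i
# (ms[i] > L) or a common word at j < i reaching at least i + L - 1
# (ms[j] >= i - j + L).  Uncovered occurrences therefore carry L = ms[i].
oracle_irredundant_words <- function(s1, s2x) {
  cp <- concat_pair(s1, s2x)
  ms1 <- oracle_ms(cp$c1, cp$c2)
  ms2 <- oracle_ms(cp$c2, cp$c1)
  words <- character(0)
  for (host in 1:2) {
    ms <- if (host == 1L) ms1 else ms2
    seqc <- if (host == 1L) cp$c1 else cp$c2
    for (i in seq_along(ms)) {
      L <- ms[[i]]
      if (L < 1L) next
      js <- seq_len(i - 1L)
      covered <- length(js) > 0L && any(ms[js] >= (i - js) + L)
      if (!covered)
        words <- c(words, decode_word(seqc[i:(i + L - 1L)]))
    }
  }
  sort(unique(words))
}

# Quadratic greedy selection of the underlying subwords: walk the words in
# priority order (longest first, ties by earliest occurrence, reference
# scanned before the extended target) and keep each occurrence untied from
# every untied occurrence already accepted -- full interval-overlap test
# against a coverage mask, including the word's own occurrences accepted
# earlier in the same round.  A word is kept iff it retains at least one
# untied occurrence in each host.
oracle_underlying <- function(s1, s2x, words = NULL) {
  cp <- concat_pair(s1, s2x)
  if (is.null(words)) words <- oracle_irredundant_words(s1, s2x)
  if (length(words) == 0L) return(list())
  cand <- lapply(words, function(w) {
    codes <- match(strsplit(w, "", fixed = TRUE)[[1L]], BASES)
    occ1 <- find_occ0(cp$c1, codes)
    occ2 <- find_occ0(cp$c2, codes)
    pos <- sort(c(occ1, cp$off2 + occ2))  # concatenated coordinates
    list(word = w, len = nchar(w), occ = pos, first = pos[[1L]])
  })
  lens <- vapply(cand, `[[`, numeric(1), "len")
  firsts <- vapply(cand, `[[`, numeric(1), "first")
  cand <- cand[order(-lens, firsts)]
  N <- length(cp$x)
  covered <- logical(N)
  out <- list()
  for (w in cand) {
    tent <- logical(N)
    untied <- integer(0)
    for (i in w$occ) {
      rng <- (i + 1L):(i + w$len)
      if (any(covered[rng]) || any(tent[rng])) next
      tent[rng] <- TRUE
      untied <- c(untied, i)
    }
    h1 <- sum(untied < cp$n1)
    h2 <- sum(untied >= cp$off2)
    if (h1 >= 1L && h2 >= 1L) {
      covered <- covered | tent
      out[[length(out) + 1L]] <- list(
        word = w$word, len = w$len,
        untied_s1 = untied[untied < cp$n1],
        untied_s2 = untied[untied >= cp$off2] - cp$off2)
    }
  }
  out
}

# right-extension-closed common substrings: common words followed by at
# least two distinct symbols over all their occurrences in the
# concatenation (end-of-host is distinct by the unique separators)
oracle_closed_common_words <- function(s1, s2x) {
  cp <- concat_pair(s1, s2x)
  ms1 <- oracle_ms(cp$c1, cp$c2)
  words <- character(0)
  for (i in seq_along(ms1)) {
    L <- ms1[[i]]
    if (L >= 1L)
      words <- c(words, vapply(seq_len(L), function(l)
        decode_word(cp$c1[i:(i + l - 1L)]), ""))
  }
  words <- unique(words)
  keep <- vapply(words, function(w) {
    codes <- match(strsplit(w, "", fixed = TRUE)[[1L]], BASES)
    occ <- find_occ0(cp$x, codes)
    followers <- cp$x[occ + length(codes) + 1L]
    length(unique(followers)) >= 2L
  }, logical(1))
  sort(words[keep])
}

# flatten an underlying_set (or oracle output) to a canonical summary for
# set comparison: word, untied starts per host
canonical_members <- function(members) {
  if (length(members) == 0L) return(character(0))
  vapply(members, function(m) {
    u1 <- if (!is.null(m$untied_s1)) m$untied_s1 else integer(0)
    u2 <- if (!is.null(m$untied_s2)) m$untied_s2 else integer(0)
    paste0(m$word, "|", paste(sort(u1), collapse = ","), "|",
           paste(sort(u2), collapse = ","))
  }, "")
}

# expand per-host untied intervals of an underlying set
untied_intervals <- function(U, host = c("s1", "s2")) {
  host <- match.arg(host)
  do.call(rbind, lapply(U, function(w) {
    st <- if (host == "s1") w$untied_s1 else w$untied_s2
    if (length(st) == 0L) return(NULL)
    cbind(start = st, end = st + w$length - 1L)
  }))
}

# Maximality check: no rejected irredundant word keeps one occurrence per
# host untied from the untied occurrences of the selected words.  Tied-ness
# is priority-aware (only a higher-priority subword can tie an occurrence),
# so the masks are grown while walking the irredundant words in priority
# order and each rejected word is tested against the selected words that
# outrank it.
check_def2_maximality <- function(U, irr, s1, s2x) {
  lens <- vapply(irr, `[[`, integer(1), "length")
  firsts <- vapply(irr, `[[`, integer(1), "first_occ")
  irr_sorted <- unclass(irr)[order(-lens, firsts)]
  sel_words <- vapply(U, `[[`, "", "word")
  mask1 <- logical(s1$n)
  mask2 <- logical(s2x$n)
  for (w in irr_sorted) {
    m <- match(w$word, sel_words)
    if (!is.na(m)) {
      u <- U[[m]]
      for (k in u$untied_s1) mask1[(k + 1L):(k + u$length)] <- TRUE
      for (k in u$untied_s2) mask2[(k + 1L):(k + u$length)] <- TRUE
    } else {
      free1 <- any(vapply(w$occ_s1, function(k)
        !any(mask1[(k + 1L):(k + w$length)]), logical(1)))
      free2 <- any(vapply(w$occ_s2, function(k)
        !any(mask2[(k + 1L):(k + w$length)]), logical(1)))
      if (isTRUE(free1) && isTRUE(free2)) return(FALSE)
    }
  }
  TRUE
}
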