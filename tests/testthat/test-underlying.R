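test_that("priority order: longer first, ties by earliest occurrence", {
  fake <- function(word, len, first)
    list(word = word, length = len, node = 0L, first_occ = first)
  cs <- structure(list(fake("w1", 5L, 7L), fake("w2", 3L, 1L),
                       fake("w3", 5L, 2L)),
                  class = "common_subwords", index = NULL)
  got <- priority_sort(cs)
  expect_equal(vapply(got, `[[`, "", "word"), c("w3", "w1", "w2"))
  one <- structure(list(fake("only", 4L, 0L)), class = "common_subwords")
  expect_equal(vapply(priority_sort(one), `[[`, "", "word"), "only")
})

test_that("priority order matches a comparison-sort oracle on random keys", {
  set.seed(61)
  lens <- sample(1:50, 1000, replace = TRUE)
  firsts <- sample(0:10000, 1000)
  cs <- structure(lapply(seq_len(1000), function(i)
    list(word = paste0("w", i), length = lens[[i]], node = i,
         first_occ = firsts[[i]])), class = "common_subwords")
  got <- vapply(priority_sort(cs), `[[`, "", "word")
  keys <- mapply(function(l, f) c(l, f), lens, firsts, SIMPLIFY = FALSE)
  ord <- order(vapply(keys, function(k) -k[[1L]], 0),
               vapply(keys, function(k) k[[2L]], 0))
  expect_equal(got, paste0("w", ord))
})

test_that("select_underlying rejects unsorted input", {
  s1 <- genome_sequence("a", "ACGTACGTCCAT")
  irr <- find_irredundant(s1, genome_sequence("b", "TTACGTAGGCAT"))
  lens <- vapply(irr, `[[`, integer(1), "length")
  if (length(irr) >= 2L && length(unique(lens)) >= 2L) {
    bad <- structure(unclass(irr)[order(lens)], class = "common_subwords",
                     index = attr(irr, "index"))
    expect_error(select_underlying(bad), "sorted")
  }
  expect_silent(select_underlying(priority_sort(irr)))
})

test_that("identical strings yield the sequence itself as sole member", {
  set.seed(62)
  for (n in c(4L, 37L, 160L)) {
    s <- rand_gs("s", n)
    for (mode in c("direct", "extended")) {
      U <- underlying_set(s, s, mode)
      expect_length(U, 1L)
      expect_equal(U[[1L]]$word, s$residues)
      expect_equal(U[[1L]]$h_s1, 1L)
      expect_gte(U[[1L]]$h_s2, 1L)
    }
  }
})

test_that("single shared word with nothing to tie is kept in full", {
  s1 <- genome_sequence("a", "ACGT")
  s2 <- genome_sequence("b", "ACGT")
  U <- underlying_set(s1, s2, "direct")
  expect_length(U, 1L)
  expect_equal(U[[1L]]$untied_s1, 0L)
  expect_equal(U[[1L]]$untied_s2, 0L)
})

test_that("selection matches the quadratic greedy oracle", {
  set.seed(63)
  for (rep in 1:40) {
    s1 <- rand_gs("a", sample(5:100, 1), gc = runif(1, 0.25, 0.75))
    s2 <- rand_gs("b", sample(5:100, 1), gc = runif(1, 0.25, 0.75))
    s2x <- if (rep %% 2 == 0) build_extended(s2) else s2
    U <- select_underlying(priority_sort(find_irredundant(s1, s2x)))
    O <- oracle_underlying(s1, s2x)
    expect_equal(canonical_members(U), canonical_members(O),
                 label = sprintf("rep %d", rep))
  }
})

test_that("underlying-set structural invariants hold on random inputs", {
  set.seed(64)
  for (rep in 1:15) {
    s1 <- rand_gs("a", sample(20:120, 1))
    s2 <- rand_gs("b", sample(20:120, 1))
    s2x <- build_extended(s2)
    U <- select_underlying(priority_sort(find_irredundant(s1, s2x)))
    for (host in c("s1", "s2")) {
      iv <- untied_intervals(U, host)
      if (is.null(iv)) next
      iv <- iv[order(iv[, "start"]), , drop = FALSE]
      if (nrow(iv) > 1L)
        expect_true(all(iv[-1L, "start"] > iv[-nrow(iv), "end"]))
      hostlen <- if (host == "s1") s1$n else s2x$n
      expect_lte(sum(iv[, "end"] - iv[, "start"] + 1L), hostlen)
    }
    expect_true(all(vapply(U, `[[`, integer(1), "h_s1") >= 1L))
    expect_true(all(vapply(U, `[[`, integer(1), "h_s2") >= 1L))
  }
})

test_that("endpoint test is sound: accepted overlaps always cover an endpoint", {
  # processing longest-first means an earlier interval overlapping
  # [i, i + |w| - 1] has length >= |w| and cannot fit strictly inside
  set.seed(65)
  for (rep in 1:10) {
    s1 <- rand_gs("a", sample(10:60, 1))
    s2 <- rand_gs("b", sample(10:60, 1))
    U <- underlying_set(s1, s2, "direct")
    lens <- vapply(U, `[[`, numeric(1), "length")
    expect_true(all(diff(vapply(U, `[[`, integer(1), "rank")) > 0))
    expect_true(all(lens == sort(lens, decreasing = TRUE)))
  }
})

test_that("definition maximality: no rejected word could be added", {
  set.seed(66)
  for (rep in 1:8) {
    s1 <- rand_gs("a", sample(10:60, 1))
    s2 <- rand_gs("b", sample(10:60, 1))
    s2x <- build_extended(s2)
    irr <- find_irredundant(s1, s2x)
    U <- select_underlying(priority_sort(irr))
    expect_true(check_def2_maximality(U, irr, s1, s2x))
  }
})
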