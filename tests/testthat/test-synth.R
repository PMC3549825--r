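test_that("generator is deterministic per seed and differs across seeds", {
  cfg <- simulation_config(seed = 5, n_leaves = 4, root_length = 300)
  f1 <- evolve_along_tree(cfg)
  f2 <- evolve_along_tree(cfg)
  expect_identical(lapply(f1$sequences, `[[`, "residues"),
                   lapply(f2$sequences, `[[`, "residues"))
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  f3 <- evolve_along_tree(simulation_config(seed = 6, n_leaves = 4,
                                            root_length = 300))
  expect_false(identical(lapply(f1$sequences, `[[`, "residues"),
                         lapply(f3$sequences, `[[`, "residues")))
  # byte-identical FASTA output
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(f1$sequences, p1)
  write_fasta(f2$sequences, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zero substitution rate and no events give identical leaves", {
  cfg <- simulation_config(seed = 9, n_leaves = 4, root_length = 200,
                           substitution_rate = 0, inversions = 0,
                           complements = 0)
  fam <- evolve_along_tree(cfg)
  res <- vapply(fam$sequences, `[[`, "", "residues")
  expect_true(all(res == res[[1]]))
  expect_identical(d_ua(fam$sequences[[1]], fam$sequences[[2]]), 0)
})

test_that("tree shapes honor the requested topology", {
  cat4 <- evolve_along_tree(simulation_config(seed = 2, n_leaves = 5,
                                              tree_shape = "caterpillar",
                                              root_length = 50,
                                              inversions = 0,
                                              complements = 0))
  expect_equal(sort(cat4$tree$tip.label), paste0("t", 1:5))
  bal <- evolve_along_tree(simulation_config(seed = 2, n_leaves = 8,
                                             tree_shape = "balanced",
                                             root_length = 50,
                                             inversions = 0,
                                             complements = 0))
  expect_equal(length(bal$tree$tip.label), 8L)
  expect_error(simulation_config(n_leaves = 6, tree_shape = "balanced",
                                 root_length = 50) |> evolve_along_tree(),
               "power-of-two")
})

test_that("a planted inversion is recovered as an inversion-class match", {
  set.seed(91)
  base <- rand_dna(1000)
  chars <- strsplit(base, "")[[1]]
  seg <- 401:600
  mut <- chars
  mut[seg] <- rev(chars[seg])
  s1 <- genome_sequence("orig", base)
  s2 <- genome_sequence("inv", paste(mut, collapse = ""))
  U <- underlying_set(s1, s2, "extended")
  cls <- unlist(lapply(U, `[[`, "class_s2"))
  expect_true("inversion" %in% cls)
  # and the inverted block itself is found at full length
  lens <- vapply(U, `[[`, numeric(1), "length")
  inv_members <- vapply(U, function(w) "inversion" %in% w$class_s2,
                        logical(1))
  expect_gte(max(lens[inv_members]), 200)
})

test_that("a planted complement is recovered as a complement-class match", {
  set.seed(92)
  base <- rand_dna(1000)
  chars <- strsplit(base, "")[[1]]
  seg <- 301:500
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mut <- chars
  mut[seg] <- comp[chars[seg]]
  U <- underlying_set(genome_sequence("orig", base),
                      genome_sequence("comp", paste(mut, collapse = "")),
                      "extended")
  cls <- unlist(lapply(U, `[[`, "class_s2"))
  expect_true("complement" %in% cls)
})

test_that("d_UA increases with the substitution rate (averaged over seeds)", {
  rates <- c(0.01, 0.08, 0.30)
  mean_d <- vapply(rates, function(r) {
    mean(vapply(1:6, function(seed) {
      fam <- evolve_along_tree(simulation_config(
        seed = seed, n_leaves = 2, root_length = 500,
        substitution_rate = r, inversions = 0, complements = 0,
        tree_shape = "caterpillar"))
      d_ua(fam$sequences[[1]], fam$sequences[[2]])
    }, 0))
  }, 0)
  expect_true(all(diff(mean_d) > 0))
})

test_that("planted inversions raise the inversion fraction over controls", {
  frac_inv <- function(seed, inv) {
    fam <- evolve_along_tree(simulation_config(
      seed = seed, n_leaves = 2, tree_shape = "caterpillar",
      root_length = 2000, substitution_rate = 0.005,
      inversions = inv, complements = 0))
    U <- underlying_set(fam$sequences[[1]], fam$sequences[[2]], "extended")
    match_class_stats(U)$fractions[["inversion"]]
  }
  for (seed in 1:3)
    expect_gt(frac_inv(seed, 2L), frac_inv(seed, 0L))
})
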