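test_that("MRP coding produces one character per non-root internal node", {
  m1 <- mrp_encode(read_newick("((A,B),C);"))
  expect_equal(dim(m1), c(3L, 1L))
  expect_equal(unclass(m1)[, 1], c(A = "1", B = "1", C = "0"))
  m2 <- mrp_encode(list(read_newick("((A,B),C);"), read_newick("((B,C),D);")))
  expect_equal(dim(m2), c(4L, 2L))
  expect_equal(unname(unclass(m2)["D", 1]), "?")
  expect_equal(unname(unclass(m2)["A", 2]), "?")
  expect_equal(unname(unclass(m2)["B", ]), c("1", "1"))
  # every character separates at least one 0 from one 1
  expect_true(all(apply(m2, 2, function(cl) any(cl == "0") && any(cl == "1"))))
  # a star tree encodes nothing
  star <- read_newick("(A,B,C,D);")
  expect_equal(ncol(mrp_encode(star)), 0)
  expect_error(mrp_encode(read_newick("(A,B);")), "3 tips")
})

test_that("fitch score matches enumeration on the textbook cases", {
  m <- mrp_encode(read_newick("((A,B),C);"))
  expect_equal(fitch_score(read_newick("((A,B),C);"), m), 1)
  expect_equal(fitch_score(read_newick("((A,C),B);"), m), 1)
  const <- matrix(c("1", "1", "?"), ncol = 1, dimnames = list(c("A", "B", "C")))
  expect_equal(fitch_score(read_newick("((A,B),C);"), const), 0)
  # weights scale the score
  two <- cbind(unclass(m), unclass(m))
  expect_equal(fitch_score(read_newick("((A,C),B);"), two, weights = c(1, 3)), 4)
})

test_that("fitch equals brute-force minimal changes and phangorn on random data", {
  set.seed(21)
  taxa <- sprintf("t%d", 1:6)
  for (rep in 1:10) {
    tr <- ape::rtree(6, tip.label = taxa)
    cols <- replicate(8, random_mrp_column(taxa), simplify = FALSE)
    m <- do.call(cbind, cols)
    mine <- fitch_score(tr, m)
    brute <- sum(vapply(cols, fitch_bruteforce, numeric(1), tree = tr))
    expect_equal(mine, brute)
    # independent implementation cross-check
    pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    expect_equal(mine, phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("ratchet search is seeded-deterministic and locally optimal", {
  set.seed(30)
  model <- unit_branch_lengths(ape::rtree(7, tip.label = sprintf("s%d", 1:7)))
  subs <- lapply(1:4, function(i) prune_to_taxa(model, sample(model$tip.label, 5)))
  M <- mrp_encode(subs)
  r1 <- ratchet_search(M, iterations = 10, seed = 5)
  r2 <- ratchet_search(M, iterations = 10, seed = 5)
  expect_identical(write_newick(r1$tree), write_newick(r2$tree))
  expect_identical(r1$score, r2$score)
  # never worse than the NJ starting tree
  start <- ape::unroot(ape::nj(gapscape:::mrp_hamming(M)))
  expect_lte(r1$score, fitch_score(start, M))
  # NNI-local optimality under original weights
  nb <- phangorn::nni(r1$tree)
  expect_true(all(vapply(nb, fitch_score, numeric(1), matrix = M) >= r1$score))
  expect_error(ratchet_search(M, iterations = 0), "iterations")
})

test_that("compatible subtrees reassemble the generating topology", {
  set.seed(14)
  model <- unit_branch_lengths(ape::rtree(6, tip.label = sprintf("s%d", 1:6)))
  subs <- lapply(1:4, function(i) prune_to_taxa(model, sample(model$tip.label, 5)))
  M <- mrp_encode(subs)
  res <- ratchet_search(M, iterations = 15, seed = 2)
  all6 <- phangorn::allTrees(6, rooted = FALSE, tip.label = model$tip.label)
  best <- min(vapply(all6, fitch_score, numeric(1), matrix = M))
  expect_equal(res$score, best)
  expect_equal(as.numeric(ape::dist.topo(res$tree, ape::unroot(model))), 0,
               ignore_attr = TRUE)
})

test_that("MRP matrices export to phylip and nexus", {
  m <- mrp_encode(list(read_newick("((A,B),C);"), read_newick("((B,C),D);")))
  p1 <- withr::local_tempfile(fileext = ".phy")
  p2 <- withr::local_tempfile(fileext = ".nex")
  write_mrp(m, p1, "phylip")
  write_mrp(m, p2, "nexus")
  expect_equal(readLines(p1)[1], "4 2")
  expect_true(any(grepl("NTAX=4 NCHAR=2", readLines(p2))))
})
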