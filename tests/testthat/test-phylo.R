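test_that("newick reading validates syntax and reports positions", {
  tr <- read_newick("((A,B),C);")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_error(read_newick("((A,B,C);"), "position")
  expect_error(read_newick("(A,B));"), "position 6")
  expect_error(read_newick("((A,B),C)"), "';'")
  # unlabeled internal nodes are fine
  expect_silent(read_newick("((A,B)X,(C,D));"))
})

test_that("newick round-trips preserve topology and labels on random trees", {
  set.seed(3)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:20, 1))
    tr2 <- read_newick(paste0(write_newick(tr), ""))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    expect_equal(suppressWarnings(as.numeric(ape::dist.topo(tr, tr2))), 0,
                 ignore_attr = TRUE)
    expect_identical(write_newick(tr2), write_newick(read_newick(write_newick(tr2))))
  }
})

test_that("pruning keeps induced quartet topologies", {
  tr <- read_newick("((A,B),C);")
  pr <- prune_to_taxa(tr, c("A", "B"))
  expect_setequal(pr$tip.label, c("A", "B"))
  expect_equal(ape::Ntip(prune_to_taxa(tr, tr$tip.label)), 3)
  expect_error(prune_to_taxa(tr, c("X", "Y")), "no requested taxon")
  set.seed(8)
  big <- unit_branch_lengths(ape::rtree(12))
  for (i in 1:20) {
    keep <- sample(big$tip.label, sample(5:9, 1))
    sub <- unit_branch_lengths(prune_to_taxa(big, keep))
    q <- sample(keep, 4)
    expect_equal(quartet_split(sub, q), quartet_split(big, q))
  }
})

test_that("faith PD counts the rooted spanning subtree once per branch", {
  tr <- toy_tree()
  expect_equal(faith_pd(tr, c("A", "B")), 3) # two tip branches + their stem
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
  expect_equal(faith_pd(tr, character(0)), 0)
  expect_error(faith_pd(tr, "Z"), "not tips")
})

test_that("faith PD is monotone under set inclusion and matches picante", {
  skip_if_not_installed("picante")
  set.seed(5)
  tr <- unit_branch_lengths(ape::rtree(10))
  sets <- list(c("t1", "t2"), c("t1", "t2", "t5"), c("t1", "t2", "t5", "t8"))
  pd <- vapply(sets, faith_pd, numeric(1), tree = tr)
  expect_true(all(diff(pd) >= 0))
  comm <- matrix(0, length(sets), 10, dimnames = list(NULL, tr$tip.label))
  for (i in seq_along(sets)) comm[i, sets[[i]]] <- 1
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(pd, ref, tolerance = 1e-9)
})

test_that("phylogenetic weighted endemism reproduces the worked example", {
  pw <- pwe(toy_tree(), toy_ranges())
  expect_equal(pw$cells$pwe, c(2.0, 1.5, 0.5))
  # conservation: cell sums equal total recorded branch length
  expect_equal(sum(pw$cells$pwe), sum(toy_tree()$edge.length), tolerance = 1e-9)
})

test_that("pwe conservation holds on random trees and ranges", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    tr <- unit_branch_lengths(ape::rtree(n))
    recorded <- sample(tr$tip.label, sample(2:n, 1))
    ranges <- tibble::tibble(
      species_id = rep(recorded, each = 3),
      cell_id = sample.int(20, 3 * length(recorded), replace = TRUE)
    ) |> dplyr::distinct()
    pw <- pwe(tr, ranges)
    recorded_len <- sum(pw$branches$length[pw$branches$n_cells > 0])
    expect_equal(sum(pw$cells$pwe), recorded_len, tolerance = 1e-9)
    # a single-species range puts the full tip path length in its cells
    if (length(recorded) == 1) {
      expect_equal(sum(pw$cells$pwe), faith_pd(tr, recorded))
    }
  }
})

test_that("lineage protection counts branch length with PA-overlapping ranges", {
  tr <- toy_tree()
  rng <- toy_ranges()
  # protecting c1 protects A, B and their stem: 3 of 4 unit branches
  expect_equal(lineage_protection(tr, rng, 1L)$prop_length, 0.75)
  expect_equal(lineage_protection(tr, rng, integer(0))$prop_length, 0)
  expect_equal(lineage_protection(tr, rng, 1:3)$prop_length, 1)
  expect_equal(lineage_protection(tr, rng, 1L)$prop_count, 0.75)
})
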