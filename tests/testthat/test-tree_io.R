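test_that("newick parsing sums printed lengths and accepts polytomies", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(root_to_tip_distances(tr)[c("A", "B", "C")],
               c(A = 1.5, B = 2.5, C = 3.0))

  star <- read_newick("(A:1,B:1,C:1);")
  expect_equal(star$Nnode, 1L)
  expect_equal(unname(root_to_tip_distances(star)), rep(1, 3))

  sci <- read_newick("((A:1e-3,B:2E-3):5e-4,C:3e-3);")
  expect_equal(root_to_tip_distances(sci)[["A"]], 1.5e-3)
})

test_that("malformed and invalid newick is rejected with useful messages", {
  expect_error(read_newick("((A:1,B:2):0.5,C:3)"), "character")
  expect_error(read_newick("((A:1,B:2:0.5,C:3);"), "unclosed")
  expect_error(read_newick("(A:1,B:2));"), "unbalanced")
  expect_error(read_newick("((A:1,A:2):0.5,C:3);"), "duplicate.*A")
  expect_error(read_newick("((A:1,B:-2):0.5,C:3);"), "negative.*B")
})

test_that("negative branch lengths can be clamped on request, with warning", {
  expect_warning(tr <- read_newick("((A:1,B:-2):0.5,C:3);",
                                   clamp_negative = TRUE), "clamp")
  expect_equal(root_to_tip_distances(tr)[["B"]], 0.5)
})

test_that("missing branch lengths parse as zero with a warning", {
  expect_warning(tr <- read_newick("((A:1,B:2):0.5,C);"), "missing")
  expect_equal(root_to_tip_distances(tr)[["C"]], 0)
  expect_warning(tr2 <- read_newick("((A,B),C);"), "branch length")
  expect_equal(unname(root_to_tip_distances(tr2)), rep(0, 3))
})

test_that("write/read round-trip preserves topology, labels and metric", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  rt <- read_newick(write_newick(tr))
  expect_equal(tip_distance_matrix(rt)[tr$tip.label, tr$tip.label],
               tip_distance_matrix(tr))

  sim <- sim_quick(n = 100, seed = 11, noise = 0.3)
  rt2 <- read_newick(write_newick(sim$tree))
  lab <- sim$tree$tip.label
  expect_lt(max(abs(tip_distance_matrix(rt2)[lab, lab] -
                    tip_distance_matrix(sim$tree)[lab, lab])), 1e-12)
  # idempotence: a second round trip is byte-identical
  expect_identical(write_newick(read_newick(write_newick(sim$tree))),
                   write_newick(sim$tree))
})

test_that("labels needing quotes survive a round-trip", {
  tr <- read_newick("(('A b':1,B:2):0.5,'C(x)':3);")
  expect_setequal(tr$tip.label, c("A b", "B", "C(x)"))
  out <- write_newick(tr)
  expect_match(out, "'A b'", fixed = TRUE)
  expect_setequal(read_newick(out)$tip.label, tr$tip.label)
})

test_that("rerooting along an edge follows path arithmetic", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  r <- reroot_at(tr, "C", 0.5)  # halfway from parent end of C's edge
  expect_equal(root_to_tip_distances(r)[c("C", "A", "B")],
               c(C = 1.5, A = 3.0, B = 4.0))
  # fraction 0 on a root-child edge leaves the rooting unchanged
  r0 <- reroot_at(tr, "C", 0)
  expect_equal(root_to_tip_distances(r0), root_to_tip_distances(tr))
})

test_that("rerooting is pure and suppresses the old degree-2 root", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  snapshot <- write_newick(tr)
  r <- reroot_at(tr, "A", 0.5)
  expect_identical(write_newick(tr), snapshot)   # input not mutated
  # old root had 2 children; after rerooting no internal vertex is left with
  # a single child (the suppressed-old-root signature)
  n_children <- table(factor(r$edge[, 1],
                             levels = (length(r$tip.label) + 1):
                                      (length(r$tip.label) + r$Nnode)))
  expect_true(all(n_children >= 2))
})

test_that("random rerooting preserves the tip-tip path-length matrix", {
  sim <- sim_quick(n = 30, seed = 5, noise = 0.2)
  lab <- sim$tree$tip.label
  ref <- tip_distance_matrix(sim$tree)[lab, lab]
  set.seed(42)
  children <- sim$tree$edge[, 2]
  for (i in 1:50) {
    pl <- root_placement(sample(children, 1), stats::runif(1))
    r <- reroot_at(sim$tree, pl)
    expect_lt(max(abs(tip_distance_matrix(r)[lab, lab] - ref)), 1e-12)
  }
})

test_that("root-to-tip distances match an independent parent-chain walk", {
  sim <- sim_quick(n = 100, seed = 2, noise = 0.5)
  d <- root_to_tip_distances(sim$tree)
  expect_equal(d, oracle_root_to_tip(sim$tree), tolerance = 1e-12)
})

test_that("distance additivity: root path sums bound patristic distances", {
  sim <- sim_quick(n = 25, seed = 8, noise = 0.1)
  d <- root_to_tip_distances(sim$tree)
  m <- tip_distance_matrix(sim$tree)
  lab <- sim$tree$tip.label
  for (x in lab[1:5]) for (y in lab[6:10])
    expect_gte(d[[x]] + d[[y]] - m[x, y], -1e-12)
})

test_that("rerooting agrees with the phytools implementation", {
  skip_if_not_installed("phytools")
  sim <- sim_quick(n = 15, seed = 13, noise = 0.2)
  lab <- sim$tree$tip.label
  # internal, non-root-child edge
  n <- length(lab)
  child <- sim$tree$edge[sim$tree$edge[, 2] > n + 1, 2][3]
  b <- sim$tree$edge.length[match(child, sim$tree$edge[, 2])]
  mine <- reroot_at(sim$tree, root_placement(child, 0.4))
  # phytools' position is also measured from the rootward (parent) end
  theirs <- phytools::reroot(sim$tree, child, position = 0.4 * b)
  expect_equal(root_to_tip_distances(mine)[lab],
               tiptempo::root_to_tip_distances(theirs)[lab], tolerance = 1e-10)
})
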