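test_that("objective at the current root equals the plain regression RSS", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  td <- tip_dates(c(A = 2005, B = 2007, C = 2010))
  # fraction 0 on a root-child edge is the current rooting
  child <- tr$edge[tr$edge[, 1] == 4, 2][1]
  obj <- objective_at(tr, root_placement(child, 0), td, "rss")
  fit <- fit_root_to_tip(td, root_to_tip_distances(tr))
  expect_equal(obj, fit$rss, tolerance = 1e-12)
})

test_that("variance objective on a star tree is zero at the root", {
  tr <- read_newick("(A:1,B:1,C:1);")
  obj <- objective_at(tr, root_placement("A", 0), criterion = "variance")
  expect_equal(obj, 0, tolerance = 1e-15)
})

test_that("objective_at equals explicit reroot + refit at random placements", {
  sim <- sim_quick(n = 15, seed = 9, noise = 0.2)
  td <- sim$dates
  set.seed(101)
  children <- sim$tree$edge[, 2]
  for (i in 1:20) {
    pl <- root_placement(sample(children, 1), stats::runif(1))
    direct <- objective_at(sim$tree, pl, td, "rss")
    rerooted <- reroot_at(sim$tree, pl)
    refit <- fit_root_to_tip(td, root_to_tip_distances(rerooted))
    expect_equal(direct, refit$rss, tolerance = 1e-10)
    dvar <- objective_at(sim$tree, pl, criterion = "variance")
    d <- root_to_tip_distances(rerooted)
    expect_equal(dvar, mean((d - mean(d))^2), tolerance = 1e-10)
  }
})

test_that("per-edge quadratic matches a dense grid search", {
  sim <- sim_quick(n = 10, seed = 14, noise = 0.3)
  td <- sim$dates
  tr <- ape::reorder.phylo(sim$tree, "cladewise")
  child <- tr$edge[5, 2]
  eo <- optimize_on_edge(tr, child, td, "rss")
  grid <- seq(0, 1, length.out = 10001)
  vals <- vapply(grid, function(x)
    objective_at(tr, root_placement(child, x), td, "rss"), numeric(1))
  expect_lt(abs(eo$argmin - grid[which.min(vals)]), 1e-4 + 1e-9)
  expect_equal(eo$objective, min(vals), tolerance = 1e-10)
})

test_that("the edge quadratic reproduces direct evaluation at interior points", {
  for (seed in c(31, 32)) {
    sim <- sim_quick(n = 12, seed = seed, noise = 0.25)
    tr <- ape::reorder.phylo(sim$tree, "cladewise")
    for (ei in c(2, 7, nrow(tr$edge))) {
      child <- tr$edge[ei, 2]
      eo <- optimize_on_edge(tr, child, sim$dates, "rss")
      for (x in seq(0.04, 0.96, length.out = 25)) {
        direct <- objective_at(tr, root_placement(child, x), sim$dates, "rss")
        expect_equal(eo$a * x^2 + eo$b * x + eo$c, direct, tolerance = 1e-9)
      }
    }
  }
})

test_that("a symmetric two-clade tree roots midway under the variance criterion", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):3);")
  br <- find_best_root(tr, criterion = "variance")
  d <- root_to_tip_distances(br$tree)
  expect_equal(br$objective, 0, tolerance = 1e-12)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
})

test_that("best root recovers the true root of a noise-free clock tree", {
  sim <- sim_quick(n = 20, seed = 17, noise = 0, rate = 3e-3)
  rr <- random_reroot(sim$tree, seed = 55)
  br <- find_best_root(rr$tree, sim$dates, "rss")
  expect_lt(br$objective, 1e-15)
  expect_equal(br$fit$slope, 3e-3, tolerance = 1e-8)
  expect_equal(br$fit$x_intercept, sim$truth$root_time, tolerance = 1e-6)
  # the recovered root point reproduces the true root-to-tip distances,
  # i.e. it lies on the true root edge to within 1e-6 of the fraction
  d_true <- root_to_tip_distances(sim$tree)
  d_got <- root_to_tip_distances(br$tree)[names(d_true)]
  expect_lt(max(abs(d_got - d_true)), 3e-3 * 1e-6)
})

test_that("an already optimal rooting is not 'improved'", {
  sim <- sim_quick(n = 20, seed = 17, noise = 0.1)
  br1 <- find_best_root(sim$tree, sim$dates, "rss")
  br2 <- find_best_root(br1$tree, sim$dates, "rss")
  expect_lt(abs(br2$objective - br1$objective), 1e-12)
  expect_equal(root_to_tip_distances(br2$tree), root_to_tip_distances(br1$tree),
               tolerance = 1e-10)
})

test_that("the exact search matches the brute-force grid oracle", {
  sim <- sim_quick(n = 12, seed = 23, noise = 0.3)
  t <- analysis_times(sim$dates)
  br <- find_best_root(sim$tree, sim$dates, "rss")
  orc <- oracle_best_root(sim$tree, t, grid = seq(0, 1, length.out = 2001))
  expect_lt(abs(br$objective - orc$obj), 1e-8)
  # same root point: distances from both placements agree to grid resolution
  d_mine <- root_to_tip_distances(br$tree)
  d_orc <- root_to_tip_distances(reroot_at(sim$tree,
                                           root_placement(orc$edge_child,
                                                          orc$fraction)))
  bmax <- max(sim$tree$edge.length)
  expect_lt(max(abs(d_mine[names(d_orc)] - d_orc)), 5e-4 * bmax + 1e-9)
})

test_that("no placement beats the reported optimum", {
  sim <- sim_quick(n = 18, seed = 29, noise = 0.2)
  br <- find_best_root(sim$tree, sim$dates, "rss")
  set.seed(77)
  children <- sim$tree$edge[, 2]
  worst <- Inf
  for (i in 1:1000) {
    pl <- root_placement(sample(children, 1), stats::runif(1))
    o <- objective_at(sim$tree, pl, sim$dates, "rss")
    worst <- min(worst, o)
    expect_gte(o, br$objective - 1e-10)
  }
  # input rooting is also never better
  fit0 <- fit_root_to_tip(sim$dates, root_to_tip_distances(sim$tree))
  expect_lte(br$objective, fit0$rss + 1e-12)
})

test_that("isochronous input steers users from rss to variance", {
  tr <- read_newick("((A:1,B:1.5):1,C:2);")
  td <- tip_dates(c(A = 2000, B = 2000, C = 2000))
  expect_error(find_best_root(tr, td, "rss"), "variance")
  br <- find_best_root(tr, criterion = "variance")
  expect_s3_class(br, "best_root")
  expect_true(is.finite(br$variance))
})

test_that("variance criterion recovers the root of an ultrametric tree", {
  # noise-free isochronous tree: all tips equidistant from the true root
  sim <- sim_quick(n = 15, seed = 41, noise = 0,
                   sampling_window = c(2009.999999, 2010))
  rr <- random_reroot(sim$tree, seed = 3)
  br <- find_best_root(rr$tree, criterion = "variance")
  expect_lt(br$objective, 1e-12)
  d <- root_to_tip_distances(br$tree)
  expect_lt(max(d) - min(d), 1e-5)
})

test_that("zero-length edges report fraction 0", {
  tr <- read_newick("((A:1,B:1):0,C:1);")
  td <- tip_dates(c(A = 2000, B = 2005, C = 2010))
  n <- length(tr$tip.label)
  child <- tr$edge[tr$edge[, 2] > n, 2][1]
  eo <- optimize_on_edge(tr, child, td, "rss")
  expect_equal(eo$argmin, 0)
})
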