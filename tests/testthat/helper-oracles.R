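# Independent oracles, deliberately avoiding the package's own code paths.

# root-to-tip distance by walking each tip's parent chain on the raw edge
# matrix (independent of ape::node.depth.edgelength)
oracle_root_to_tip <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    plen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  root <- n + 1L
  d <- numeric(n)
  for (tip in seq_len(n)) {
    v <- tip
    while (v != root) { d[tip] <- d[tip] + plen[v]; v <- parent[v] }
  }
  names(d) <- tree$tip.label
  d
}

# OLS via stats::lm (QR) — independent of the centered-sums implementation
oracle_ols <- function(t, d) {
  m <- stats::lm(d ~ t)
  co <- unname(stats::coef(m))
  list(intercept = co[1], slope = co[2],
       rss = sum(stats::resid(m)^2),
       r_squared = summary(m)$r.squared,
       residuals = unname(stats::resid(m)),
       leverage = unname(stats::hatvalues(m)))
}

# Brute-force best-root oracle: for every edge, materialize the rerooted
# tree and refit with lm.fit over a fraction grid. The tree is rebuilt once
# per edge at an interior point; grid points then vary only the two
# root-incident branch lengths (the rerooted trees differ in nothing else).
oracle_best_root <- function(tree, t, grid = seq(0, 1, length.out = 2001),
                             criterion = "rss") {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  children <- tree$edge[, 2]
  best <- list(obj = Inf, edge_child = NA, fraction = NA)
  X1 <- cbind(1, t[tree$tip.label])
  obj_of <- function(d) {
    if (criterion == "rss") sum(stats::lm.fit(X1, d)$residuals^2)
    else mean((d - mean(d))^2)
  }
  for (ei in seq_along(children)) {
    child <- children[ei]
    b <- tree$edge.length[ei]
    if (b == 0) {
      d <- tiptempo::root_to_tip_distances(tiptempo::reroot_at(tree, child, 0))
      o <- obj_of(d[tree$tip.label])
      if (o < best$obj) best <- list(obj = o, edge_child = child, fraction = 0)
      next
    }
    mid <- tiptempo::reroot_at(tree, child, 0.5)
    # the new root's two incident edges carry fractions x*b and (1-x)*b
    rn <- length(mid$tip.label) + 1L
    ri <- which(mid$edge[, 1] == rn)
    stopifnot(length(ri) == 2)
    base_len <- mid$edge.length
    # identify which root edge leads toward the original child's side
    side_tips <- if (child <= n) tree$tip.label[child]
                 else ape::extract.clade(tree, child)$tip.label
    kid1 <- mid$edge[ri[1], 2]
    tips1 <- if (kid1 <= n) mid$tip.label[kid1]
             else ape::extract.clade(mid, kid1)$tip.label
    child_side <- if (setequal(tips1, side_tips)) 1 else 2
    for (x in grid) {
      if (x == 0 || x == 1) {
        d <- tiptempo::root_to_tip_distances(tiptempo::reroot_at(tree, child, x))
      } else {
        # shift the split point by (x - 1/2)*b relative to the midpoint tree;
        # deltas keep any branch the suppressed old root fused into the
        # parent-side root edge
        el <- base_len
        el[ri[child_side]] <- el[ri[child_side]] + (0.5 - x) * b
        el[ri[-child_side][1]] <- el[ri[-child_side][1]] + (x - 0.5) * b
        mid$edge.length <- el
        d <- tiptempo::root_to_tip_distances(mid)
      }
      o <- obj_of(d[tree$tip.label])
      if (o < best$obj - 1e-15)
        best <- list(obj = o, edge_child = child, fraction = x)
    }
  }
  best
}

# edges of a tree as (child, length) in preorder
preorder_children <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  data.frame(child = tree$edge[, 2], len = tree$edge.length)
}

sim_quick <- function(n = 20, seed = 1, noise = 0, rate = 3e-3, ...) {
  simulate_clock_tree(simulation_config(n_tips = n, rate = rate,
                                        rate_noise = noise, seed = seed, ...))
}
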