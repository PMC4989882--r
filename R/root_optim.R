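# Best-fitting-root search. When the root sits at distance x*b from the
# parent end of an edge of length b, every tip's root-to-tip distance is an
# affine function of x: tips below the edge's child see delta_i + (1-x)*b,
# all others gamma_i + x*b. Both rooting criteria — the residual sum of
# squares of the regression (heterochronous) and the population variance of
# root-to-tip distances (isochronous) — depend on the distances only through
# sum(d), sum(d^2) and sum(d*t), so each is an exact quadratic in x on every
# edge. The search therefore evaluates each edge's quadratic at x in
# {0, 1/2, 1}, solves it in closed form, and takes the global minimizer —
# deterministic and O(E) after two tree traversals, with no iterative 1-D
# search and no rerooted tree materialized during the scan.

.CRITERIA <- c("rss", "variance")

# Per-edge affine-coefficient sums via two traversals.
# Postorder: subtree ("in") sums of distances measured from each edge's
# child. Preorder: all-tips sums measured from each vertex, from which the
# complementary ("out") sums measured from each edge's parent follow.
.edge_sums <- function(tree, t = NULL) {
  n <- length(tree$tip.label)
  nv <- n + tree$Nnode
  tree <- ape::reorder.phylo(tree, "cladewise")
  E <- nrow(tree$edge)
  ep <- tree$edge[, 1]; ec <- tree$edge[, 2]; el <- tree$edge.length
  tt <- if (is.null(t)) numeric(n) else as.numeric(t)

  k <- numeric(nv); Sa <- numeric(nv); Saa <- numeric(nv)
  Sat <- numeric(nv); St <- numeric(nv)
  k[seq_len(n)] <- 1
  St[seq_len(n)] <- tt
  for (i in rev(seq_len(E))) {        # postorder: children before parents
    p <- ep[i]; c <- ec[i]; b <- el[i]
    k[p]   <- k[p] + k[c]
    Sa[p]  <- Sa[p] + Sa[c] + k[c] * b
    Saa[p] <- Saa[p] + Saa[c] + 2 * b * Sa[c] + k[c] * b * b
    Sat[p] <- Sat[p] + Sat[c] + b * St[c]
    St[p]  <- St[p] + St[c]
  }
  root <- n + 1L
  F1 <- numeric(nv); F2 <- numeric(nv); Ft <- numeric(nv)
  F1[root] <- Sa[root]; F2[root] <- Saa[root]; Ft[root] <- Sat[root]
  O1 <- numeric(E); O2 <- numeric(E); Ot <- numeric(E)
  for (i in seq_len(E)) {             # preorder: parents before children
    p <- ep[i]; c <- ec[i]; b <- el[i]
    O1[i] <- F1[p] - (Sa[c] + k[c] * b)
    O2[i] <- F2[p] - (Saa[c] + 2 * b * Sa[c] + k[c] * b * b)
    Ot[i] <- Ft[p] - (Sat[c] + b * St[c])
    m <- n - k[c]
    F1[c] <- Sa[c] + O1[i] + m * b
    F2[c] <- Saa[c] + O2[i] + 2 * b * O1[i] + m * b * b
    Ft[c] <- Sat[c] + Ot[i] + b * (St[root] - St[c])
  }
  list(tree = tree, n = n, E = E, child = ec, blen = el,
       k_in = k[ec], Sa_in = Sa[ec], Saa_in = Saa[ec],
       Sat_in = Sat[ec], St_in = St[ec],
       O1 = O1, O2 = O2, Ot = Ot,
       T1 = St[root], Stt = sum((tt - mean(tt))^2))
}

# vectorized objective over all edges at a common fraction x
.objective_from_sums <- function(es, x, criterion) {
  n <- es$n; b <- es$blen; kin <- es$k_in; m <- n - kin
  Sd  <- es$Sa_in + kin * (1 - x) * b + es$O1 + m * x * b
  Sd2 <- es$Saa_in + 2 * (1 - x) * b * es$Sa_in + kin * ((1 - x) * b)^2 +
         es$O2 + 2 * x * b * es$O1 + m * (x * b)^2
  Sdd <- Sd2 - Sd * Sd / n
  if (criterion == "variance") return(Sdd / n)
  Sdt <- es$Sat_in + (1 - x) * b * es$St_in + es$Ot + x * b * (es$T1 - es$St_in)
  cdt <- Sdt - Sd * es$T1 / n
  Sdd - cdt * cdt / es$Stt
}

# closed-form minimum of a*x^2 + b*x + c on [0, 1]; flat / concave cases take
# the better endpoint, ties the smaller fraction
.quad_argmin <- function(a, b, f0, f1) {
  x <- ifelse(a > 0, pmin(1, pmax(0, -b / (2 * a))), ifelse(f1 < f0, 1, 0))
  ifelse(is.finite(x), x, 0)
}

.prep_criterion <- function(tree, dates, criterion) {
  criterion <- match.arg(criterion, .CRITERIA)
  if (criterion == "rss") {
    if (is.null(dates))
      stop("criterion 'rss' needs sampling dates", call. = FALSE)
    if (inherits(dates, "tip_dates")) t <- analysis_times(dates) else t <- dates
    miss <- setdiff(tree$tip.label, names(t))
    if (length(miss))
      stop("no sampling date for tip(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    t <- t[tree$tip.label]
    if (max(t) - min(t) == 0)
      stop("all sampling times are identical: the residual criterion is ",
           "undefined; use criterion = 'variance' (isochronous mode)",
           call. = FALSE)
  } else t <- NULL
  list(criterion = criterion, t = t)
}

#' Evaluate a rooting criterion at an arbitrary root placement
#'
#' Computes the objective — the regression residual sum of squares
#' (\code{"rss"}, heterochronous) or the population variance of root-to-tip
#' distances (\code{"variance"}, isochronous) — for the tree rooted at the
#' given placement, without materializing a rerooted tree: tip distances are
#' assembled from a traversal on each side of the placement edge and are
#' affine in the fraction.
#'
#' @param tree A validated \code{phylo} object.
#' @param placement A \code{\link{root_placement}}.
#' @param dates \code{\link{tip_dates}} (or named forward-time vector);
#'   required for \code{"rss"}, ignored for \code{"variance"}.
#' @param criterion \code{"rss"} or \code{"variance"}.
#' @return The objective value (a single number).
#' @export
objective_at <- function(tree, placement, dates = NULL,
                         criterion = c("rss", "variance")) {
  stopifnot(inherits(tree, "phylo"), inherits(placement, "root_placement"))
  pc <- .prep_criterion(tree, dates, match.arg(criterion))
  n <- length(tree$tip.label)
  child <- .resolve_edge_child(tree, placement$edge_child)
  ei <- match(child, tree$edge[, 2])
  parent <- tree$edge[ei, 1]
  b <- tree$edge.length[ei]
  x <- placement$fraction
  adj <- .tt_adjacency(tree)
  din <- .dist_from(adj, child, block = parent, n)    # clade side, from child
  dout <- .dist_from(adj, parent, block = child, n)   # rest, from parent
  d <- ifelse(is.na(din), dout + x * b, din + (1 - x) * b)
  if (pc$criterion == "variance") {
    return(mean((d - mean(d))^2))
  }
  t <- pc$t
  .ols_centered(t, d)$rss
}

# distances from vertex v to every tip, never crossing the v--block edge;
# tips on the far side come back NA
.dist_from <- function(adj, v, block, n) {
  nv <- length(adj$nbr)
  dist <- rep(NA_real_, nv)
  dist[v] <- 0
  stk_v <- v; stk_p <- if (is.null(block)) 0L else block
  while (length(stk_v)) {
    cur <- stk_v[length(stk_v)]; par <- stk_p[length(stk_p)]
    stk_v <- stk_v[-length(stk_v)]; stk_p <- stk_p[-length(stk_p)]
    nbs <- adj$nbr[[cur]]; lns <- adj$len[[cur]]
    for (j in seq_along(nbs)) {
      w <- nbs[j]
      if (w == par) next
      dist[w] <- dist[cur] + lns[j]
      stk_v <- c(stk_v, w); stk_p <- c(stk_p, cur)
    }
  }
  dist[seq_len(n)]
}

#' Exact quadratic of the rooting objective along one edge
#'
#' Fits the objective's quadratic in the placement fraction through its exact
#' values at x = 0, 1/2, 1 and minimizes it in closed form on [0, 1]; the
#' returned objective value is a direct evaluation at the argmin.
#'
#' @inheritParams objective_at
#' @param edge_child Child node of the edge (tip label or node id).
#' @return An object of class \code{"edge_objective"}: coefficients
#'   \code{a}, \code{b}, \code{c} of \eqn{a x^2 + b x + c}, \code{argmin},
#'   and \code{objective} at the argmin. Zero-length edges report fraction 0.
#' @export
optimize_on_edge <- function(tree, edge_child, dates = NULL,
                             criterion = c("rss", "variance")) {
  pc <- .prep_criterion(tree, dates, match.arg(criterion))
  es <- .edge_sums(tree, pc$t)
  child <- .resolve_edge_child(es$tree, edge_child)
  i <- match(child, es$child)
  if (is.na(i)) stop("edge not found for node ", edge_child, call. = FALSE)
  sub <- lapply(es[c("Sa_in", "Saa_in", "Sat_in", "St_in", "O1", "O2", "Ot",
                     "k_in", "blen", "child")], `[`, i)
  sub <- c(sub, es[c("n", "T1", "Stt")])
  f0 <- .objective_from_sums(sub, 0, pc$criterion)
  fh <- .objective_from_sums(sub, 0.5, pc$criterion)
  f1 <- .objective_from_sums(sub, 1, pc$criterion)
  a <- 2 * (f0 + f1 - 2 * fh)
  bq <- f1 - f0 - a
  xmin <- if (sub$blen == 0) 0 else .quad_argmin(a, bq, f0, f1)
  obj <- .objective_from_sums(sub, xmin, pc$criterion)
  structure(list(edge_child = child,
                 edge_label = .label_for_node(es$tree, child),
                 a = a, b = bq, c = f0, argmin = xmin, objective = obj,
                 criterion = pc$criterion),
            class = "edge_objective")
}

.label_for_node <- function(tree, v) {
  n <- length(tree$tip.label)
  if (v <= n) tree$tip.label[v]
  else if (!is.null(tree$node.label) && nzchar(tree$node.label[v - n]))
    tree$node.label[v - n]
  else paste0("node#", v)
}

#' @export
print.edge_objective <- function(x, ...) {
  cat(sprintf("<edge objective (%s)> edge above %s: %.6g x^2 + %.6g x + %.6g\n",
              x$criterion, x$edge_label, x$a, x$b, x$c))
  cat(sprintf("  argmin %.6g, objective %.6g\n", x$argmin, x$objective))
  invisible(x)
}

#' Find the best-fitting root
#'
#' Scans every edge of the tree for the root placement minimizing the chosen
#' criterion: the residual sum of squares of the root-to-tip regression
#' (heterochronous data, \code{"rss"}) or the population variance of
#' root-to-tip distances (isochronous data, \code{"variance"}). Each edge's
#' objective is an exact quadratic in the placement fraction, so the scan is
#' deterministic and O(E). The input rooting is itself a candidate (fraction
#' 0 on a root-child edge), so the returned objective never exceeds the
#' objective at the supplied root. Ties are broken by preorder edge index,
#' then by the smaller fraction.
#'
#' A negative slope at the best root is reported with a warning, not an
#' error: it simply means the data carry little or no temporal signal.
#'
#' @inheritParams objective_at
#' @return An object of class \code{"best_root"}: \code{placement}
#'   (\code{\link{root_placement}}), \code{tree} (rerooted at it),
#'   \code{objective}, \code{criterion}, and — for \code{"rss"} — \code{fit},
#'   the regression on the rerooted tree; for \code{"variance"},
#'   \code{variance}.
#' @export
#' @examples
#' sim <- simulate_clock_tree(simulation_config(n_tips = 12, seed = 7))
#' br <- find_best_root(sim$tree, sim$dates, "rss")
#' br$fit$slope
find_best_root <- function(tree, dates = NULL,
                           criterion = c("rss", "variance")) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3)
    stop("best-root search needs at least 3 tips", call. = FALSE)
  pc <- .prep_criterion(tree, dates, match.arg(criterion))
  tree <- validate_tree(tree)
  es <- .edge_sums(tree, pc$t)
  f0 <- .objective_from_sums(es, 0, pc$criterion)
  fh <- .objective_from_sums(es, 0.5, pc$criterion)
  f1 <- .objective_from_sums(es, 1, pc$criterion)
  a <- 2 * (f0 + f1 - 2 * fh)
  bq <- f1 - f0 - a
  xmin <- .quad_argmin(a, bq, f0, f1)
  xmin[es$blen == 0] <- 0
  obj <- a * xmin^2 + bq * xmin + f0
  best <- 1L              # strict improvement scan keeps the first (preorder)
  for (i in seq_len(es$E)) if (obj[i] < obj[best]) best <- i
  placement <- root_placement(es$child[best], xmin[best])
  rerooted <- reroot_at(es$tree, placement)
  out <- list(placement = placement,
              placement_label = .label_for_node(es$tree, es$child[best]),
              tree = rerooted, objective = obj[best],
              criterion = pc$criterion)
  if (pc$criterion == "rss") {
    fit <- fit_root_to_tip(pc$t, root_to_tip_distances(rerooted))
    if (fit$slope < 0)
      warning("best-fitting root has a negative rate: the data contain ",
              "little or no temporal signal", call. = FALSE)
    out$fit <- fit
  } else {
    d <- root_to_tip_distances(rerooted)
    out$variance <- mean((d - mean(d))^2)
  }
  structure(out, class = "best_root")
}

#' @export
print.best_root <- function(x, ...) {
  cat(sprintf("Best-fitting root (%s criterion)\n", x$criterion))
  cat(sprintf("  placement: edge above %s, fraction %.6g from parent end\n",
              x$placement_label, x$placement$fraction))
  cat(sprintf("  objective: %.6g\n", x$objective))
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$variance))
    cat(sprintf("  root-to-tip distance variance: %.6g\n", x$variance))
  invisible(x)
}
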