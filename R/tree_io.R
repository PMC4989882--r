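# Trees are ape "phylo" objects throughout: tips are vertices 1..Ntip, internal
# vertices Ntip+1..Ntip+Nnode, the root is Ntip+1, and $edge holds (parent,
# child) rows in preorder (cladewise) order. All branch lengths are genetic
# distances in substitutions/site.

#' Read a newick tree
#'
#' Parses a single newick description into an \code{ape::phylo} tree and
#' validates it for root-to-tip analysis: tip labels must be unique and
#' non-empty, and branch lengths finite. Quoted labels, scientific-notation
#' branch lengths, internal (support) labels and polytomies are accepted.
#' Surrounding single quotes are stripped from labels, so a tip written
#' \code{'A b'} is stored as \code{"A b"}.
#'
#' @param text A newick string terminated by \code{";"}.
#' @param clamp_negative If \code{TRUE}, negative branch lengths (produced by
#'   some distance methods) are clamped to 0 with a warning. The default is to
#'   reject them with an error, since silent clamping can mask exactly the
#'   data problems a temporal-signal check is meant to reveal.
#' @return A rooted \code{phylo} object with an \code{edge.length} vector
#'   (missing lengths are set to 0 with a warning).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):0.5,C:3);")
#' root_to_tip_distances(tr)
read_newick <- function(text, clamp_negative = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  tree <- withCallingHandlers(
    ape::read.tree(text = text),
    warning = function(w) {
      if (grepl("semicolon", conditionMessage(w)))
        stop(sprintf("newick parse error at character %d: tree not terminated by ';'",
                     nchar(text)), call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(tree) || inherits(tree, "multiPhylo"))
    stop("newick parse error: expected a single tree description", call. = FALSE)
  tree$tip.label <- .unquote_labels(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- .unquote_labels(tree$node.label)
  validate_tree(tree, clamp_negative = clamp_negative)
}

#' Read a newick tree from a file
#'
#' @param path Path to a file containing one newick tree.
#' @inheritParams read_newick
#' @return A validated \code{phylo} object.
#' @export
read_tree_file <- function(path, clamp_negative = FALSE) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  read_newick(txt, clamp_negative = clamp_negative)
}

# Fast-fail syntax scan so users get a character position for the common
# breakages (unbalanced parentheses, missing terminator) before ape's parser,
# which reports neither.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at character %d: unbalanced ')'", i),
             call. = FALSE)
    }
  }
  if (in_quote)
    stop("newick parse error: unterminated quoted label", call. = FALSE)
  if (depth != 0L)
    stop(sprintf("newick parse error at character %d: %d unclosed '('",
                 nchar(text), depth), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop(sprintf("newick parse error at character %d: tree not terminated by ';'",
                 nchar(text)), call. = FALSE)
  invisible(TRUE)
}

.unquote_labels <- function(x) {
  quoted <- !is.na(x) & grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Validate a phylogenetic tree for root-to-tip analysis
#'
#' Checks the invariants the rest of the package relies on: unique non-empty
#' tip labels and finite, non-negative branch lengths. Missing branch lengths
#' (common on root edges) become 0 with a warning.
#'
#' @param tree A \code{phylo} object.
#' @inheritParams read_newick
#' @return The (possibly repaired) tree, invisibly valid.
#' @export
validate_tree <- function(tree, clamp_negative = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  lab <- tree$tip.label
  if (any(is.na(lab) | !nzchar(lab)))
    stop("empty tip label at tip index ", which(is.na(lab) | !nzchar(lab))[1],
         call. = FALSE)
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  miss <- !is.finite(tree$edge.length)
  if (any(miss)) {
    warning(sum(miss), " edge(s) with missing branch length treated as 0",
            call. = FALSE)
    tree$edge.length[miss] <- 0
  }
  neg <- tree$edge.length < 0
  if (any(neg)) {
    who <- .edge_names(tree)[neg]
    if (clamp_negative) {
      warning("clamped ", sum(neg), " negative branch length(s) to 0 (edges above: ",
              paste(who, collapse = ", "), ")", call. = FALSE)
      tree$edge.length[neg] <- 0
    } else {
      stop("negative branch length on edge(s) above: ",
           paste(who, collapse = ", "),
           " (use clamp_negative = TRUE to clamp to 0)", call. = FALSE)
    }
  }
  tree
}

# human-readable name for each edge, by its child node
.edge_names <- function(tree) {
  child <- tree$edge[, 2]
  n <- length(tree$tip.label)
  ifelse(child <= n, tree$tip.label[child], paste0("node#", child))
}

#' Serialize a tree to newick
#'
#' Writes topology, labels and branch lengths with 15 significant digits so
#' that \code{read_newick(write_newick(t))} reproduces \code{t} to full
#' double precision. Labels containing newick metacharacters or whitespace
#' are single-quoted (internal quotes doubled).
#'
#' @param tree A \code{phylo} object.
#' @param digits Significant digits for branch lengths (default 15).
#' @return A single newick string ending in \code{";"}.
#' @export
write_newick <- function(tree, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  nv <- n + tree$Nnode
  kids <- vector("list", nv)
  elen <- numeric(nv)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    kids[[p]] <- c(kids[[p]], c)
    elen[c] <- if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[i]
  }
  nlab <- tree$node.label
  fmt <- paste0("%.", digits, "g")
  lab_of <- function(v) {
    if (v <= n) .quote_label(tree$tip.label[v])
    else if (!is.null(nlab) && nzchar(nlab[v - n]) && !is.na(nlab[v - n]))
      .quote_label(nlab[v - n])
    else ""
  }
  root <- n + 1L
  # iterative post-order serialization (recursion overflows on large trees)
  out <- character(nv)
  stack <- root; state <- integer(0)
  visit <- rev(.preorder_vertices(kids, root))
  for (v in visit) {
    if (is.null(kids[[v]])) {
      out[v] <- .quote_label(tree$tip.label[v])
    } else {
      inner <- paste(out[kids[[v]]], collapse = ",")
      out[v] <- paste0("(", inner, ")", lab_of(v))
    }
    if (v != root && !is.na(elen[v]))
      out[v] <- paste0(out[v], ":", sprintf(fmt, elen[v]))
  }
  paste0(out[root], ";")
}

.quote_label <- function(x) {
  if (grepl("[][(){}:;,' \t\n]", x))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

# preorder listing of vertices from an adjacency (children) list
.preorder_vertices <- function(kids, root) {
  nv <- length(kids)
  ord <- integer(nv); top <- 1L; k <- 0L
  stack <- integer(nv); stack[1L] <- root
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; ord[k] <- v
    ch <- kids[[v]]
    for (c in rev(ch)) { top <- top + 1L; stack[top] <- c }
  }
  ord[seq_len(k)]
}

#' Root-to-tip distances
#'
#' Sum of branch lengths (substitutions/site) on the unique path from the
#' root to each tip — the response variable of the temporal-signal
#' regression.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @return A named numeric vector, one entry per tip label.
#' @export
#' @examples
#' root_to_tip_distances(read_newick("((A:1,B:2):0.5,C:3);"))
root_to_tip_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)[seq_len(n)]
  names(d) <- tree$tip.label
  d
}

#' Describe a candidate root placement
#'
#' An edge (identified by its \emph{child} node) plus a fractional position
#' along it, measured from the \strong{parent} end: fraction 0 places the
#' root at the parent node, fraction 1 at the child node.
#'
#' @param edge_child Child node of the edge: a tip label, or an integer node
#'   id in ape numbering.
#' @param fraction Position in \code{[0, 1]} from the parent end.
#' @return An object of class \code{"root_placement"}.
#' @export
root_placement <- function(edge_child, fraction) {
  stopifnot(length(edge_child) == 1L, length(fraction) == 1L,
            is.finite(fraction), fraction >= 0, fraction <= 1)
  structure(list(edge_child = edge_child, fraction = as.numeric(fraction)),
            class = "root_placement")
}

#' @export
print.root_placement <- function(x, ...) {
  cat(sprintf("<root placement> edge above %s, fraction %.6g from parent end\n",
              as.character(x$edge_child), x$fraction))
  invisible(x)
}

# resolve a tip label / node id to a vertex number; must not be the root
.resolve_edge_child <- function(tree, edge_child) {
  n <- length(tree$tip.label)
  root <- n + 1L
  if (is.character(edge_child)) {
    v <- match(edge_child, tree$tip.label)
    if (is.na(v) && !is.null(tree$node.label))
      v <- n + match(edge_child, tree$node.label)
    if (is.na(v)) stop("placement edge not found: no node labelled '",
                       edge_child, "'", call. = FALSE)
  } else {
    v <- as.integer(edge_child)
    if (is.na(v) || v < 1L || v > n + tree$Nnode || v == root)
      stop("placement edge not found: invalid node id ", edge_child,
           call. = FALSE)
  }
  if (v == root) stop("placement edge not found: node is the current root",
                      call. = FALSE)
  v
}

# undirected adjacency (neighbour + length lists) of the tree's metric graph
.tt_adjacency <- function(tree) {
  nv <- length(tree$tip.label) + tree$Nnode
  nbr <- vector("list", nv)
  len <- vector("list", nv)
  el <- tree$edge.length
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    nbr[[p]] <- c(nbr[[p]], c); len[[p]] <- c(len[[p]], el[i])
    nbr[[c]] <- c(nbr[[c]], p); len[[c]] <- c(len[[c]], el[i])
  }
  list(nbr = nbr, len = len)
}

#' Reroot a tree at a point along an edge
#'
#' Places the root at distance \code{fraction * b} from the \emph{parent} end
#' of the edge above \code{edge_child} (length \code{b}), preserving the
#' unrooted metric exactly: every tip-tip path length is unchanged. The
#' operation is pure — a new tree is returned. If the former root is left
#' with degree 2 it is suppressed (its two incident edges fused, lengths
#' summed), so output trees never contain redundant degree-2 nodes. At
#' fraction 0 or 1 the root is placed at the existing parent or child node
#' with no zero-length edge — except fraction 1 on a terminal edge, where a
#' root node is created at the tip's position (a labelled tip cannot serve
#' as the root).
#'
#' @param tree A validated \code{phylo} object.
#' @param placement A \code{\link{root_placement}}, or a tip label/node id
#'   (combined with \code{fraction}).
#' @param fraction Used when \code{placement} is not a \code{root_placement}.
#' @return A new rooted \code{phylo} object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):0.5,C:3);")
#' root_to_tip_distances(reroot_at(tr, "C", 0.5))
reroot_at <- function(tree, placement, fraction = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!inherits(placement, "root_placement")) {
    if (is.null(fraction)) stop("supply a root_placement or a fraction")
    placement <- root_placement(placement, fraction)
  }
  n <- length(tree$tip.label)
  root <- n + 1L
  child <- .resolve_edge_child(tree, placement$edge_child)
  x <- placement$fraction
  ei <- match(child, tree$edge[, 2])
  if (is.na(ei)) stop("placement edge not found for node ", child, call. = FALSE)
  parent <- tree$edge[ei, 1]
  b <- tree$edge.length[ei]

  adj <- .tt_adjacency(tree)
  tip_is <- child <= n
  if (x == 0 || b == 0) {
    new_root <- parent
  } else if (x == 1 && !tip_is) {
    new_root <- child
  } else {
    # split the edge: new vertex nv1 with parent-side length x*b
    nv1 <- n + tree$Nnode + 1L
    g <- x * b
    drop_nb <- function(v, w) {
      k <- which(adj$nbr[[v]] == w)[1]
      adj$nbr[[v]] <<- adj$nbr[[v]][-k]; adj$len[[v]] <<- adj$len[[v]][-k]
    }
    drop_nb(parent, child); drop_nb(child, parent)
    adj$nbr[[nv1]] <- c(parent, child); adj$len[[nv1]] <- c(g, b - g)
    adj$nbr[[parent]] <- c(adj$nbr[[parent]], nv1)
    adj$len[[parent]] <- c(adj$len[[parent]], g)
    adj$nbr[[child]] <- c(adj$nbr[[child]], nv1)
    adj$len[[child]] <- c(adj$len[[child]], b - g)
    new_root <- nv1
  }
  if (new_root == root) return(tree)
  .rebuild_rooted(tree, adj, new_root)
}

# Rebuild a phylo object from the undirected metric graph, rooted at
# `new_root`, suppressing any non-root internal vertex of degree 2 (only the
# old root can be one). Tip numbering keeps the original relative order.
.rebuild_rooted <- function(tree, adj, new_root) {
  n <- length(tree$tip.label)
  old_nlab <- tree$node.label
  edges_p <- integer(0); edges_c <- integer(0); edges_l <- numeric(0)
  # iterative DFS: stack of (vertex, parent-in-rooted-sense)
  stk_v <- new_root; stk_p <- 0L
  order_internal <- integer(0)
  tip_seen <- integer(0)
  children_of <- list()
  while (length(stk_v)) {
    v <- stk_v[length(stk_v)]; pv <- stk_p[length(stk_p)]
    stk_v <- stk_v[-length(stk_v)]; stk_p <- stk_p[-length(stk_p)]
    if (v > n || v == new_root) order_internal <- c(order_internal, v)
    nbs <- adj$nbr[[v]]; lns <- adj$len[[v]]
    keep <- nbs != pv
    nbs <- nbs[keep]; lns <- lns[keep]
    for (k in seq_along(nbs)) {
      c0 <- nbs[k]; l0 <- lns[k]; prev <- v
      # splice through degree-2 internal vertices (the suppressed old root)
      repeat {
        if (c0 <= n) break
        onb <- adj$nbr[[c0]]
        if (length(onb) != 2L) break
        nxt <- onb[onb != prev]
        if (length(nxt) != 1L) break
        l0 <- l0 + adj$len[[c0]][which(onb == nxt)[1]]
        prev <- c0; c0 <- nxt
      }
      edges_p <- c(edges_p, v); edges_c <- c(edges_c, c0); edges_l <- c(edges_l, l0)
      if (c0 <= n) tip_seen <- c(tip_seen, c0)
      stk_v <- c(stk_v, c0); stk_p <- c(stk_p, prev)
    }
  }
  # renumber: tips keep original ids; internals numbered in preorder
  internal_old <- unique(c(new_root, edges_p))
  new_id <- integer(n + tree$Nnode + 1L)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[internal_old] <- n + seq_along(internal_old)
  edge <- cbind(new_id[edges_p], new_id[edges_c])
  # preorder edge ordering (ape cladewise): sort by DFS discovery of child
  out <- list(edge = edge, edge.length = edges_l,
              tip.label = tree$tip.label, Nnode = length(internal_old))
  if (!is.null(old_nlab)) {
    nlab <- rep("", length(internal_old))
    keep_old <- internal_old[internal_old > n & internal_old <= n + tree$Nnode]
    nlab[match(keep_old, internal_old)] <- old_nlab[keep_old - n]
    out$node.label <- nlab
  }
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Tip-tip path-length matrix
#'
#' Patristic distances between all tip pairs; invariant under rerooting and
#' therefore the canonical check that \code{\link{reroot_at}} preserved the
#' unrooted metric.
#'
#' @param tree A \code{phylo} object.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
tip_distance_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}
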