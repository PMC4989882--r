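# Clock-tree simulator with known ground truth. Every other module is
# testable against it without external data: the generator draws a
# serial-sample (heterochronous) coalescent genealogy, converts branch
# durations to genetic distances at a known substitution rate — optionally
# with lognormal per-branch rate multipliers emulating a relaxed clock —
# and can inject the three classic data-quality anomalies: a frozen
# (archived/vaccine) strain, a misdated tip, and an over-diverged tip.

#' Simulation configuration
#'
#' @param n_tips Number of tips (>= 3).
#' @param rate True substitution rate u, substitutions/site/year (> 0).
#' @param sampling_window Two-element numeric: earliest and latest sampling
#'   time (decimal years); tips sample uniformly within it.
#' @param root_time Floor on the root date (years): if the coalescent's
#'   TMRCA lands later than this, the root is pushed back to it (both
#'   root-child branches lengthened equally, preserving the clock). Must
#'   precede the sampling window.
#' @param rate_noise Standard deviation (log scale) of the lognormal
#'   per-branch rate multiplier; 0 = strict clock.
#' @param ne Coalescent timescale (effective population size in years);
#'   waiting time between joins among k active lineages is
#'   Exp(choose(k, 2) / ne).
#' @param anomalies List of anomaly descriptors, each a list with
#'   \code{type} (\code{"frozen"}, \code{"misdated"} or \code{"divergent"}),
#'   \code{tip} (label, or \code{NA} to pick one at random), and
#'   \code{years} (frozen storage / misdating shift) or \code{distance}
#'   (extra divergence).
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_tips = 50, rate = 3e-3,
                              sampling_window = c(2000, 2010),
                              root_time = 1990, rate_noise = 0, ne = 5,
                              anomalies = list(), seed = 1L) {
  stopifnot(n_tips >= 3, rate > 0, rate_noise >= 0, ne > 0,
            length(sampling_window) == 2, diff(sampling_window) > 0)
  if (root_time >= sampling_window[1])
    stop("infeasible config: root_time must precede the sampling window",
         call. = FALSE)
  for (a in anomalies) {
    if (!is.list(a) || is.null(a$type) ||
        !a$type %in% c("frozen", "misdated", "divergent"))
      stop("anomaly type must be 'frozen', 'misdated' or 'divergent'",
           call. = FALSE)
  }
  structure(list(n_tips = as.integer(n_tips), rate = rate,
                 sampling_window = sampling_window, root_time = root_time,
                 rate_noise = rate_noise, ne = ne, anomalies = anomalies,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a heterochronous clock tree with known truth
#'
#' Draws tip sampling times uniformly in the window, builds a genealogy by
#' random pairwise joins backward in time with exponential waiting times
#' (serial-sample coalescent), then scales each branch's duration by the
#' true rate times an optional lognormal multiplier to obtain genetic branch
#' lengths. With \code{rate_noise = 0} and no anomalies the root-to-tip
#' regression on the true rooting is exact: r^2 = 1, slope = rate,
#' x-intercept = root time.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List of class \code{"clock_sim"}: \code{tree} (genetic-distance
#'   \code{phylo}, true rooting), \code{dates} (\code{\link{tip_dates}},
#'   forward), and \code{truth}: \code{rate}, \code{root_time} (realized
#'   TMRCA date), \code{tip_times}, \code{node_times}, \code{anomalies}
#'   (with resolved tip labels), \code{seed}.
#' @export
#' @examples
#' sim <- simulate_clock_tree(simulation_config(n_tips = 10, seed = 42))
#' fit_root_to_tip(sim$dates, root_to_tip_distances(sim$tree))$r_squared
simulate_clock_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_tips
  labels <- sprintf("tip%02d", seq_len(n))
  t_tip <- stats::runif(n, config$sampling_window[1], config$sampling_window[2])
  names(t_tip) <- labels

  # serial coalescent backward in time; vertex times for 2n-1 vertices
  nv <- 2L * n - 1L
  vtime <- numeric(nv)
  vtime[seq_len(n)] <- t_tip
  ord <- order(t_tip, decreasing = TRUE)     # enter lineages latest-first
  active <- integer(0)
  pending <- ord
  cur <- t_tip[pending[1]]
  next_node <- n + 1L
  edges <- matrix(0L, nrow = nv - 1L, ncol = 2L)
  ne_edges <- 0L
  repeat {
    while (length(pending) && t_tip[pending[1]] >= cur - 1e-12) {
      active <- c(active, pending[1]); pending <- pending[-1]
    }
    if (length(active) + length(pending) <= 1L && length(active) == 1L) break
    k <- length(active)
    if (k < 2L) {
      cur <- t_tip[pending[1]]
      next
    }
    w <- stats::rexp(1, rate = choose(k, 2) / config$ne)
    if (length(pending) && cur - w < t_tip[pending[1]]) {
      cur <- t_tip[pending[1]]
      next
    }
    cur <- cur - w
    pair <- sample.int(k, 2)
    joined <- active[pair]
    vtime[next_node] <- cur
    ne_edges <- ne_edges + 1L
    edges[ne_edges, ] <- c(next_node, joined[1])
    ne_edges <- ne_edges + 1L
    edges[ne_edges, ] <- c(next_node, joined[2])
    active <- c(active[-pair], next_node)
    next_node <- next_node + 1L
  }
  root_v <- active[1]
  # floor the root at root_time: lengthening both root-child durations by the
  # same amount keeps the genealogy clock-like
  if (vtime[root_v] > config$root_time) vtime[root_v] <- config$root_time

  # assemble phylo: renumber so root becomes n+1 in preorder
  kids <- vector("list", nv)
  for (i in seq_len(ne_edges))
    kids[[edges[i, 1]]] <- c(kids[[edges[i, 1]]], edges[i, 2])
  ordv <- .preorder_vertices(kids, root_v)
  internal <- ordv[ordv > n]
  new_id <- integer(nv)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[internal] <- n + seq_along(internal)
  emat <- matrix(0L, ne_edges, 2)
  elen <- numeric(ne_edges)
  j <- 0L
  mult <- function() if (config$rate_noise == 0) 1
                     else stats::rlnorm(1, 0, config$rate_noise)
  # deterministic edge order for the rate-noise draws: preorder
  for (v in ordv) for (c in kids[[v]]) {
    j <- j + 1L
    emat[j, ] <- c(new_id[v], new_id[c])
    dur <- vtime[c] - vtime[v]
    elen[j] <- config$rate * dur * mult()
  }
  tree <- structure(list(edge = emat, edge.length = elen,
                         tip.label = labels, Nnode = n - 1L),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")

  dates <- tip_dates(t_tip, "forward")
  truth <- list(rate = config$rate, root_time = vtime[root_v],
                tip_times = t_tip,
                node_times = stats::setNames(vtime[c(seq_len(n), internal)],
                                             c(labels, rep(NA, length(internal)))),
                anomalies = list(), seed = config$seed)

  for (a in config$anomalies) {
    tip <- if (is.null(a$tip) || is.na(a$tip))
      sample(labels, 1) else a$tip
    inj <- inject_anomaly(tree, dates,
                          c(a[setdiff(names(a), "tip")], list(tip = tip)))
    tree <- inj$tree; dates <- inj$dates
    truth$anomalies <- c(truth$anomalies, list(inj$truth))
  }
  structure(list(tree = tree, dates = dates, truth = truth),
            class = "clock_sim")
}

#' Inject a data-quality anomaly into a simulated data set
#'
#' \describe{
#'   \item{frozen}{adds \code{years} of storage to the tip's \emph{date}
#'     only — the archived strain accrued no divergence while frozen, so it
#'     falls below the regression line;}
#'   \item{misdated}{shifts the tip's date by \code{years} (either sign) —
#'     a mislabelled sampling date, visible as a large x-displacement;}
#'   \item{divergent}{adds \code{distance} substitutions/site to the
#'     terminal branch — a recombinant or low-quality sequence, visible as a
#'     large positive y-residual.}
#' }
#'
#' @param tree A \code{phylo} tree.
#' @param dates A \code{\link{tip_dates}}.
#' @param anomaly List with \code{type}, \code{tip}, and \code{years} or
#'   \code{distance} as above.
#' @return List: modified \code{tree}, \code{dates}, and \code{truth} record
#'   of the edit (type, tip, amount).
#' @export
inject_anomaly <- function(tree, dates, anomaly) {
  stopifnot(inherits(tree, "phylo"), inherits(dates, "tip_dates"),
            is.list(anomaly))
  tip <- anomaly$tip
  if (is.null(tip) || !tip %in% tree$tip.label)
    stop("unknown tip for anomaly: ", tip, call. = FALSE)
  type <- match.arg(anomaly$type, c("frozen", "misdated", "divergent"))
  truth <- list(type = type, tip = tip)
  if (type %in% c("frozen", "misdated")) {
    yrs <- anomaly$years
    if (is.null(yrs)) stop("anomaly needs 'years'", call. = FALSE)
    sgn <- if (dates$direction == "backward") -1 else 1
    shift <- if (type == "frozen") abs(yrs) else yrs
    dates$times[tip] <- dates$times[tip] + sgn * shift
    truth$years <- shift
  } else {
    extra <- anomaly$distance
    if (is.null(extra)) stop("'divergent' anomaly needs 'distance'", call. = FALSE)
    v <- match(tip, tree$tip.label)
    ei <- match(v, tree$edge[, 2])
    tree$edge.length[ei] <- tree$edge.length[ei] + extra
    if (tree$edge.length[ei] < 0)
      stop("'divergent' anomaly would make the terminal branch negative",
           call. = FALSE)
    truth$distance <- extra
  }
  list(tree = tree, dates = dates, truth = truth)
}

#' Reroot a tree at a random placement
#'
#' Presents a simulated (or any) rooted tree as if it had been arbitrarily
#' rooted by a distance method: picks a uniform non-root-adjacent edge and a
#' uniform interior fraction. Used to exercise the best-root search against
#' known truth.
#'
#' @param tree A \code{phylo} tree.
#' @param seed Optional integer seed.
#' @return List: \code{tree} (rerooted), \code{placement} used.
#' @export
random_reroot <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  children <- tree$edge[, 2]
  i <- sample(length(children), 1)
  frac <- stats::runif(1, 0.05, 0.95)
  placement <- root_placement(children[i], frac)
  list(tree = reroot_at(tree, placement), placement = placement)
}
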