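# Data-quality views on the root-to-tip regression. Two anomaly geometries
# are distinguished: a large y-residual (tip far above/below the line — too
# much or too little divergence for its date: sequencing/assembly/alignment
# error, recombination, hypermutation) and a large x-displacement (tip far
# left/right of the line — the stated date does not match the divergence:
# mislabelling, contamination, archived/vaccine strains dated at
# sequencing rather than storage time). Attribution of cause is left to the
# user; these are exploration aids, not tests.

#' Ancestor traces
#'
#' For each tip, connects its regression point (t_i, d_i) to the point on
#' the fitted line whose distance equals the root-to-tip distance of the
#' tip's immediate ancestral node, d_p: the trace point is
#' (t_r + d_p / u, d_p). A tip whose terminal branch hangs from an
#' early-diverging ancestor produces a long horizontal trace — the signature
#' of a dating problem rather than a divergence problem.
#'
#' @param tree The rooted \code{phylo} tree the regression was fitted on.
#' @param fit The \code{rtt_fit} for that tree (nonzero slope required).
#' @return Data frame of class \code{"ancestor_traces"}: \code{tip},
#'   \code{time}, \code{distance}, \code{parent_divergence} (d_p),
#'   \code{trace_time} (t_r + d_p/u). \code{parent_divergence <= distance}
#'   always, with equality only for zero-length terminal branches.
#' @export
ancestor_traces <- function(tree, fit) {
  stopifnot(inherits(tree, "phylo"), inherits(fit, "rtt_fit"))
  if (fit$slope == 0)
    stop("ancestor traces are undefined without a temporal trend (zero slope)",
         call. = FALSE)
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  parent <- integer(n)
  parent[tree$edge[tree$edge[, 2] <= n, 2]] <- tree$edge[tree$edge[, 2] <= n, 1]
  dp <- depth[parent]
  names(dp) <- tree$tip.label
  pts <- fit$points
  common <- intersect(pts$tip, names(dp))
  if (length(common) < nrow(pts))
    stop("tree and regression points disagree on tip labels", call. = FALSE)
  pts <- pts[match(common, pts$tip), ]
  out <- data.frame(tip = pts$tip, time = pts$time, distance = pts$distance,
                    parent_divergence = dp[common],
                    trace_time = fit$x_intercept + dp[common] / fit$slope,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ancestor_traces", "data.frame")
  out
}

#' Classify tips against the regression line
#'
#' Assigns every tip a side (\code{"above"} iff its y-residual is strictly
#' positive; a residual of exactly 0 is \code{"below"} by a fixed
#' convention, for determinism), its x-displacement — the horizontal
#' distance from the tip's point to the line at the tip's divergence,
#' \eqn{t_i - (t_r + d_i/u)}, defined only for nonzero slope — and an
#' outlier flag: \code{TRUE} iff |y-residual| exceeds \code{k} sample
#' standard deviations of the y-residuals. The default k = 3 is a
#' convenience only; raw residuals are always reported so users can apply
#' their own judgement.
#'
#' @param fit An \code{rtt_fit}.
#' @param k Positive standardized-residual threshold (default 3).
#' @return Data frame of class \code{"tip_flags"}: \code{tip}, \code{time},
#'   \code{distance}, \code{residual}, \code{x_displacement}, \code{side},
#'   \code{flagged}.
#' @export
classify_tips <- function(fit, k = 3) {
  stopifnot(inherits(fit, "rtt_fit"), is.numeric(k), k > 0)
  pts <- fit$points
  res <- pts$residual
  sdres <- stats::sd(res)
  xdisp <- if (fit$slope == 0) rep(NA_real_, nrow(pts))
           else pts$time - (fit$x_intercept + pts$distance / fit$slope)
  out <- data.frame(
    tip = pts$tip, time = pts$time, distance = pts$distance,
    residual = res, x_displacement = xdisp,
    side = ifelse(res > 0, "above", "below"),
    flagged = if (is.na(sdres) || sdres == 0) rep(FALSE, nrow(pts))
              else abs(res) > k * sdres,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tip_flags", "data.frame")
  out
}

#' Residual summary: histogram and scatter
#'
#' Histogram of the y-residuals (Freedman-Diaconis bin rule, at least 5
#' bins; degenerate all-equal residuals get a single bin) plus the
#' (fitted value, residual) scatter pairs ordered by fitted value.
#'
#' @param fit An \code{rtt_fit} with at least 3 points.
#' @return List of class \code{"residual_summary"}: \code{breaks},
#'   \code{counts}, \code{mids}, \code{bin_rule}, and \code{scatter} (data
#'   frame of fitted, residual).
#' @export
residual_summary <- function(fit) {
  stopifnot(inherits(fit, "rtt_fit"))
  res <- fit$points$residual
  if (length(res) < 3) stop("need at least 3 points", call. = FALSE)
  rng <- max(res) - min(res)
  if (rng == 0) {
    w <- max(abs(res[1]), 1) * 1e-8
    h <- list(breaks = c(res[1] - w, res[1] + w),
              counts = length(res), mids = res[1])
    rule <- "degenerate (all residuals equal): single bin"
  } else {
    nb <- max(5L, grDevices::nclass.FD(res))
    h <- graphics::hist(res, breaks = nb, plot = FALSE)
    rule <- sprintf("Freedman-Diaconis, minimum 5 bins (%d used)",
                    length(h$counts))
  }
  ord <- order(fit$points$fitted)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 bin_rule = rule,
                 scatter = data.frame(fitted = fit$points$fitted[ord],
                                      residual = res[ord])),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat("Residual summary (", nrow(x$scatter), " points)\n", sep = "")
  cat("  bins: ", x$bin_rule, "\n", sep = "")
  cat("  counts: ", paste(x$counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Assemble the per-tip diagnostics table
#'
#' Joins the regression points, tip classification and ancestor traces into
#' the table written as \code{PREFIX.diagnostics.tsv} by
#' \code{\link{analyze}}.
#'
#' @inheritParams ancestor_traces
#' @param k Outlier threshold, see \code{\link{classify_tips}}.
#' @return Data frame: tip, date, distance, residual, x_displacement, side,
#'   flagged, parent_divergence, trace_time (the last two \code{NA} when the
#'   slope is zero).
#' @export
diagnostics_table <- function(tree, fit, k = 3) {
  flags <- classify_tips(fit, k)
  if (fit$slope != 0) {
    tr <- ancestor_traces(tree, fit)
    flags$parent_divergence <- tr$parent_divergence[match(flags$tip, tr$tip)]
    flags$trace_time <- tr$trace_time[match(flags$tip, tr$tip)]
  } else {
    flags$parent_divergence <- NA_real_
    flags$trace_time <- NA_real_
  }
  names(flags)[names(flags) == "time"] <- "date"
  class(flags) <- "data.frame"
  flags
}
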