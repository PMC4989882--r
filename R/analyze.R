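# End-to-end workflow: load tree -> attach dates -> (optionally) best-root
# -> regression -> diagnostics -> files. This is the non-interactive
# equivalent of the classic point-and-click temporal-signal check.

#' Run the full root-to-tip analysis
#'
#' Heterochronous mode (dates supplied): fits the root-to-tip regression,
#' optionally after a best-fitting-root search, and produces the per-tip
#' diagnostics. Isochronous mode (\code{dates = NULL}): reports the
#' histogram of root-to-tip distances and, with \code{best_root = TRUE},
#' the variance-minimizing root. A negative slope is a warning in the
#' report, never a failure.
#'
#' @param tree A \code{phylo} object, a newick string, or a path to a
#'   newick file.
#' @param dates A \code{\link{tip_dates}}, a path to a tab-delimited date
#'   table, or \code{NULL} for isochronous mode.
#' @param best_root Search all edges for the optimal root placement.
#' @param criterion Rooting criterion; defaults to \code{"rss"} when dates
#'   are present, \code{"variance"} otherwise.
#' @param outlier_k Standardized-residual threshold for flagging tips.
#' @param backward Treat table/label dates as years before present.
#' @param clamp_negative Clamp negative branch lengths to 0 (warning)
#'   instead of failing.
#' @param drop_undated Drop tips without dates (with a logged list) instead
#'   of failing.
#' @param out_prefix If non-NULL, write \code{PREFIX.rooted.nwk},
#'   \code{PREFIX.rtt.tsv}, \code{PREFIX.diagnostics.tsv},
#'   \code{PREFIX.stats.json} (and \code{PREFIX.plot.svg} with
#'   \code{plot = TRUE}).
#' @param plot Attempt the regression/residual plot; plotting failures never
#'   fail the analysis.
#' @return An \code{"analysis_report"}: input digest, mode, rooting record,
#'   \code{fit} (heterochronous) or \code{distance_summary} (isochronous),
#'   \code{diagnostics} data frame, accumulated \code{warnings}, and
#'   \code{files} written.
#' @export
#' @examples
#' sim <- simulate_clock_tree(simulation_config(n_tips = 15, seed = 3))
#' rep <- analyze(sim$tree, sim$dates, best_root = TRUE)
#' rep$fit$slope
analyze <- function(tree, dates = NULL, best_root = FALSE,
                    criterion = NULL, outlier_k = 3, backward = FALSE,
                    clamp_negative = FALSE, drop_undated = FALSE,
                    out_prefix = NULL, plot = FALSE) {
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  tree_src <- if (is.character(tree)) tree else "<phylo object>"
  tree <- withCallingHandlers(.as_tree(tree, clamp_negative),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  dates_src <- if (is.character(dates)) dates
               else if (is.null(dates)) "<none>" else "<tip_dates object>"
  if (is.character(dates))
    dates <- load_dates_table(dates, if (backward) "backward" else "forward")

  mode <- if (is.null(dates)) "isochronous" else "heterochronous"
  if (is.null(criterion))
    criterion <- if (mode == "heterochronous") "rss" else "variance"

  if (mode == "heterochronous") {
    chk <- match_dates_to_tree(tree, dates)
    if (length(chk$missing_dates)) {
      if (drop_undated) {
        note(paste0("dropped ", length(chk$missing_dates), " undated tip(s): ",
                    paste(chk$missing_dates, collapse = ", ")))
        tree <- ape::drop.tip(tree, chk$missing_dates)
        if (is.null(tree) || length(tree$tip.label) < 3)
          stop("fewer than 3 dated tips remain after dropping undated tips",
               call. = FALSE)
      } else {
        stop("no sampling date for tip(s): ",
             paste(chk$missing_dates, collapse = ", "),
             " (use drop_undated = TRUE to exclude them)", call. = FALSE)
      }
    }
  }

  rooting <- list(source = "user-supplied", placement = NULL)
  objective <- NULL
  if (best_root) {
    br <- withCallingHandlers(
      find_best_root(tree, dates, criterion),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    tree <- br$tree
    objective <- br$objective
    rooting <- list(source = "best-fit",
                    placement = list(edge_child = br$placement_label,
                                     fraction = br$placement$fraction),
                    objective = br$objective, criterion = criterion)
  }

  dists <- root_to_tip_distances(tree)
  report <- list(
    input = list(tree = tree_src, n_tips = length(tree$tip.label),
                 date_source = dates_src),
    mode = mode, rooting = rooting, warnings = character(0), files = character(0))

  if (mode == "heterochronous") {
    fit <- fit_root_to_tip(dates, dists)
    if (fit$slope < 0)
      note("negative rate estimate: the data contain little or no temporal signal")
    report$fit <- fit
    report$diagnostics <- diagnostics_table(tree, fit, k = outlier_k)
  } else {
    report$distance_summary <- .distance_histogram(dists)
    if (!is.null(objective)) report$variance <- objective
  }
  report$tree <- tree
  report$warnings <- warnings
  class(report) <- "analysis_report"

  if (!is.null(out_prefix))
    report <- .write_outputs(report, out_prefix, plot = plot)
  report
}

.as_tree <- function(tree, clamp_negative) {
  if (inherits(tree, "phylo")) return(validate_tree(tree, clamp_negative))
  stopifnot(is.character(tree), length(tree) == 1L)
  if (grepl(";\\s*$", tree) && grepl("\\(", tree))
    read_newick(tree, clamp_negative)
  else read_tree_file(tree, clamp_negative)
}

.distance_histogram <- function(dists) {
  if (max(dists) - min(dists) == 0) {
    list(breaks = c(dists[1] - 1e-8, dists[1] + 1e-8),
         counts = length(dists), mids = dists[1],
         mean = mean(dists), variance = 0)
  } else {
    h <- graphics::hist(dists, breaks = max(5L, grDevices::nclass.FD(dists)),
                        plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids,
         mean = mean(dists), variance = mean((dists - mean(dists))^2))
  }
}

.write_outputs <- function(report, prefix, plot = FALSE) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f_tree <- paste0(prefix, ".rooted.nwk")
  writeLines(write_newick(report$tree), f_tree)
  files <- c(files, f_tree)
  stats <- list(
    n = report$input$n_tips, mode = report$mode, rooting = report$rooting,
    warnings = report$warnings)
  if (report$mode == "heterochronous") {
    fit <- report$fit
    f_rtt <- paste0(prefix, ".rtt.tsv")
    utils::write.table(
      data.frame(tip = fit$points$tip, date = fit$points$time,
                 distance = fit$points$distance,
                 residual = fit$points$residual),
      f_rtt, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f_rtt)
    f_diag <- paste0(prefix, ".diagnostics.tsv")
    utils::write.table(report$diagnostics, f_diag, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f_diag)
    stats <- c(stats, list(
      slope = fit$slope, intercept = fit$intercept,
      x_intercept = if (is.nan(fit$x_intercept)) "undefined" else fit$x_intercept,
      r = fit$r, r_squared = fit$r_squared, rss = fit$rss))
  } else {
    stats <- c(stats, list(distance_mean = report$distance_summary$mean,
                           distance_variance = report$distance_summary$variance,
                           histogram = report$distance_summary[c("breaks", "counts")]))
  }
  f_json <- paste0(prefix, ".stats.json")
  jsonlite::write_json(stats, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, f_json)
  if (plot) {
    f_plot <- paste0(prefix, ".plot.svg")
    ok <- tryCatch({ .plot_report(report, f_plot); TRUE },
                   error = function(e) FALSE)
    if (ok) files <- c(files, f_plot)
  }
  report$files <- files
  report
}

# regression scatter + fitted line + ancestor traces, and residual histogram
.plot_report <- function(report, path) {
  grDevices::svg(path, width = 10, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  if (report$mode == "heterochronous") {
    fit <- report$fit
    pts <- fit$points
    graphics::plot(pts$time, pts$distance, pch = 19, cex = 0.6,
                   col = ifelse(pts$residual > 0, "firebrick", "steelblue"),
                   xlab = "sampling time (years)",
                   ylab = "root-to-tip distance (subs/site)",
                   main = sprintf("rate %.3g, r2 %.3g", fit$slope, fit$r_squared))
    graphics::abline(fit$intercept, fit$slope, lwd = 2)
    if (fit$slope != 0 && !is.null(report$diagnostics$trace_time))
      graphics::segments(pts$time, pts$distance,
                         report$diagnostics$trace_time[match(pts$tip, report$diagnostics$tip)],
                         report$diagnostics$parent_divergence[match(pts$tip, report$diagnostics$tip)],
                         col = grDevices::adjustcolor("darkgreen", 0.5))
    rs <- residual_summary(fit)
    graphics::hist(pts$residual, breaks = rs$breaks, main = "residuals",
                   xlab = "residual (subs/site)")
  } else {
    ds <- report$distance_summary
    graphics::plot(ds$mids, ds$counts, type = "h", lwd = 5,
                   xlab = "root-to-tip distance (subs/site)", ylab = "count",
                   main = "isochronous: distance histogram")
    graphics::plot.new()
  }
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Root-to-tip analysis (", x$mode, " mode, ", x$input$n_tips,
      " tips)\n", sep = "")
  cat("  rooting: ", x$rooting$source, sep = "")
  if (!is.null(x$rooting$placement))
    cat(sprintf(" (edge above %s, fraction %.4g)",
                x$rooting$placement$edge_child, x$rooting$placement$fraction))
  cat("\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$distance_summary))
    cat(sprintf("  distance mean %.6g, variance %.6g\n",
                x$distance_summary$mean, x$distance_summary$variance))
  for (w in x$warnings) cat("  WARNING: ", w, "\n", sep = "")
  if (length(x$files)) cat("  files: ", paste(basename(x$files), collapse = ", "),
                           "\n", sep = "")
  invisible(x)
}

#' Pre-flight validation of tree and dates
#'
#' Checks the inputs without running the analysis: tip/date symmetric
#' difference, duplicate labels, negative or missing branch lengths, and
#' date parse failures. Always returns a record; problems are content, not
#' errors.
#'
#' @param tree Path to a newick file, newick string, or \code{phylo}.
#' @param dates Path to a date table, \code{\link{tip_dates}}, or
#'   \code{NULL}.
#' @param backward Treat table dates as years before present.
#' @return List of class \code{"validation_record"}: \code{problems}
#'   (character vector, empty when clean), plus detail fields
#'   \code{missing_dates}, \code{extra_dates}, \code{duplicate_labels},
#'   \code{negative_edges}, \code{missing_lengths}, \code{date_errors}.
#' @export
validate_inputs <- function(tree, dates = NULL, backward = FALSE) {
  problems <- character(0)
  rec <- list(missing_dates = character(0), extra_dates = character(0),
              duplicate_labels = character(0), negative_edges = character(0),
              missing_lengths = 0L, date_errors = character(0))
  tr <- tryCatch({
    if (inherits(tree, "phylo")) tree
    else if (grepl(";\\s*$", tree) && grepl("\\(", tree))
      ape::read.tree(text = tree)
    else ape::read.tree(tree)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    problems <- c(problems, "tree: not parseable as newick")
  } else {
    tr$tip.label <- .unquote_labels(tr$tip.label)
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    if (length(dup)) {
      rec$duplicate_labels <- dup
      problems <- c(problems, paste0("tree: duplicate tip label(s): ",
                                     paste(dup, collapse = ", ")))
    }
    if (is.null(tr$edge.length)) {
      rec$missing_lengths <- nrow(tr$edge)
      problems <- c(problems, "tree: no branch lengths")
    } else {
      nmiss <- sum(!is.finite(tr$edge.length))
      if (nmiss) {
        rec$missing_lengths <- nmiss
        problems <- c(problems, paste0("tree: ", nmiss,
                                       " edge(s) missing a branch length"))
      }
      neg <- which(tr$edge.length < 0)
      if (length(neg)) {
        rec$negative_edges <- .edge_names(tr)[neg]
        problems <- c(problems,
                      paste0("tree: negative branch length above: ",
                             paste(rec$negative_edges, collapse = ", ")))
      }
    }
  }
  dt <- NULL
  if (!is.null(dates)) {
    dt <- tryCatch({
      if (inherits(dates, "tip_dates")) dates
      else load_dates_table(dates, if (backward) "backward" else "forward")
    }, error = function(e) {
      rec$date_errors <<- conditionMessage(e)
      NULL
    })
    if (is.null(dt)) {
      problems <- c(problems, paste0("dates: ", rec$date_errors))
    } else if (!is.null(tr)) {
      chk <- match_dates_to_tree(tr, dt)
      rec$missing_dates <- chk$missing_dates
      rec$extra_dates <- chk$extra_dates
      if (length(chk$missing_dates))
        problems <- c(problems, paste0("dates: no date for tip(s): ",
                                       paste(chk$missing_dates, collapse = ", ")))
      if (length(chk$extra_dates))
        problems <- c(problems, paste0("dates: dated label(s) not in tree: ",
                                       paste(chk$extra_dates, collapse = ", ")))
    }
  }
  structure(c(list(problems = problems), rec), class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  if (!length(x$problems)) {
    cat("validation: no problems found\n")
  } else {
    cat("validation: ", length(x$problems), " problem(s)\n", sep = "")
    for (p in x$problems) cat("  - ", p, "\n", sep = "")
  }
  invisible(x)
}
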