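# Ordinary least squares of root-to-tip distance d on sampling time t:
#   E[d_i] = u * (t_i - t_root)
# The slope is the substitution rate u (subs/site/year); the x-intercept is
# the point estimate of the root date t_root. Because tips share ancestry the
# points are not independent, so no p-values or confidence intervals are
# produced anywhere: r and r^2 are informal dispersion measures only.

#' Fit the root-to-tip regression
#'
#' Ordinary least squares (with intercept) of root-to-tip genetic distance
#' on sampling time, accumulated with centered sums for numerical stability
#' at large n. A negative slope is a legal result — it indicates little or
#' no temporal signal, not an error.
#'
#' @param times Named numeric vector of sampling times (decimal years,
#'   forward scale), or a \code{\link{tip_dates}} object.
#' @param distances Named numeric vector of root-to-tip distances
#'   (substitutions/site). Names must match \code{times}.
#' @return An object of class \code{"rtt_fit"}: a list with \code{slope}
#'   (rate, subs/site/year), \code{intercept}, \code{x_intercept} (root-time
#'   estimate; \code{NaN} when the slope is 0), \code{r}, \code{r_squared}
#'   (0 when the distances have zero variance), \code{rss}, \code{n}, and a
#'   \code{points} data frame (tip, time, distance, fitted, residual).
#' @export
#' @examples
#' fit_root_to_tip(c(a = 5, b = 10, c = 15), c(a = 0.5, b = 1.0, c = 1.5))
fit_root_to_tip <- function(times, distances) {
  if (inherits(times, "tip_dates")) times <- analysis_times(times)
  if (is.null(names(times)) || is.null(names(distances)))
    stop("times and distances must be named by tip label", call. = FALSE)
  common <- intersect(names(times), names(distances))
  miss <- setdiff(names(distances), names(times))
  if (length(miss))
    stop("no sampling date for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  t <- as.numeric(times[common])
  d <- as.numeric(distances[common])
  n <- length(common)
  if (n < 3)
    stop("root-to-tip regression needs at least 3 tips (got ", n, ")",
         call. = FALSE)
  if (max(t) - min(t) == 0)
    stop("all sampling times are identical: no regression is possible; ",
         "use the isochronous analysis (variance of root-to-tip distances) ",
         "instead", call. = FALSE)
  fit <- .ols_centered(t, d)
  fitted <- fit$intercept + fit$slope * t
  resid <- d - fitted
  structure(c(fit, list(
    n = n,
    points = data.frame(tip = common, time = t, distance = d,
                        fitted = fitted, residual = resid,
                        stringsAsFactors = FALSE)
  )), class = "rtt_fit")
}

# Centered single-pass-style accumulation: means first, then centered second
# moments. Avoids the catastrophic cancellation of the naive sum(x^2) form.
.ols_centered <- function(t, d) {
  n <- length(t)
  tbar <- mean(t); dbar <- mean(d)
  ct <- t - tbar; cd <- d - dbar
  stt <- sum(ct * ct)
  sdd <- sum(cd * cd)
  std <- sum(ct * cd)
  slope <- std / stt
  intercept <- dbar - slope * tbar
  rss <- max(0, sdd - std * std / stt)
  r <- if (sdd == 0) 0 else std / sqrt(stt * sdd)
  x_intercept <- if (slope == 0) NaN else -intercept / slope
  list(slope = slope, intercept = intercept, x_intercept = x_intercept,
       r = r, r_squared = r * r, rss = rss)
}

#' @export
print.rtt_fit <- function(x, ...) {
  cat("Root-to-tip regression (", x$n, " tips)\n", sep = "")
  cat(sprintf("  rate (slope)      : %.6g subs/site/year\n", x$slope))
  cat(sprintf("  x-intercept (root): %s\n",
              if (is.nan(x$x_intercept)) "undefined (zero slope)"
              else sprintf("%.6g", x$x_intercept)))
  cat(sprintf("  r = %.4g, r^2 = %.4g  (informal dispersion measure)\n",
              x$r, x$r_squared))
  cat(sprintf("  residual sum of squares: %.6g\n", x$rss))
  if (x$slope < 0)
    cat("  WARNING: negative rate - little or no temporal signal\n")
  invisible(x)
}

#' Summarize a root-to-tip regression
#'
#' Structured summary of a fit: rate, root-time estimate, correlation,
#' dispersion, residual moments. Deliberately excludes p-values and
#' confidence intervals: the points share phylogenetic ancestry and are not
#' independent, so those quantities would not be valid.
#'
#' @param fit An \code{rtt_fit} from \code{\link{fit_root_to_tip}}.
#' @return A list of class \code{"rtt_report"} with fields \code{slope},
#'   \code{intercept}, \code{x_intercept} (the string \code{"undefined"}
#'   when the slope is 0), \code{r}, \code{r_squared}, \code{rss},
#'   \code{residual_mean}, \code{residual_sd}, \code{n}.
#' @export
regression_report <- function(fit) {
  stopifnot(inherits(fit, "rtt_fit"))
  res <- fit$points$residual
  structure(list(
    slope = fit$slope,
    intercept = fit$intercept,
    x_intercept = if (is.nan(fit$x_intercept)) "undefined" else fit$x_intercept,
    r = fit$r,
    r_squared = fit$r_squared,
    rss = fit$rss,
    residual_mean = mean(res),
    residual_sd = stats::sd(res),
    n = fit$n,
    negative_rate_warning = fit$slope < 0
  ), class = "rtt_report")
}

#' @export
print.rtt_report <- function(x, ...) {
  cat("Root-to-tip regression report\n")
  cat(sprintf("  n                 : %d\n", x$n))
  cat(sprintf("  rate (slope)      : %.6g subs/site/year\n", x$slope))
  cat(sprintf("  intercept         : %.6g subs/site\n", x$intercept))
  cat(sprintf("  root time (x-int) : %s\n",
              if (identical(x$x_intercept, "undefined")) "undefined"
              else sprintf("%.6g", x$x_intercept)))
  cat(sprintf("  r / r^2           : %.4g / %.4g (informal dispersion measure)\n",
              x$r, x$r_squared))
  cat(sprintf("  RSS               : %.6g\n", x$rss))
  cat(sprintf("  residuals         : mean %.3g, sd %.3g\n",
              x$residual_mean, x$residual_sd))
  if (isTRUE(x$negative_rate_warning))
    cat("  WARNING: negative rate - little or no temporal signal\n")
  invisible(x)
}
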