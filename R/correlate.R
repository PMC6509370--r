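#' Annual posterior series
#'
#' A fitted model's posterior for an annual quantity (mass at 30 days in
#' grams, lawn proportion, behavior proportion): one column of draws per
#' year. Built by [mass_at_30_series()], [lawn_extent_series()] and
#' [behavior_proportion_series()].
#'
#' @param label Variable label.
#' @param years Integer vector of years.
#' @param draws Numeric matrix, draws x years.
#' @return An object of class `annual_series`.
#' @export
annual_series <- function(label, years, draws) {
  draws <- as.matrix(draws)
  years <- as.integer(years)
  stopifnot(length(years) == ncol(draws), nrow(draws) >= 1,
            !anyDuplicated(years))
  colnames(draws) <- as.character(years)
  structure(list(label = label, years = years, draws = draws),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat("Annual posterior series '", x$label, "': ", length(x$years),
      " years (", min(x$years), "-", max(x$years), "), ",
      nrow(x$draws), " draws/year\n", sep = "")
  invisible(x)
}

#' Years present in both series
#'
#' @param x,y `annual_series` objects.
#' @return Sorted integer vector (possibly empty) of shared years.
#' @export
shared_years <- function(x, y) {
  stopifnot(inherits(x, "annual_series"), inherits(y, "annual_series"))
  sort(intersect(x$years, y$years))
}

#' Posterior-resampling correlation between two annual series
#'
#' Estimates the association between two fitted models' annual estimates
#' while carrying their posterior uncertainty: for each of `n_samples`
#' replicates, one posterior value per shared year is drawn independently
#' for each variable and an ordinary least-squares line of `y` on `x` is
#' fitted; the replicate slopes form the reported distribution. The
#' result is summarized as the mean slope, its f statistic, and the
#' proportion of positive replicate slopes. Slopes are on the variables'
#' natural scales (e.g. grams of mass-at-30 per unit lawn proportion).
#'
#' @param x,y [annual_series] objects (>= 3 shared years required).
#' @param n_samples Number of resampling replicates (default 300).
#' @param seed RNG seed.
#' @return A `posterior_correlation` object: list with `slopes`,
#'   `mean_slope`, `f`, `prop_positive`, `years`, `n_samples`, labels,
#'   and `summary` (quantile summary of the slope draws).
#' @export
correlate_posteriors <- function(x, y, n_samples = 300L, seed = 1L) {
  stopifnot(inherits(x, "annual_series"), inherits(y, "annual_series"),
            n_samples >= 1)
  yrs <- shared_years(x, y)
  if (length(yrs) < 3)
    stop("insufficient data: ", length(yrs),
         " shared year(s); at least 3 required")
  xs <- x$draws[, as.character(yrs), drop = FALSE]
  ys <- y$draws[, as.character(yrs), drop = FALSE]
  if (max(apply(xs, 2, stats::var)) == 0 &&
      stats::var(colMeans(xs)) == 0)
    stop("degenerate regression: x draws have zero variance")
  set.seed(seed)
  ny <- length(yrs)
  cols <- seq_len(ny)
  slopes <- vapply(seq_len(n_samples), function(r) {
    xv <- xs[cbind(sample.int(nrow(xs), ny, replace = TRUE), cols)]
    yv <- ys[cbind(sample.int(nrow(ys), ny, replace = TRUE), cols)]
    vx <- sum((xv - mean(xv))^2)
    if (vx == 0) return(NA_real_)
    sum((xv - mean(xv)) * (yv - mean(yv))) / vx
  }, numeric(1))
  if (anyNA(slopes)) {
    if (all(is.na(slopes)))
      stop("degenerate regression: x draws have zero variance")
    slopes <- slopes[!is.na(slopes)]
  }
  structure(
    list(slopes = slopes,
         mean_slope = mean(slopes),
         f = if (mean(slopes) == 0) 0.5 else f_statistic(slopes),
         prop_positive = mean(slopes > 0),
         years = yrs, n_samples = n_samples,
         x_label = x$label, y_label = y$label,
         summary = posterior_summary(slopes)),
    class = "posterior_correlation")
}

#' @export
print.posterior_correlation <- function(x, ...) {
  cat("Posterior-resampling regression: ", x$y_label, " ~ ", x$x_label,
      "\n", sep = "")
  cat("  shared years: ", length(x$years), " (", min(x$years), "-",
      max(x$years), "), replicates: ", length(x$slopes), "\n", sep = "")
  cat(sprintf("  slope mean %.4g  (2.5%% %.4g, 97.5%% %.4g)\n",
              x$mean_slope, x$summary$`cri_2.5`, x$summary$`cri_97.5`))
  cat(sprintf("  f = %.3f, proportion of positive slopes = %.3f\n",
              x$f, x$prop_positive))
  invisible(x)
}
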