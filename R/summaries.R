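#' The f statistic (posterior probability of direction)
#'
#' The portion of a parameter's posterior draws lying on the same side of
#' zero as the posterior mean. Draws exactly at zero count toward neither
#' side (they stay in the denominator); a posterior mean of exactly zero
#' returns 0.5 by convention, with a warning.
#'
#' f is invariant to positive rescaling of the draws and to flipping the
#' sign of every draw.
#'
#' @param draws Numeric vector of posterior draws (>= 1 draw).
#' @return A proportion in \[0, 1\] (0.5-1 for unimodal posteriors).
#' @export
f_statistic <- function(draws) {
  stopifnot(is.numeric(draws), length(draws) >= 1, all(is.finite(draws)))
  m <- mean(draws)
  if (m == 0) {
    warning("posterior mean is exactly zero; returning f = 0.5")
    return(0.5)
  }
  sum(sign(draws) == sign(m)) / length(draws)
}

#' Posterior summary of a scalar parameter
#'
#' Mean, sd, empirical 2.5% and 97.5% credible bounds (the default
#' `quantile()` type-7 rule, linear interpolation of order statistics) and
#' the [f_statistic()]. This is the row shape of every reported trend
#' table.
#'
#' @param x A numeric vector of draws, or a [posterior_draws] object.
#' @param parameter Parameter name (required when `x` is a
#'   `posterior_draws` object).
#' @return One-row data frame with columns `mean`, `sd`, `cri_2.5`,
#'   `cri_97.5`, `f`.
#' @export
posterior_summary <- function(x, parameter = NULL) {
  if (inherits(x, "posterior_draws")) {
    if (is.null(parameter)) stop("parameter name required")
    x <- draws_of(x, parameter)
  }
  stopifnot(is.numeric(x), length(x) >= 1)
  q <- unname(stats::quantile(x, c(0.025, 0.975)))
  data.frame(mean = mean(x),
             sd = if (length(x) > 1) stats::sd(x) else 0,
             `cri_2.5` = q[1], `cri_97.5` = q[2],
             f = if (mean(x) == 0) 0.5 else f_statistic(x),
             check.names = FALSE)
}

#' Summarize every (or selected) parameter of a draws object
#'
#' @param object A [posterior_draws] object.
#' @param parameters Parameter names; defaults to all.
#' @param label Value for the `label` column of the returned trend table.
#' @param ... Unused.
#' @return Trend-table data frame (`label`, `parameter`, `mean`, `sd`,
#'   `cri_2.5`, `cri_97.5`, `f`), as written by [write_trend_table()].
#' @export
summary.posterior_draws <- function(object, parameters = NULL,
                                    label = object$meta$model %||% "model",
                                    ...) {
  parameters <- parameters %||% parameter_names(object)
  rows <- lapply(parameters, function(nm) {
    s <- posterior_summary(object, nm)
    cbind(data.frame(label = label, parameter = nm), s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
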