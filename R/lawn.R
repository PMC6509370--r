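#' Lawn model specification
#'
#' The hierarchical binomial model of annual *Carex subspathacea* extent:
#' each photo's lawn point count is `Binomial(points_total, P_t)` and the
#' annual extent varies around a linear trend across years. The year
#' effect is placed on the log-odds of `P_t` (a normal year effect on the
#' proportion itself would be unbounded), with a half-normal prior on the
#' logit-scale year sd.
#'
#' @param year_origin Year mapped to covariate 0 (default 1991, the first
#'   survey year).
#' @param prior_scale_sigma Half-normal prior scale for the logit-scale
#'   year-effect sd.
#' @return A `lawn_model_spec` list.
#' @export
lawn_model_spec <- function(year_origin = 1991L, prior_scale_sigma = 5) {
  structure(list(year_origin = as.integer(year_origin),
                 prior_scale_sigma = prior_scale_sigma),
            class = "lawn_model_spec")
}

#' Fit the grazing-lawn extent model
#'
#' Photos within a year are conditionally independent binomials given the
#' year's extent, so the fit depends on the data only through per-year
#' point totals (splitting or merging photos of a year leaves the
#' posterior unchanged). Years without photos are simply absent from the
#' model.
#'
#' @param photos Data frame of photo samples (`year`, `points_total`,
#'   `points_lawn`), e.g. from [read_photo_samples()] or
#'   [simulate_lawn_photos()].
#' @param spec A [lawn_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @return A [posterior_draws] object (subclass `lawn_fit`) with
#'   parameters `alpha_extent`, `beta_extent`, `sigma_extent` and one
#'   logit-scale `eta_t[year]` per surveyed year.
#' @export
fit_lawn_model <- function(photos, spec = lawn_model_spec(),
                           mcmc = mcmc_settings()) {
  stopifnot(all(c("year", "points_total", "points_lawn") %in% names(photos)))
  fit <- fit_binomial_trend(photos$year, photos$points_lawn,
                            photos$points_total, spec$year_origin,
                            name = "lawn",
                            mcmc = mcmc,
                            prior_scale_sigma = spec$prior_scale_sigma)
  names(fit$parameters)[match(c("alpha", "beta", "sigma"),
                              names(fit$parameters))] <-
    c("alpha_extent", "beta_extent", "sigma_extent")
  fit$meta$model <- "lawn"
  attr(fit, "spec") <- spec
  class(fit) <- c("lawn_fit", class(fit))
  fit
}

#' Per-year posterior summaries of lawn extent (proportion scale)
#'
#' Applies the inverse-logit transform to each year's draws and
#' summarizes.
#'
#' @param fit A `lawn_fit` from [fit_lawn_model()].
#' @return Data frame with one row per surveyed year: `year`, `mean`,
#'   `sd`, `cri_2.5`, `cri_97.5`, `f`.
#' @export
lawn_extent_by_year <- function(fit) {
  stopifnot(inherits(fit, "lawn_fit"))
  years <- attr(fit, "years")
  rows <- lapply(years, function(y) {
    p <- stats::plogis(draws_of(fit, sprintf("eta_t[%d]", y)))
    cbind(data.frame(year = y), posterior_summary(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annual posterior series of lawn extent
#'
#' @param fit A `lawn_fit`.
#' @return An [annual_series] of lawn proportions over the surveyed years.
#' @export
lawn_extent_series <- function(fit) {
  stopifnot(inherits(fit, "lawn_fit"))
  years <- attr(fit, "years")
  nd <- length(draws_of(fit, "beta_extent"))
  draws <- vapply(years, function(y)
    stats::plogis(draws_of(fit, sprintf("eta_t[%d]", y))), numeric(nd))
  annual_series("lawn_extent", years, draws)
}
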