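#' Growth model specification
#'
#' The hierarchical gosling growth model: individual mass is
#' `Normal(hatch_mass + beta_t * age, sigma_mass^2)` with the intercept
#' fixed at the mean hatch mass (43.6 g); year-specific daily growth rates
#' follow `beta_t ~ Normal(alpha_growth + beta_growth * (year - origin),
#' sigma_growth^2)`. Growth is treated as linear over the 22-45 day
#' capture window only.
#'
#' Priors: Normal(0, 100^2) on `alpha_growth` and `beta_growth`;
#' half-Normal on the standard deviations (scale
#' `prior_scale_sigma_mass` for the gram-scale residual sd,
#' `prior_scale_sigma_growth` for the year-slope sd). Either sd can be
#' fixed to a known value instead of estimated, which is used by the
#' closed-form validation checks.
#'
#' @param hatch_mass Fixed intercept, grams (default 43.6).
#' @param year_origin Year mapped to covariate 0 (default 1987).
#' @param prior_sd_coef SD of the normal priors on the hyper-intercept and
#'   hyper-slope.
#' @param prior_scale_sigma_mass,prior_scale_sigma_growth Half-normal
#'   prior scales for the two sds.
#' @param sigma_mass,sigma_growth `NULL` to estimate (default) or a fixed
#'   positive value.
#' @return A `growth_model_spec` list.
#' @export
growth_model_spec <- function(hatch_mass = 43.6, year_origin = 1987L,
                              prior_sd_coef = 100,
                              prior_scale_sigma_mass = 100,
                              prior_scale_sigma_growth = 10,
                              sigma_mass = NULL, sigma_growth = NULL) {
  stopifnot(hatch_mass > 0, prior_sd_coef > 0,
            is.null(sigma_mass) || sigma_mass > 0,
            is.null(sigma_growth) || sigma_growth > 0)
  structure(list(hatch_mass = hatch_mass,
                 year_origin = as.integer(year_origin),
                 prior_sd_coef = prior_sd_coef,
                 prior_scale_sigma_mass = prior_scale_sigma_mass,
                 prior_scale_sigma_growth = prior_scale_sigma_growth,
                 sigma_mass = sigma_mass, sigma_growth = sigma_growth),
            class = "growth_model_spec")
}

#' Fit the hierarchical gosling growth model
#'
#' Gibbs sampling: the year slopes and the hyper-coefficients have
#' conjugate normal full conditionals (the per-year likelihood enters only
#' through the sufficient statistics `sum(age^2)`, `sum(age * (mass -
#' hatch_mass))` and `sum((mass - hatch_mass)^2)`); the two standard
#' deviations are updated by slice sampling on the log scale.
#'
#' @param records Data frame of capture records (`year`, `age_days`,
#'   `mass_g`), e.g. from [read_gosling_records()] or
#'   [simulate_growth_data()].
#' @param spec A [growth_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @return A [posterior_draws] object (subclass `growth_fit`) with
#'   parameters `alpha_growth`, `beta_growth`, `sigma_mass`,
#'   `sigma_growth` and one `beta_t[year]` per modeled year.
#' @export
fit_growth_model <- function(records, spec = growth_model_spec(),
                             mcmc = mcmc_settings()) {
  stopifnot(all(c("year", "age_days", "mass_g") %in% names(records)))
  years <- sort(unique(records$year))
  if (length(years) < 2)
    stop("hyper-trend unidentifiable: at least 2 distinct years required")
  yr_idx <- match(records$year, years)
  h <- spec$hatch_mass
  saa <- tapply(records$age_days^2, yr_idx, sum)
  sam <- tapply(records$age_days * (records$mass_g - h), yr_idx, sum)
  smm <- tapply((records$mass_g - h)^2, yr_idx, sum)
  n_t <- tabulate(yr_idx, nbins = length(years))
  one_age <- tapply(records$age_days, yr_idx,
                    function(a) length(unique(a)) == 1) & n_t > 1
  if (any(one_age))
    warning("all ages equal within year(s) ",
            paste(years[one_age], collapse = ", "),
            "; year slope only weakly identified")
  x <- years - spec$year_origin
  model <- growth_sampler(saa = as.numeric(saa), sam = as.numeric(sam),
                          smm = as.numeric(smm), n_t = n_t, x = x,
                          years = years, spec = spec)
  fit <- sample_posterior(model, mcmc)
  fit$meta$model <- "growth"
  attr(fit, "years") <- years
  attr(fit, "spec") <- spec
  class(fit) <- c("growth_fit", class(fit))
  fit
}

growth_sampler <- function(saa, sam, smm, n_t, x, years, spec) {
  tt <- length(x)
  n_total <- sum(n_t)
  prior_prec <- 1 / spec$prior_sd_coef^2
  ls_slopes <- sam / saa
  est_sm <- is.null(spec$sigma_mass)
  est_sg <- is.null(spec$sigma_growth)
  rss <- function(beta) sum(smm - 2 * beta * sam + beta^2 * saa)

  list(
    name = "growth",
    init = function(chain) {
      beta <- ls_slopes + stats::rnorm(tt, 0, 0.2)
      co <- stats::coef(stats::lm.fit(cbind(1, x), beta))
      sm0 <- if (est_sm) {
        max(sqrt(max(rss(ls_slopes), 1e-6) / max(n_total - tt, 1)), 0.5) *
          exp(stats::rnorm(1, 0, 0.2))
      } else spec$sigma_mass
      sg0 <- if (est_sg) {
        max(stats::sd(ls_slopes), 0.05) * exp(stats::rnorm(1, 0, 0.2))
      } else spec$sigma_growth
      list(beta = beta,
           alpha = co[1] + stats::rnorm(1, 0, 0.5),
           beta_g = co[2] + stats::rnorm(1, 0, 0.05),
           sm = sm0, sg = sg0)
    },
    step = function(state, adapt) {
      mu_t <- state$alpha + state$beta_g * x
      # year slopes: conjugate normal
      prec <- saa / state$sm^2 + 1 / state$sg^2
      mean_t <- (sam / state$sm^2 + mu_t / state$sg^2) / prec
      state$beta <- stats::rnorm(tt, mean_t, 1 / sqrt(prec))
      # hyper-coefficients: bivariate normal
      xtx <- matrix(c(tt, sum(x), sum(x), sum(x^2)), 2, 2) / state$sg^2
      a_mat <- xtx + diag(prior_prec, 2)
      b_vec <- c(sum(state$beta), sum(x * state$beta)) / state$sg^2
      ch <- chol(a_mat)
      mean_ab <- backsolve(ch, forwardsolve(t(ch), b_vec))
      draw <- mean_ab + backsolve(ch, stats::rnorm(2))
      state$alpha <- draw[1]
      state$beta_g <- draw[2]
      # residual mass sd
      if (est_sm) {
        r <- rss(state$beta)
        sc <- spec$prior_scale_sigma_mass
        state$sm <- exp(slice_sample1(log(state$sm), function(ls) {
          s <- exp(ls)
          -n_total * ls - r / (2 * s^2) - s^2 / (2 * sc^2) + ls
        }, w = 0.5))
      }
      # year-slope sd
      if (est_sg) {
        dev <- sum((state$beta - (state$alpha + state$beta_g * x))^2)
        sc <- spec$prior_scale_sigma_growth
        state$sg <- exp(slice_sample1(log(state$sg), function(ls) {
          s <- exp(ls)
          -tt * ls - dev / (2 * s^2) - s^2 / (2 * sc^2) + ls
        }, w = 0.5))
      }
      state
    },
    monitor = function(state) {
      c(alpha_growth = unname(state$alpha),
        beta_growth = unname(state$beta_g),
        sigma_mass = unname(state$sm),
        sigma_growth = unname(state$sg),
        stats::setNames(state$beta, sprintf("beta_t[%d]", years)))
    })
}

#' Posterior of model-predicted mass at 30 days for one year
#'
#' The per-draw transform `hatch_mass + 30 * beta_t`.
#'
#' @param fit A `growth_fit` from [fit_growth_model()].
#' @param year A modeled calendar year.
#' @return List with `draws` (numeric vector, grams) and `summary` (a
#'   [posterior_summary()] row).
#' @export
mass_at_30 <- function(fit, year) {
  stopifnot(inherits(fit, "growth_fit"))
  years <- attr(fit, "years")
  if (!year %in% years)
    stop("year ", year, " was not modeled; modeled years: ",
         paste(range(years), collapse = "-"))
  h <- attr(fit, "spec")$hatch_mass
  d <- h + 30 * draws_of(fit, sprintf("beta_t[%d]", year))
  list(draws = d, summary = posterior_summary(d))
}

#' Annual posterior series of mass at 30 days
#'
#' @param fit A `growth_fit`.
#' @return An [annual_series] (grams) over all modeled years, for use with
#'   [correlate_posteriors()].
#' @export
mass_at_30_series <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  years <- attr(fit, "years")
  h <- attr(fit, "spec")$hatch_mass
  draws <- vapply(years,
                  function(y) h + 30 * draws_of(fit, sprintf("beta_t[%d]", y)),
                  numeric(length(draws_of(fit, "beta_growth"))))
  annual_series("mass_at_30", years, draws)
}
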