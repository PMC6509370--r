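#' Parameters for the gosling growth simulator
#'
#' Defaults emulate the study conditions of the long-term Tutakoke River
#' data: growth-rate intercept 21.422 g/day at the 1987 origin, hyper-trend
#' -0.100 g/day per year, hatch mass 43.6 g, capture ages 22-45 days,
#' years 1987-2014 with 2001 missing. Year-level slope variation
#' (`sigma_growth`) and residual mass noise (`sigma_mass`) are set to
#' realistic scales for ~600-900 g goslings.
#'
#' @param alpha_growth Growth rate (g/day) at `year_origin`.
#' @param beta_growth Trend in growth rate, g/day per year.
#' @param sigma_growth SD of year random slopes (g/day).
#' @param sigma_mass Residual mass SD (g).
#' @param hatch_mass Mean hatch mass (g), the fixed model intercept.
#' @param years Integer vector of years with data (gaps allowed).
#' @param n_per_year Goslings captured per year.
#' @param age_low,age_high Inclusive capture-age window (days).
#' @param year_origin Year mapped to covariate 0; defaults to `min(years)`.
#' @param seed RNG seed; generators are pure functions of (params, seed).
#' @return A `growth_sim_params` list.
#' @export
growth_sim_params <- function(alpha_growth = 21.422, beta_growth = -0.100,
                              sigma_growth = 0.5, sigma_mass = 60,
                              hatch_mass = 43.6,
                              years = setdiff(1987:2014, 2001L),
                              n_per_year = 100L,
                              age_low = 22L, age_high = 45L,
                              year_origin = NULL, seed = 1L) {
  if (length(years) == 0) stop("years must be non-empty")
  stopifnot(sigma_growth >= 0, sigma_mass >= 0, hatch_mass > 0,
            n_per_year >= 1, age_low <= age_high)
  if (is.null(year_origin)) year_origin <- min(years)
  structure(list(alpha_growth = alpha_growth, beta_growth = beta_growth,
                 sigma_growth = sigma_growth, sigma_mass = sigma_mass,
                 hatch_mass = hatch_mass, years = as.integer(sort(years)),
                 n_per_year = as.integer(n_per_year),
                 age_low = as.integer(age_low),
                 age_high = as.integer(age_high),
                 year_origin = as.integer(year_origin),
                 seed = as.integer(seed)),
            class = "growth_sim_params")
}

#' Parameters for the grazing-lawn photo simulator
#'
#' Defaults emulate the aerial survey: logit-scale extent intercept -3.126
#' (about 4% cover) at the 1991 origin, logit trend -0.191 per year,
#' ~250 photos per surveyed year, and the survey gap years
#' (1992, 1996, 2000, 2002, 2003, 2005, 2006) absent.
#'
#' @param alpha_extent Logit of lawn proportion at `year_origin`.
#' @param beta_extent Trend, logit units per year.
#' @param sigma_extent SD of logit-scale year effects.
#' @param photos_per_year Photos sampled per surveyed year.
#' @param points_per_photo Grid points classified per photo.
#' @param years Integer vector of surveyed years.
#' @param year_origin Year mapped to covariate 0; defaults to `min(years)`.
#' @param seed RNG seed.
#' @return A `lawn_sim_params` list.
#' @export
lawn_sim_params <- function(alpha_extent = -3.126, beta_extent = -0.191,
                            sigma_extent = 0.5,
                            photos_per_year = 250L, points_per_photo = 150L,
                            years = setdiff(1991:2016,
                                            c(1992L, 1996L, 2000L, 2002L,
                                              2003L, 2005L, 2006L)),
                            year_origin = NULL, seed = 1L) {
  if (length(years) == 0) stop("years must be non-empty")
  stopifnot(sigma_extent >= 0, photos_per_year >= 1, points_per_photo >= 1)
  if (is.null(year_origin)) year_origin <- min(years)
  structure(list(alpha_extent = alpha_extent, beta_extent = beta_extent,
                 sigma_extent = sigma_extent,
                 photos_per_year = as.integer(photos_per_year),
                 points_per_photo = as.integer(points_per_photo),
                 years = as.integer(sort(years)),
                 year_origin = as.integer(year_origin),
                 seed = as.integer(seed)),
            class = "lawn_sim_params")
}

#' Default behavior trend table for the simulator
#'
#' One row per (group, behavior): the study-mean time-budget proportion
#' `mu`, the logit trend `beta` per year, and the logit-scale year-effect
#' SD `sigma`. The logit intercept `alpha` at the year origin is derived so
#' that the mid-study proportion equals `mu`.
#'
#' @return Data frame with columns `group`, `behavior`, `mu`, `beta`,
#'   `sigma`.
#' @export
default_behavior_trends <- function() {
  rows <- rbind(
    data.frame(group = "gosling",
               behavior = c("foraging", "walking", "resting", "aggression",
                            "alert"),
               mu = c(0.705, 0.109, 0.135, 0.0005, 0.006),
               beta = c(-0.005, 0.050, -0.024, 0, 0)),
    data.frame(group = "female",
               behavior = c("foraging", "walking", "resting", "aggression",
                            "alert"),
               mu = c(0.501, 0.111, 0.118, 0.010, 0.191),
               beta = c(-0.005, 0.046, -0.016, -0.034, -0.005)),
    data.frame(group = "male",
               behavior = c("foraging", "walking", "resting", "aggression",
                            "alert"),
               mu = c(0.372, 0.062, 0.114, 0.021, 0.368),
               beta = c(0.000, 0.045, -0.018, -0.018, -0.008)))
  rows$sigma <- 0.3
  rows
}

#' Parameters for the behavior-bout simulator
#'
#' @param trends Data frame with columns `group`, `behavior`, `beta`,
#'   `sigma` and either `alpha` (logit intercept at the year origin) or
#'   `mu` (study-mean proportion, from which `alpha` is derived as
#'   `qlogis(mu) - beta * mean(year covariate)`).
#' @param years Integer vector of observed years; defaults to 1987-2015
#'   with the 1989, 2006 and 2012 gaps.
#' @param bouts_per_year Observation bouts per (year, group).
#' @param scans_per_bout Scans per bout; must lie in 31-60 so simulated
#'   bouts pass the 30-minute filter.
#' @param year_origin Year mapped to covariate 0; defaults to `min(years)`.
#' @param seed RNG seed.
#' @return A `behavior_sim_params` list.
#' @export
behavior_sim_params <- function(trends = default_behavior_trends(),
                                years = setdiff(1987:2015,
                                                c(1989L, 2006L, 2012L)),
                                bouts_per_year = 30L, scans_per_bout = 60L,
                                year_origin = NULL, seed = 1L) {
  if (length(years) == 0) stop("years must be non-empty")
  stopifnot(bouts_per_year >= 1,
            scans_per_bout >= 31, scans_per_bout <= 60)
  need <- c("group", "behavior", "beta", "sigma")
  if (!all(need %in% names(trends)))
    stop("trends needs columns: ", paste(need, collapse = ", "))
  if (is.null(year_origin)) year_origin <- min(years)
  if (is.null(trends$alpha)) {
    if (is.null(trends$mu)) stop("trends needs either alpha or mu")
    xbar <- mean(as.integer(years) - as.integer(year_origin))
    trends$alpha <- stats::qlogis(trends$mu) - trends$beta * xbar
  }
  structure(list(trends = trends, years = as.integer(sort(years)),
                 bouts_per_year = as.integer(bouts_per_year),
                 scans_per_bout = as.integer(scans_per_bout),
                 year_origin = as.integer(year_origin),
                 seed = as.integer(seed)),
            class = "behavior_sim_params")
}

#' Simulate gosling capture records
#'
#' For each year `t` a daily growth rate is drawn as
#' `beta_t ~ Normal(alpha_growth + beta_growth * (t - origin),
#' sigma_growth^2)`; each gosling gets an age uniform on the capture window
#' and `mass ~ Normal(hatch_mass + beta_t * age, sigma_mass^2)`.
#'
#' @param p A [growth_sim_params()] object.
#' @return Data frame of capture records (`id`, `year`, `age_days`,
#'   `mass_g`) with the generating year slopes in `attr(, "truth")`.
#' @export
simulate_growth_data <- function(p) {
  stopifnot(inherits(p, "growth_sim_params"))
  set.seed(p$seed)
  x <- p$years - p$year_origin
  beta_t <- stats::rnorm(length(p$years),
                         p$alpha_growth + p$beta_growth * x, p$sigma_growth)
  out <- growth_records_from_slopes(beta_t, p)
  attr(out, "truth") <- list(beta_t = stats::setNames(beta_t,
                                                      as.character(p$years)),
                             params = p)
  out
}

# draw ages and masses given fixed year slopes (RNG state is the caller's)
growth_records_from_slopes <- function(beta_t, p) {
  recs <- vector("list", length(p$years))
  ages <- seq.int(p$age_low, p$age_high)
  for (j in seq_along(p$years)) {
    age <- ages[sample.int(length(ages), p$n_per_year, replace = TRUE)]
    mass <- stats::rnorm(p$n_per_year, p$hatch_mass + beta_t[j] * age,
                         p$sigma_mass)
    recs[[j]] <- data.frame(
      id = sprintf("G%d-%04d", p$years[j], seq_len(p$n_per_year)),
      year = p$years[j], age_days = age, mass_g = mass)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate aerial grazing-lawn photo samples
#'
#' Per year the logit of the lawn proportion is drawn around its linear
#' trend; each photo's lawn point count is `Binomial(points_per_photo,
#' P_t)`.
#'
#' @param p A [lawn_sim_params()] object.
#' @return Data frame of photo samples (`year`, `points_total`,
#'   `points_lawn`) with the generating proportions in `attr(, "truth")`.
#' @export
simulate_lawn_photos <- function(p) {
  stopifnot(inherits(p, "lawn_sim_params"))
  set.seed(p$seed)
  simulate_lawn_photos_impl(p)
}

simulate_lawn_photos_impl <- function(p) {
  x <- p$years - p$year_origin
  eta <- stats::rnorm(length(p$years),
                      p$alpha_extent + p$beta_extent * x, p$sigma_extent)
  prob <- stats::plogis(eta)
  out <- do.call(rbind, lapply(seq_along(p$years), function(j) {
    data.frame(year = p$years[j], points_total = p$points_per_photo,
               points_lawn = stats::rbinom(p$photos_per_year,
                                           p$points_per_photo, prob[j]))
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- list(p = stats::setNames(prob, as.character(p$years)),
                             eta = stats::setNames(eta, as.character(p$years)),
                             params = p)
  out
}

#' Simulate behavior observation bouts
#'
#' Per (year, group) the logit of each behavior's probability is drawn
#' around its own linear trend. Within a bout, scan counts for the
#' simulated categories (plus an unclassified remainder) are drawn from a
#' multinomial whose cell probabilities are the marginal behavior
#' probabilities, rescaled only if they exceed 1. Each simulated behavior's
#' count is therefore marginally `Binomial(scans_per_bout, theta)`, the
#' structure assumed by the per-behavior fits, while counts within a bout
#' never exceed the scan total.
#'
#' @param p A [behavior_sim_params()] object.
#' @return Wide data frame of bouts (`year`, `group`, `duration_min`,
#'   `total_scans`, one column per simulated behavior) with the generating
#'   probabilities in `attr(, "truth")`.
#' @export
simulate_behavior_bouts <- function(p) {
  stopifnot(inherits(p, "behavior_sim_params"))
  set.seed(p$seed)
  x <- p$years - p$year_origin
  groups <- unique(p$trends$group)
  theta_truth <- list()
  rows <- list()
  for (g in groups) {
    tg <- p$trends[p$trends$group == g, , drop = FALSE]
    nb <- nrow(tg)
    for (j in seq_along(p$years)) {
      eta <- stats::rnorm(nb, tg$alpha + tg$beta * x[j], tg$sigma)
      theta <- stats::plogis(eta)
      theta_truth[[paste(g, p$years[j])]] <-
        stats::setNames(theta, tg$behavior)
      q <- theta / max(1, sum(theta))
      cell <- c(q, max(0, 1 - sum(q)))
      counts <- t(stats::rmultinom(p$bouts_per_year, p$scans_per_bout, cell))
      block <- data.frame(year = rep(p$years[j], p$bouts_per_year),
                          group = g,
                          duration_min = p$scans_per_bout,
                          total_scans = p$scans_per_bout)
      for (b in seq_len(nb)) block[[tg$behavior[b]]] <- counts[, b]
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(theta = theta_truth, params = p)
  out
}

#' Simulate a coupled growth + lawn + behavior scenario
#'
#' Generates the three data streams over one shared set of years with a
#' known linear coupling between lawn extent and gosling size: lawn
#' proportions `P_t` are simulated first, then year growth slopes are set
#' so that expected mass at 30 days equals a flat baseline
#' (`hatch_mass + 30 * alpha_growth`) plus `coupling * (P_t - mean(P_t))`,
#' plus `Normal(0, sigma_growth^2)` year noise. The growth params'
#' `beta_growth` is deliberately ignored here: in the coupled scenario any
#' year trend in gosling size arises through the trending lawn extent,
#' which keeps the regression slope of mass-at-30 on lawn proportion equal
#' to `coupling` (an independent baseline year trend would be collinear
#' with the trending lawn and confound the slope). Used to validate the
#' posterior-resampling correlation stage by recovery of `coupling`
#' (grams per unit lawn proportion).
#'
#' @param growth A [growth_sim_params()]; its `years` must equal the lawn
#'   years.
#' @param lawn A [lawn_sim_params()].
#' @param behavior Optional [behavior_sim_params()] (same years).
#' @param coupling Slope of expected mass-at-30 on lawn proportion (g).
#' @param seed RNG seed for the whole scenario.
#' @return List with elements `growth`, `lawn`, `behavior` (or `NULL`) and
#'   `truth` (coupling, lawn proportions, year slopes).
#' @export
simulate_joint_scenario <- function(growth, lawn, behavior = NULL,
                                    coupling = 0, seed = 1L) {
  stopifnot(inherits(growth, "growth_sim_params"),
            inherits(lawn, "lawn_sim_params"))
  if (!identical(growth$years, lawn$years))
    stop("growth and lawn year sets must match")
  if (!is.null(behavior) && !identical(behavior$years, growth$years))
    stop("behavior years must match the shared year set")
  set.seed(seed)
  photos <- simulate_lawn_photos_impl(lawn)
  p_t <- attr(photos, "truth")$p
  beta_t <- growth$alpha_growth +
    coupling * (p_t - mean(p_t)) / 30 +
    stats::rnorm(length(growth$years), 0, growth$sigma_growth)
  records <- growth_records_from_slopes(beta_t, growth)
  bouts <- NULL
  if (!is.null(behavior)) {
    b2 <- behavior
    b2$seed <- seed + 1L
    bouts <- simulate_behavior_bouts(b2)
  }
  list(growth = records, lawn = photos, behavior = bouts,
       truth = list(coupling = coupling,
                    p = p_t,
                    beta_t = stats::setNames(beta_t,
                                             as.character(growth$years))))
}
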