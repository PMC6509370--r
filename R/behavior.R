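#' Behavior model specification
#'
#' The hierarchical binomial time-budget model for one (group, behavior)
#' cell: a bout's scan count for the behavior is
#' `Binomial(total_scans, theta_t)`, with the year log-odds varying around
#' a linear trend. One scalar trend slope per cell; the five behavior
#' categories are fitted marginally and independently (they are not
#' jointly constrained to sum to one).
#'
#' @param group One of `"gosling"`, `"female"`, `"male"`.
#' @param behavior Behavior category label.
#' @param year_origin Year mapped to covariate 0 (default 1987).
#' @param prior_scale_sigma Half-normal prior scale for the logit-scale
#'   year-effect sd.
#' @param categories Valid behavior labels.
#' @return A `behavior_model_spec` list.
#' @export
behavior_model_spec <- function(group, behavior, year_origin = 1987L,
                                prior_scale_sigma = 5,
                                categories = c("foraging", "alert",
                                               "walking", "aggression",
                                               "resting")) {
  group <- match.arg(group, c("gosling", "female", "male"))
  if (!behavior %in% categories)
    stop("unknown behavior: ", behavior, "; valid: ",
         paste(categories, collapse = ", "))
  structure(list(group = group, behavior = behavior,
                 year_origin = as.integer(year_origin),
                 prior_scale_sigma = prior_scale_sigma),
            class = "behavior_model_spec")
}

#' Fit the time-budget trend model for one group and behavior
#'
#' @param bouts Data frame of observation bouts in the wide shape of
#'   [read_behavior_bouts()] / [simulate_behavior_bouts()]; assumed
#'   already filtered to bouts over 30 minutes.
#' @param spec A [behavior_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @return A [posterior_draws] object (subclass `behavior_fit`) with
#'   parameters `alpha`, `beta`, `sigma` and one `eta_t[year]` per
#'   observed year.
#' @export
fit_behavior_model <- function(bouts, spec, mcmc = mcmc_settings()) {
  stopifnot(inherits(spec, "behavior_model_spec"),
            all(c("year", "group", "total_scans") %in% names(bouts)))
  sub <- bouts[bouts$group == spec$group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no bouts for group ", spec$group)
  if (!spec$behavior %in% names(sub))
    stop("no count column for behavior ", spec$behavior)
  if (length(unique(sub$year)) < 2)
    stop("trend unidentifiable: group ", spec$group,
         " observed in fewer than 2 years")
  fit <- fit_binomial_trend(sub$year, sub[[spec$behavior]], sub$total_scans,
                            spec$year_origin,
                            name = paste(spec$group, spec$behavior),
                            mcmc = mcmc,
                            prior_scale_sigma = spec$prior_scale_sigma)
  fit$meta$model <- paste(spec$group, spec$behavior)
  attr(fit, "spec") <- spec
  class(fit) <- c("behavior_fit", class(fit))
  fit
}

#' Annual posterior series of a behavior's time-budget proportion
#'
#' @param fit A `behavior_fit`.
#' @return An [annual_series] of proportions over the observed years.
#' @export
behavior_proportion_series <- function(fit) {
  stopifnot(inherits(fit, "behavior_fit"))
  years <- attr(fit, "years")
  nd <- length(draws_of(fit, "beta"))
  draws <- vapply(years, function(y)
    stats::plogis(draws_of(fit, sprintf("eta_t[%d]", y))), numeric(nd))
  spec <- attr(fit, "spec")
  annual_series(paste(spec$group, spec$behavior, sep = "_"), years, draws)
}

#' Trend table across groups and behaviors
#'
#' Fits [fit_behavior_model()] for every requested (group, behavior) cell
#' and assembles the reported table: the posterior mean time-budget
#' proportion `mu` (the year-averaged inverse-logit year effects), the
#' trend slope summary and its f statistic. Cells whose fit fails are
#' reported with a note rather than aborting the rest; cells with a
#' near-zero overall proportion (< 1% of scans) are flagged
#' low-information, since a logit-scale trend for a behavior that almost
#' never occurs is weakly identified.
#'
#' @param bouts Wide bout data frame.
#' @param groups Character vector of groups to fit.
#' @param behaviors Character vector of behavior categories to fit.
#' @param mcmc An [mcmc_settings()]; the seed is offset per cell so cells
#'   are independent but the whole table is reproducible.
#' @param year_origin Year mapped to covariate 0.
#' @return Data frame with one row per cell: `group`, `behavior`, `mu`,
#'   `beta_mean`, `beta_sd`, `cri_2.5`, `cri_97.5`, `f`, `note`.
#' @export
behavior_trend_table <- function(bouts,
                                 groups = c("gosling", "female", "male"),
                                 behaviors = c("foraging", "walking",
                                               "resting"),
                                 mcmc = mcmc_settings(),
                                 year_origin = 1987L) {
  cells <- expand.grid(group = groups, behavior = behaviors,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$group[i]
    b <- cells$behavior[i]
    cell_mcmc <- mcmc
    cell_mcmc$seed <- mcmc$seed + i
    res <- tryCatch({
      spec <- behavior_model_spec(g, b, year_origin = year_origin)
      fit <- fit_behavior_model(bouts, spec, cell_mcmc)
      ser <- behavior_proportion_series(fit)
      mu <- mean(rowMeans(ser$draws))
      bs <- posterior_summary(fit, "beta")
      note <- if (mu < 0.01) "low-information: near-zero behavior" else ""
      data.frame(group = g, behavior = b, mu = mu,
                 beta_mean = bs$mean, beta_sd = bs$sd,
                 `cri_2.5` = bs$`cri_2.5`, `cri_97.5` = bs$`cri_97.5`,
                 f = bs$f, note = note, check.names = FALSE)
    }, error = function(e) {
      data.frame(group = g, behavior = b, mu = NA_real_,
                 beta_mean = NA_real_, beta_sd = NA_real_,
                 `cri_2.5` = NA_real_, `cri_97.5` = NA_real_, f = NA_real_,
                 note = paste("fit failed:", conditionMessage(e)),
                 check.names = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
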