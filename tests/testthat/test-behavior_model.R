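test_that("behavior model recovers a strong locomotion trend", {
  trends <- data.frame(group = "gosling", behavior = "walking",
                       mu = 0.109, beta = 0.05, sigma = 0.3)
  p <- behavior_sim_params(trends, years = 1987:2013, bouts_per_year = 30,
                           scans_per_bout = 60, seed = 41)
  d <- simulate_behavior_bouts(p)
  fit <- fit_behavior_model(d, behavior_model_spec("gosling", "walking",
                                                   year_origin = 1987),
                            quick_mcmc(seed = 42))
  s <- posterior_summary(fit, "beta")
  expect_lt(s$`cri_2.5`, 0.05)
  expect_gt(s$`cri_97.5`, 0.05)
  expect_gt(s$f, 0.99)
})

test_that("a flat time budget yields no detected trend", {
  fs <- vapply(1:5, function(s) {
    trends <- data.frame(group = "gosling", behavior = "resting",
                         mu = 0.2, beta = 0, sigma = 0.2)
    p <- behavior_sim_params(trends, years = 1990:2009, bouts_per_year = 15,
                             seed = 400 + s)
    d <- simulate_behavior_bouts(p)
    fit <- fit_behavior_model(d, behavior_model_spec("gosling", "resting",
                                                     year_origin = 1990),
                              quick_mcmc(seed = 500 + s, iterations = 500,
                                         burnin = 300))
    posterior_summary(fit, "beta")$f
  }, numeric(1))
  expect_lt(median(fs), 0.95)
  expect_gte(min(fs), 0.5)
})

test_that("a behavior occupying every scan drives theta to the boundary", {
  d <- bout_row(1990:1999, "female", 60, 60, foraging = 60)
  fit <- fit_behavior_model(d, behavior_model_spec("female", "foraging",
                                                   year_origin = 1990),
                            quick_mcmc(seed = 43, iterations = 400,
                                       burnin = 300))
  ser <- behavior_proportion_series(fit)
  expect_true(all(colMeans(ser$draws) > 0.9))
})

test_that("per-behavior fits share no state across fitting order", {
  p <- behavior_sim_params(years = 1990:1999, bouts_per_year = 10, seed = 44)
  d <- simulate_behavior_bouts(p)
  mc <- quick_mcmc(seed = 45, iterations = 300, burnin = 200)
  walk_first <- fit_behavior_model(d, behavior_model_spec("gosling", "walking",
                                                          year_origin = 1990),
                                   mc)
  fit_behavior_model(d, behavior_model_spec("gosling", "foraging",
                                            year_origin = 1990), mc)
  walk_second <- fit_behavior_model(d,
                                    behavior_model_spec("gosling", "walking",
                                                        year_origin = 1990),
                                    mc)
  expect_identical(walk_first$parameters, walk_second$parameters)
})

test_that("posterior-mean time budgets sum to about one across categories", {
  p <- behavior_sim_params(years = 1990:1999, bouts_per_year = 20, seed = 46)
  d <- simulate_behavior_bouts(p)
  tbl <- behavior_trend_table(d, groups = "gosling",
                              behaviors = c("foraging", "alert", "walking",
                                            "aggression", "resting"),
                              mcmc = quick_mcmc(seed = 47, iterations = 400,
                                                burnin = 300),
                              year_origin = 1990)
  total <- sum(tbl$mu)
  expect_gt(total, 0)
  expect_lte(total, 1.1)
})

test_that("the trend table covers all cells, flags rare behaviors, and reruns identically", {
  p <- behavior_sim_params(years = 1990:1997, bouts_per_year = 10, seed = 48)
  d <- simulate_behavior_bouts(p)
  mc <- quick_mcmc(seed = 49, iterations = 300, burnin = 200)
  tbl <- behavior_trend_table(d, groups = c("gosling", "female", "male"),
                              behaviors = c("foraging", "walking", "resting"),
                              mcmc = mc, year_origin = 1990)
  expect_equal(nrow(tbl), 9)
  expect_true(all(tbl$note == ""))
  agg <- behavior_trend_table(d, groups = "gosling",
                              behaviors = "aggression", mcmc = mc,
                              year_origin = 1990)
  expect_lt(agg$mu, 0.01)
  expect_match(agg$note, "low-information")
  expect_identical(tbl, behavior_trend_table(
    d, groups = c("gosling", "female", "male"),
    behaviors = c("foraging", "walking", "resting"),
    mcmc = mc, year_origin = 1990))
})

test_that("behavior fit preconditions are enforced and failures isolated", {
  one_year <- bout_row(1990, "male", 60, 60, foraging = 30)
  expect_error(fit_behavior_model(one_year,
                                  behavior_model_spec("male", "foraging")),
               "fewer than 2 years")
  expect_error(fit_behavior_model(one_year,
                                  behavior_model_spec("female", "foraging")),
               "no bouts")
  expect_error(behavior_model_spec("gosling", "sleeping"), "unknown behavior")
  # a failing cell is reported, the others still fit
  tbl <- behavior_trend_table(one_year, groups = "male",
                              behaviors = c("foraging", "walking"),
                              mcmc = quick_mcmc(iterations = 100,
                                                burnin = 100))
  expect_equal(nrow(tbl), 2)
  expect_true(all(grepl("fit failed", tbl$note)))
})
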