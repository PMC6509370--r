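test_that("growth model recovers generating parameters from synthetic data", {
  p <- growth_sim_params(years = 1987:2015, n_per_year = 100,
                         beta_growth = -0.10, sigma_growth = 0.5,
                         sigma_mass = 60, seed = 21)
  d <- simulate_growth_data(p)
  fit <- fit_growth_model(d, growth_model_spec(year_origin = 1987),
                          quick_mcmc(seed = 22))
  s <- summary(fit, parameters = c("alpha_growth", "beta_growth",
                                   "sigma_mass", "sigma_growth"))
  get <- function(nm) s[s$parameter == nm, ]
  expect_gt(get("beta_growth")$`cri_97.5`, -0.10)
  expect_lt(get("beta_growth")$`cri_2.5`, -0.10)
  expect_gt(get("alpha_growth")$`cri_97.5`, 21.422)
  expect_lt(get("alpha_growth")$`cri_2.5`, 21.422)
  expect_lt(abs(get("sigma_mass")$mean - 60), 3)
  diag <- check_convergence(fit)
  expect_true(all(diag$rhat < 1.05, na.rm = TRUE))
})

test_that("noise-free data pin the year slopes to the exact linear system", {
  p <- growth_sim_params(alpha_growth = 21, beta_growth = -0.1,
                         sigma_growth = 0, sigma_mass = 0,
                         years = 1990:1994, n_per_year = 50, seed = 23)
  d <- simulate_growth_data(p)
  truth <- attr(d, "truth")$beta_t
  spec <- growth_model_spec(year_origin = 1990, sigma_mass = 1,
                            sigma_growth = 0.1)
  fit <- fit_growth_model(d, spec, quick_mcmc(seed = 24))
  for (y in names(truth)) {
    est <- mean(draws_of(fit, sprintf("beta_t[%s]", y)))
    expect_lt(abs(est - truth[[y]]), 1e-3)
  }
})

test_that("large-n single-year slope converges to the fixed-intercept LS estimator", {
  set.seed(25)
  age <- sample(22:45, 4000, replace = TRUE)
  mass <- 43.6 + 21 * age + rnorm(4000, 0, 60)
  d <- data.frame(year = rep(c(2000, 2001), each = 2000),
                  age_days = age, mass_g = mass)
  ls_slope <- function(sub) sum(sub$age_days * (sub$mass_g - 43.6)) /
    sum(sub$age_days^2)
  fit <- fit_growth_model(d, growth_model_spec(year_origin = 2000),
                          quick_mcmc(seed = 26))
  for (y in c(2000, 2001)) {
    est <- mean(draws_of(fit, sprintf("beta_t[%d]", y)))
    expect_lt(abs(est - ls_slope(d[d$year == y, ])), 0.02)
  }
})

test_that("mass at 30 days is the linear transform of the year slope", {
  p <- growth_sim_params(years = 1990:1993, n_per_year = 30, seed = 27)
  d <- simulate_growth_data(p)
  fit <- fit_growth_model(d, growth_model_spec(year_origin = 1990),
                          quick_mcmc(seed = 28, iterations = 400,
                                     burnin = 300))
  m30 <- mass_at_30(fit, 1991)
  b <- draws_of(fit, "beta_t[1991]")
  expect_equal(m30$draws, 43.6 + 30 * b)
  expect_equal(m30$summary$mean, 43.6 + 30 * mean(b))
  expect_error(mass_at_30(fit, 1985), "not modeled")
  ser <- mass_at_30_series(fit)
  expect_equal(ser$years, 1990:1993)
  expect_equal(ser$draws[, 2], m30$draws)
})

test_that("growth fit preconditions are enforced", {
  one_year <- data.frame(year = 2000, age_days = c(25, 30), mass_g = c(500, 600))
  expect_error(fit_growth_model(one_year), "2 distinct years")
  same_age <- data.frame(year = rep(c(2000, 2001), each = 3),
                         age_days = c(30, 30, 30, 25, 30, 35),
                         mass_g = c(600, 610, 590, 500, 620, 700))
  expect_warning(fit_growth_model(same_age,
                                  growth_model_spec(year_origin = 2000,
                                                    sigma_mass = 50,
                                                    sigma_growth = 1),
                                  quick_mcmc(iterations = 100, burnin = 100)),
                 "weakly identified")
})

test_that("the hyper-trend is equivariant to shifting the year origin", {
  p <- growth_sim_params(years = 1990:2009, n_per_year = 60, seed = 29)
  d <- simulate_growth_data(p)
  f0 <- fit_growth_model(d, growth_model_spec(year_origin = 1990),
                         quick_mcmc(seed = 30))
  f5 <- fit_growth_model(d, growth_model_spec(year_origin = 1995),
                         quick_mcmc(seed = 30))
  b0 <- mean(draws_of(f0, "beta_growth"))
  b5 <- mean(draws_of(f5, "beta_growth"))
  a0 <- mean(draws_of(f0, "alpha_growth"))
  a5 <- mean(draws_of(f5, "alpha_growth"))
  expect_lt(abs(b0 - b5), 0.01)
  expect_lt(abs(a5 - (a0 + 5 * b0)), 0.1)
})
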