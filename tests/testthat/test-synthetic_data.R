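test_that("noise-free growth simulation reduces to exact arithmetic", {
  p <- growth_sim_params(alpha_growth = 20, beta_growth = 0,
                         sigma_growth = 0, sigma_mass = 0,
                         years = 2000:2002, n_per_year = 5,
                         age_low = 30, age_high = 30, seed = 7)
  d <- simulate_growth_data(p)
  expect_true(all(d$mass_g == 43.6 + 20 * 30))       # 643.6 g exactly
  p2 <- growth_sim_params(alpha_growth = 20, beta_growth = 0,
                          sigma_growth = 0, sigma_mass = 0,
                          years = 2000:2001, n_per_year = 20, seed = 8)
  d2 <- simulate_growth_data(p2)
  expect_equal(d2$mass_g, 43.6 + 20 * d2$age_days)
})

test_that("growth generator is a pure function of (params, seed)", {
  p <- growth_sim_params(years = 1990:1995, n_per_year = 10, seed = 42)
  expect_identical(simulate_growth_data(p), simulate_growth_data(p))
  p2 <- p; p2$seed <- 43L
  expect_false(identical(simulate_growth_data(p)$mass_g,
                         simulate_growth_data(p2)$mass_g))
})

test_that("empirical residual sd converges to sigma_mass", {
  p <- growth_sim_params(beta_growth = 0, sigma_growth = 0, sigma_mass = 50,
                         years = 2000:2001, n_per_year = 5000, seed = 9)
  d <- simulate_growth_data(p)
  resid <- d$mass_g - (43.6 + 21.422 * d$age_days)
  expect_lt(abs(sd(resid) - 50) / 50, 0.02)
})

test_that("lawn generator matches its binomial moments and boundaries", {
  p <- lawn_sim_params(alpha_extent = 0, beta_extent = 0, sigma_extent = 0,
                       years = 2000:2004, photos_per_year = 400,
                       points_per_photo = 100, seed = 10)
  d <- simulate_lawn_photos(p)
  expect_lt(abs(mean(d$points_lawn / d$points_total) - 0.5), 0.01)
  expect_equal(length(unique(attr(d, "truth")$p)), 1)  # constant model
  # proportion forced to ~0 -> all counts zero
  p0 <- lawn_sim_params(alpha_extent = -50, beta_extent = 0,
                        sigma_extent = 0, years = 2000:2002,
                        photos_per_year = 50, seed = 11)
  expect_true(all(simulate_lawn_photos(p0)$points_lawn == 0))
})

test_that("behavior generator hits its marginal scan-count proportions", {
  trends <- data.frame(group = "gosling", behavior = "foraging",
                       mu = 0.705, beta = 0, sigma = 0)
  p <- behavior_sim_params(trends, years = 2000:2001, bouts_per_year = 2000,
                           scans_per_bout = 60, seed = 12)
  d <- simulate_behavior_bouts(p)
  expect_lt(abs(mean(d$foraging / d$total_scans) - 0.705), 0.01)
  expect_identical(simulate_behavior_bouts(p), simulate_behavior_bouts(p))
  # probability ~0 -> all counts zero
  t0 <- data.frame(group = "gosling", behavior = "alert",
                   alpha = -50, beta = 0, sigma = 0)
  p0 <- behavior_sim_params(t0, years = 2000:2001, bouts_per_year = 20,
                            seed = 13)
  expect_true(all(simulate_behavior_bouts(p0)$alert == 0))
})

test_that("simulated bouts always respect the scan-total invariant", {
  for (s in 1:5) {
    p <- behavior_sim_params(years = 1987:1995, bouts_per_year = 20,
                             scans_per_bout = 45, seed = s)
    d <- simulate_behavior_bouts(p)
    counts <- as.matrix(d[, setdiff(names(d), c("year", "group",
                                                "duration_min",
                                                "total_scans"))])
    expect_true(all(rowSums(counts) <= d$total_scans))
    expect_true(all(d$duration_min > 30))
  }
})

test_that("simulator params enforce their invariants", {
  expect_error(growth_sim_params(years = integer()), "non-empty")
  expect_error(growth_sim_params(sigma_mass = -1))
  expect_error(behavior_sim_params(scans_per_bout = 20))
  expect_error(lawn_sim_params(photos_per_year = 0))
})

test_that("joint scenario requires matching year sets and records truth", {
  g <- growth_sim_params(years = 1991:2000, n_per_year = 10)
  l <- lawn_sim_params(years = 1991:1999)
  expect_error(simulate_joint_scenario(g, l), "must match")
  l2 <- lawn_sim_params(years = 1991:2000, photos_per_year = 20)
  sc <- simulate_joint_scenario(g, l2, coupling = 500, seed = 3)
  expect_equal(sc$truth$coupling, 500)
  expect_equal(names(sc$truth$p), as.character(1991:2000))
  # coupling enters the year slopes linearly in the lawn proportion
  g0 <- growth_sim_params(years = 1991:2000, n_per_year = 10,
                          sigma_growth = 0, sigma_mass = 0)
  sc0 <- simulate_joint_scenario(g0, l2, coupling = 600, seed = 3)
  expected <- g0$alpha_growth + 600 * (sc0$truth$p - mean(sc0$truth$p)) / 30
  expect_equal(unname(sc0$truth$beta_t), unname(expected))
})
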