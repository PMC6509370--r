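# Shared hierarchical binomial trend sampler.
#
# Data enter per year through binomial sufficient statistics (successes
# s_t out of k_t trials; photos/bouts of a year are conditionally
# independent given the year parameter, so only the totals matter). The
# year log-odds eta_t are Normal(alpha + beta * x_t, sigma^2); eta_t are
# updated by vectorized adaptive random-walk Metropolis (scales tuned to
# ~0.44 acceptance during burn-in only), (alpha, beta) by their conjugate
# bivariate-normal conditional, sigma by slice sampling on log(sigma) with
# a half-normal prior.
binomial_trend_sampler <- function(s_t, k_t, x, years, name,
                                   prior_sd_coef = 100,
                                   prior_scale_sigma = 5) {
  tt <- length(x)
  prior_prec <- 1 / prior_sd_coef^2
  eta_hat <- stats::qlogis((s_t + 0.5) / (k_t + 1))
  loglik <- function(eta) s_t * eta - k_t * log1pexp(eta)

  list(
    name = name,
    init = function(chain) {
      eta <- eta_hat + stats::rnorm(tt, 0, 0.3)
      co <- stats::coef(stats::lm.fit(cbind(1, x), eta))
      sig0 <- max(stats::sd(eta_hat - co[1] - co[2] * x), 0.05) *
        exp(stats::rnorm(1, 0, 0.2))
      list(eta = eta,
           alpha = co[1] + stats::rnorm(1, 0, 0.3),
           beta = co[2] + stats::rnorm(1, 0, 0.03),
           sig = sig0,
           step_size = pmax(1 / sqrt(pmax(k_t * 0.1, 1)), 0.05),
           iter = 0L)
    },
    step = function(state, adapt) {
      state$iter <- state$iter + 1L
      mu <- state$alpha + state$beta * x
      # year effects: vectorized random-walk Metropolis
      prop <- state$eta + state$step_size * stats::rnorm(tt)
      lp_cur <- loglik(state$eta) - (state$eta - mu)^2 / (2 * state$sig^2)
      lp_prop <- loglik(prop) - (prop - mu)^2 / (2 * state$sig^2)
      acc <- log(stats::runif(tt)) < lp_prop - lp_cur
      state$eta[acc] <- prop[acc]
      if (adapt) {
        gamma <- min(0.5, 1 / sqrt(state$iter))
        state$step_size <- state$step_size * exp(gamma * (acc - 0.44))
      }
      # hyper-coefficients: conjugate bivariate normal
      xtx <- matrix(c(tt, sum(x), sum(x), sum(x^2)), 2, 2) / state$sig^2
      a_mat <- xtx + diag(prior_prec, 2)
      b_vec <- c(sum(state$eta), sum(x * state$eta)) / state$sig^2
      ch <- chol(a_mat)
      mean_ab <- backsolve(ch, forwardsolve(t(ch), b_vec))
      draw <- mean_ab + backsolve(ch, stats::rnorm(2))
      state$alpha <- draw[1]
      state$beta <- draw[2]
      # year-effect sd
      dev <- sum((state$eta - (state$alpha + state$beta * x))^2)
      state$sig <- exp(slice_sample1(log(state$sig), function(ls) {
        s <- exp(ls)
        -tt * ls - dev / (2 * s^2) - s^2 / (2 * prior_scale_sigma^2) + ls
      }, w = 0.5))
      state
    },
    monitor = function(state) {
      c(alpha = unname(state$alpha),
        beta = unname(state$beta),
        sigma = unname(state$sig),
        stats::setNames(state$eta, sprintf("eta_t[%d]", years)))
    })
}

# aggregate (successes, trials) per year and fit the trend sampler
fit_binomial_trend <- function(year, successes, trials, year_origin, name,
                               mcmc, prior_scale_sigma = 5) {
  years <- sort(unique(year))
  if (length(years) < 2)
    stop("trend unidentifiable: at least 2 distinct years required")
  idx <- match(year, years)
  s_t <- as.numeric(tapply(successes, idx, sum))
  k_t <- as.numeric(tapply(trials, idx, sum))
  if (sum(s_t) == 0)
    warning("all counts are zero; posterior will sit at the boundary")
  x <- years - year_origin
  model <- binomial_trend_sampler(s_t, k_t, x, years, name,
                                  prior_scale_sigma = prior_scale_sigma)
  fit <- sample_posterior(model, mcmc)
  attr(fit, "years") <- years
  fit
}
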