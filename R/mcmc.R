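#' MCMC settings
#'
#' @param chains Number of chains (>= 2 required for convergence
#'   diagnostics).
#' @param iterations Post-burn-in draws kept per chain.
#' @param burnin Burn-in (adaptation) iterations discarded per chain.
#' @param seed Integer seed; a fixed seed reproduces draws exactly.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(chains = 4L, iterations = 2000L, burnin = 1000L,
                          seed = 1L) {
  stopifnot(chains >= 1, iterations >= 1, burnin >= 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Run the sampler for a model specification
#'
#' The shared posterior-sampling contract: a model specification provides
#' `init(chain)` (an initial state, overdispersed across chains),
#' `step(state, adapt)` (one full Metropolis-within-Gibbs sweep; proposal
#' adaptation is permitted only while `adapt` is `TRUE`, i.e. during
#' burn-in, so the kept draws come from a fixed transition kernel) and
#' `monitor(state)` (the named parameter vector to record). Chains are run
#' sequentially under a single seeded RNG stream, so a fixed seed
#' reproduces every draw.
#'
#' @param model A model specification as built by the `fit_*` functions or
#'   [proportion_model()].
#' @param mcmc An [mcmc_settings()] object.
#' @return A [posterior_draws] object.
#' @export
sample_posterior <- function(model, mcmc = mcmc_settings()) {
  stopifnot(is.list(model), is.function(model$init),
            is.function(model$step), is.function(model$monitor))
  set.seed(mcmc$seed)
  first <- model$monitor(model$init(1L))
  if (any(!is.finite(first)))
    stop("initialization error: non-finite parameter values at the ",
         "starting state")
  pnames <- names(first)
  draws <- array(NA_real_,
                 dim = c(mcmc$iterations, mcmc$chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    state <- model$init(ch)
    for (i in seq_len(mcmc$burnin)) state <- model$step(state, adapt = TRUE)
    for (i in seq_len(mcmc$iterations)) {
      state <- model$step(state, adapt = FALSE)
      draws[i, ch, ] <- model$monitor(state)
    }
  }
  if (any(!is.finite(draws)))
    stop("diagnostic error: sampler produced non-finite draws")
  params <- lapply(stats::setNames(pnames, pnames),
                   function(nm) draws[, , nm, drop = TRUE])
  if (mcmc$chains == 1L)
    params <- lapply(params, function(v) matrix(v, ncol = 1L))
  posterior_draws(params, meta = list(seed = mcmc$seed,
                                      chains = mcmc$chains,
                                      iterations = mcmc$iterations,
                                      burnin = mcmc$burnin,
                                      model = model$name %||% "model"))
}

#' Container for posterior draws
#'
#' @param parameters Named list; each element an iterations x chains
#'   numeric matrix of draws for one parameter.
#' @param meta List with at least `seed`, `chains`, `iterations`, `burnin`.
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(parameters, meta) {
  stopifnot(is.list(parameters), length(parameters) >= 1,
            !is.null(names(parameters)))
  dims <- unique(lapply(parameters, dim))
  if (length(dims) != 1)
    stop("all parameters must share the same iterations x chains shape")
  structure(list(parameters = parameters, meta = meta),
            class = "posterior_draws")
}

#' Parameter names held in a draws object
#' @param x A `posterior_draws` object.
#' @return Character vector.
#' @export
parameter_names <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  names(x$parameters)
}

#' Pooled draws for one parameter
#'
#' @param x A `posterior_draws` object.
#' @param parameter Parameter name.
#' @return Numeric vector of all post-burn-in draws, chains concatenated.
#' @export
draws_of <- function(x, parameter) {
  stopifnot(inherits(x, "posterior_draws"))
  m <- x$parameters[[parameter]]
  if (is.null(m))
    stop("unknown parameter: ", parameter, "; available: ",
         paste(utils::head(parameter_names(x), 12), collapse = ", "),
         if (length(parameter_names(x)) > 12) ", ..." else "")
  as.vector(m)
}

#' @export
print.posterior_draws <- function(x, ...) {
  np <- length(x$parameters)
  d <- dim(x$parameters[[1]])
  cat("Posterior draws (", x$meta$model %||% "model", "): ",
      np, " parameters, ", d[2], " chains x ", d[1], " iterations\n",
      sep = "")
  show <- utils::head(parameter_names(x), 8)
  for (nm in show)
    cat(sprintf("  %-18s mean %10.4f  sd %9.4f\n", nm,
                mean(x$parameters[[nm]]), stats::sd(x$parameters[[nm]])))
  if (np > 8) cat("  ... and", np - 8, "more\n")
  invisible(x)
}

#' Persist posterior draws to a long-format CSV
#'
#' Columns `chain`, `iteration`, `parameter`, `value`; read back with
#' [read_posterior_draws()].
#'
#' @param x A `posterior_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(x, path) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- dim(x$parameters[[1]])
  long <- do.call(rbind, lapply(parameter_names(x), function(nm) {
    m <- x$parameters[[nm]]
    data.frame(chain = rep(seq_len(d[2]), each = d[1]),
               iteration = rep(seq_len(d[1]), times = d[2]),
               parameter = nm, value = as.vector(m))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_posterior_draws()]
#' @param path CSV path.
#' @param meta Optional metadata list to attach.
#' @return A `posterior_draws` object.
#' @export
read_posterior_draws <- function(path, meta = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("chain", "iteration", "parameter", "value") %in% names(d)))
  chains <- max(d$chain)
  iters <- max(d$iteration)
  pnames <- unique(d$parameter)
  params <- lapply(stats::setNames(pnames, pnames), function(nm) {
    sub <- d[d$parameter == nm, ]
    m <- matrix(NA_real_, iters, chains)
    m[cbind(sub$iteration, sub$chain)] <- sub$value
    m
  })
  posterior_draws(params, meta = meta %||%
                    list(seed = NA_integer_, chains = chains,
                         iterations = iters, burnin = NA_integer_,
                         model = "restored"))
}

#' Single-proportion binomial model with a flat prior
#'
#' A conjugate toy used to validate the sampler: `y` successes in `K`
#' trials with a Uniform(0, 1) prior on the proportion, whose exact
#' posterior is Beta(y + 1, K - y + 1). Sampled by adaptive random-walk
#' Metropolis on the logit scale; the monitored parameter is `p`.
#'
#' @param y,K Successes and trials, `0 <= y <= K`.
#' @return A model specification for [sample_posterior()].
#' @export
proportion_model <- function(y, K) {
  stopifnot(y >= 0, K >= 1, y <= K)
  # uniform prior on p => density p(1-p) on the logit scale
  lp <- function(eta) (y + 1) * eta - (K + 2) * log1pexp(eta)
  list(
    name = sprintf("proportion(y=%d, K=%d)", y, K),
    init = function(chain) {
      eta0 <- stats::qlogis((y + 1) / (K + 2)) + stats::rnorm(1, 0, 0.5)
      list(eta = eta0, step_size = 2.4 / sqrt(max(1, K * 0.25)), iter = 0L)
    },
    step = function(state, adapt) {
      state$iter <- state$iter + 1L
      prop <- state$eta + state$step_size * stats::rnorm(1)
      acc <- log(stats::runif(1)) < lp(prop) - lp(state$eta)
      if (acc) state$eta <- prop
      if (adapt) {
        gamma <- min(0.5, 1 / sqrt(state$iter))
        state$step_size <- state$step_size * exp(gamma * ((acc * 1) - 0.44))
      }
      state
    },
    monitor = function(state) c(p = stats::plogis(state$eta)))
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(pmin(x, 33))))

# univariate slice sampler (stepping out + shrinkage, Neal 2003);
# logf must be finite at x0
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler: non-finite density at current point")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  lower <- x0 - w * u
  upper <- lower + w
  k <- max_steps
  while (k > 0 && is.finite(lf <- logf(lower)) && lf > z) {
    lower <- lower - w
    k <- k - 1
  }
  k <- max_steps
  while (k > 0 && is.finite(uf <- logf(upper)) && uf > z) {
    upper <- upper + w
    k <- k - 1
  }
  repeat {
    x1 <- stats::runif(1, lower, upper)
    f1 <- logf(x1)
    if (is.finite(f1) && f1 > z) return(x1)
    if (x1 < x0) lower <- x1 else upper <- x1
    if (upper - lower < 1e-12) return(x0)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
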