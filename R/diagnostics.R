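#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio computed over the 2 x chains half-chains. Values near 1 indicate
#' the chains have mixed; the pipeline warns above 1.01.
#'
#' @param m Iterations x chains matrix of draws for one parameter.
#' @return Scalar R-hat (NA when the draws are constant).
#' @export
rhat <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  half <- floor(n / 2)
  if (half < 2 || ncol(m) < 1) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(ch)
    cbind(m[seq_len(half), ch], m[(n - half + 1):n, ch])))
  w <- mean(apply(halves, 2, stats::var))
  b <- half * stats::var(colMeans(halves))
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using chain-averaged autocorrelations with
#' Geyer's initial monotone positive-sequence truncation. For independent
#' draws the result is close to the total draw count (it is capped there).
#'
#' @param m Iterations x chains matrix of draws for one parameter.
#' @return Scalar ESS.
#' @export
ess <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  nch <- ncol(m)
  if (n < 4) return(NA_real_)
  if (stats::sd(m) == 0) return(NA_real_)
  max_lag <- min(n - 2, 500L)
  rho <- rowMeans(vapply(seq_len(nch), function(ch) {
    a <- stats::acf(m[, ch], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1)))
  # Geyer: sum consecutive lag pairs while their sum stays positive and
  # non-increasing
  s <- 0
  prev <- Inf
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k + 1] + ifelse(k + 2 <= length(rho), rho[k + 2], 0)
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
    k <- k + 2
  }
  min(n * nch, n * nch / (1 + 2 * s))
}

#' Convergence diagnostics for a draws object
#'
#' Split R-hat and effective sample size per parameter. Requires at least
#' two chains; warns if any R-hat exceeds `threshold`.
#'
#' @param x A [posterior_draws] object.
#' @param threshold R-hat warning threshold (default 1.01).
#' @return Data frame with columns `parameter`, `rhat`, `ess`, plus a
#'   logical attribute `"converged"`.
#' @export
check_convergence <- function(x, threshold = 1.01) {
  stopifnot(inherits(x, "posterior_draws"))
  if (ncol(x$parameters[[1]]) < 2)
    stop("diagnostics unavailable: at least 2 chains are required")
  out <- data.frame(parameter = parameter_names(x),
                    rhat = vapply(x$parameters, rhat, numeric(1)),
                    ess = vapply(x$parameters, ess, numeric(1)))
  rownames(out) <- NULL
  bad <- out$parameter[!is.na(out$rhat) & out$rhat > threshold]
  if (length(bad) > 0)
    warning("R-hat exceeds ", threshold, " for: ",
            paste(bad, collapse = ", "))
  attr(out, "converged") <- length(bad) == 0
  out
}
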