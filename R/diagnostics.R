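#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain non-stationarity inflates the statistic. Values
#' near 1 indicate the chains agree; the package's convergence contract is
#' split R-hat < 1.05.
#'
#' @param draws A matrix (iterations x chains) or a list of equal-length
#'   numeric vectors, one per chain.
#' @return The split R-hat (scalar).
#' @export
split_rhat <- function(draws) {
  ch <- .as_chain_list(draws)
  half <- lapply(ch, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(length(x) - n + 1L):length(x)])
  })
  ch <- unlist(half, recursive = FALSE)
  m <- length(ch)
  n <- length(ch[[1]])
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size using the initial positive
#' sequence estimator on chain-pooled autocorrelations. Conservative and
#' simple; the package's convergence contract asks for ESS > 400 on
#' reported parameters.
#'
#' @inheritParams split_rhat
#' @return Estimated effective number of independent draws.
#' @export
ess_basic <- function(draws) {
  ch <- .as_chain_list(draws)
  n <- length(ch[[1]])
  m <- length(ch)
  if (n < 4) return(m * n)
  max_lag <- min(n - 2L, 500L)
  # average the per-chain autocorrelations (each about its own mean)
  rho <- rowMeans(vapply(
    ch,
    function(x) {
      if (sd(x) == 0) return(rep(0, max_lag))
      acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1, 1, 1]
    },
    numeric(max_lag)
  ))
  # sum paired autocorrelations while the pair sums stay positive
  s <- 0
  k <- 1L
  while (k + 1L <= max_lag) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

.as_chain_list <- function(draws) {
  if (is.matrix(draws)) {
    draws <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  }
  if (!is.list(draws) || length(draws) == 0) {
    stop("`draws` must be a matrix or a non-empty list of chains")
  }
  if (length(unique(lengths(draws))) != 1) stop("chains must have equal length")
  draws
}
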