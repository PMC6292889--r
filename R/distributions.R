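#' Negative binomial log-pmf in mean/size parameterization
#'
#' Log-probability of a count under the negative binomial distribution with
#' mean `mu` and size (dispersion) `theta`, the parameterization used
#' throughout the package: `Var(Y) = mu + mu^2 / theta`, and
#' `P(Y = 0) = (theta / (theta + mu))^theta`. Larger `theta` means less
#' overdispersion; the Poisson is the `theta -> Inf` limit.
#'
#' @param y Non-negative integer count (vectorized).
#' @param mu Mean, strictly positive (vectorized).
#' @param theta Size parameter, strictly positive.
#' @return Log-probability `log P(Y = y)`.
#' @examples
#' nb_logpmf(0, mu = 1, theta = 1) # log(0.5)
#' @export
nb_logpmf <- function(y, mu, theta) {
  if (any(mu <= 0)) stop("`mu` must be strictly positive")
  if (any(theta <= 0)) stop("`theta` must be strictly positive")
  if (any(y < 0) || any(y != floor(y))) stop("`y` must be a non-negative integer")
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu) - log(theta + mu))
}

#' Second-difference structure matrix of an order-2 random walk
#'
#' Returns the n x n intrinsic precision structure `Q = D'D` where `D` is the
#' (n-2) x n second-difference operator. `Q` has rank `n - 2`; its null space
#' is spanned by constant and linear functions of time, which is what lets
#' the RW2 prior smooth a trend without penalizing its level or slope.
#'
#' @param n Series length, at least 3.
#' @return An `n x n` matrix.
#' @export
rw2_structure_matrix <- function(n) {
  if (n < 3) stop("RW2 requires a series of length >= 3")
  D <- matrix(0, n - 2L, n)
  for (j in seq_len(n - 2L)) D[j, j:(j + 2L)] <- c(1, -2, 1)
  crossprod(D)
}

#' Improper log-density of an order-2 random walk
#'
#' Log-density (up to an additive constant) of a latent series `f` under an
#' intrinsic order-2 random walk with precision `tau`:
#' `(n-2)/2 * log(tau) - tau/2 * sum((f[t+1] - 2 f[t] + f[t-1])^2)`.
#' The density is invariant to adding any linear function of time to `f`.
#'
#' @param f Numeric vector, length at least 3.
#' @param tau Precision, strictly positive.
#' @return Log-density up to a constant.
#' @export
rw2_logdensity <- function(f, tau) {
  n <- length(f)
  if (n < 3) stop("RW2 requires a series of length >= 3")
  if (tau <= 0) stop("`tau` must be strictly positive")
  ssd <- sum(diff(f, differences = 2)^2)
  (n - 2) / 2 * log(tau) - tau / 2 * ssd
}

#' Penalized-complexity prior log-density for a standard deviation
#'
#' The PC prior used for random-effect and random-walk standard deviations:
#' an exponential density on sigma with rate `lambda = -log(alpha) / u`, so
#' that `P(sigma > u) = alpha`. It shrinks toward the base model sigma = 0
#' (a flat trend / no random effect), which controls over-fitting of the
#' latent temporal trend.
#'
#' @param sigma Standard deviation, >= 0 (vectorized).
#' @param u Scale parameter of the tail condition, > 0. Default 0.1.
#' @param alpha Tail probability `P(sigma > u)`, in (0, 1). Default 0.01.
#' @return Log-density of sigma.
#' @examples
#' # P(sigma > 0.1) = 0.01 under the default parameters:
#' integrate(function(s) exp(pc_prior_logdensity(s)), 0.1, Inf)$value
#' @export
pc_prior_logdensity <- function(sigma, u = 0.1, alpha = 0.01) {
  if (u <= 0) stop("`u` must be strictly positive")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (any(sigma < 0)) stop("`sigma` must be non-negative")
  lambda <- -log(alpha) / u
  log(lambda) - lambda * sigma
}

#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' Computes WAIC from a draws x observations matrix of pointwise posterior
#' log-likelihoods: `lppd = sum_i log mean_s exp(ll[s, i])`,
#' `p_waic = sum_i var_s(ll[s, i])`, `waic = -2 (lppd - p_waic)`. Lower WAIC
#' indicates better estimated out-of-sample predictive fit; the variance
#' penalty `p_waic` is the effective number of parameters.
#'
#' @param loglik_matrix Numeric matrix, draws in rows, observations in
#'   columns; at least 2 draws; all entries finite.
#' @return A list with elements `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(loglik_matrix) {
  loglik_matrix <- as.matrix(loglik_matrix)
  if (nrow(loglik_matrix) < 2) stop("WAIC needs at least 2 posterior draws")
  if (!all(is.finite(loglik_matrix))) stop("non-finite log-likelihoods")
  # log mean exp per observation, stabilized by the column maximum
  m <- apply(loglik_matrix, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(loglik_matrix, 2, m)))))
  p_waic <- sum(apply(loglik_matrix, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}
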