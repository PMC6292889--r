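#' Specification of the hierarchical negative-binomial trend model
#'
#' Defines the structure and priors of the CPUE trend model: a negative
#' binomial likelihood with log effort offset, a gear fixed effect, iid
#' normal random effects for region and site-within-region, and a latent
#' order-2 random-walk (RW2) temporal effect. Two variants are supported:
#' `"regional_rw"` lets the RW2 trajectory vary by region (all regions
#' sharing the same smoothing hyperparameter), `"global_rw"` has a single
#' shared trajectory plus an additive region effect.
#'
#' The RW2 standard deviation carries a penalized-complexity prior with
#' `P(sigma > pc_u) = pc_alpha` (defaults 0.1 and 0.01). Fixed effects get
#' broad normal priors; region/site standard deviations get a weaker PC
#' prior; the NB size theta gets a log-uniform prior on a wide range. All
#' are exposed here rather than asserted as canonical.
#'
#' @param variant `"regional_rw"` or `"global_rw"`.
#' @param temporal `"rw2"` (default) or `"none"`; the latter drops the
#'   latent trend and is mainly useful for diagnostics and cross-checks
#'   against standard NB GLM fits.
#' @param pc_u,pc_alpha PC prior parameters for the RW2 standard deviation.
#' @param pc_u_re,pc_alpha_re PC prior parameters for the region and site
#'   random-effect standard deviations.
#' @param beta_sd Standard deviation of the normal priors on fixed effects.
#' @param theta_range Support of the log-uniform prior on theta.
#' @return A `trend_model_spec` object.
#' @export
trend_model_spec <- function(variant = c("regional_rw", "global_rw"),
                             temporal = c("rw2", "none"),
                             pc_u = 0.1, pc_alpha = 0.01,
                             pc_u_re = 1, pc_alpha_re = 0.1,
                             beta_sd = 100,
                             theta_range = c(exp(-7), exp(9))) {
  variant <- match.arg(variant)
  temporal <- match.arg(temporal)
  if (pc_u <= 0 || pc_alpha <= 0 || pc_alpha >= 1) {
    stop("PC prior needs u > 0 and alpha in (0, 1)")
  }
  structure(
    list(variant = variant, temporal = temporal,
         pc_u = pc_u, pc_alpha = pc_alpha,
         pc_u_re = pc_u_re, pc_alpha_re = pc_alpha_re,
         beta_sd = beta_sd, theta_range = theta_range),
    class = "trend_model_spec"
  )
}

#' Fit the Bayesian negative-binomial RW2 trend model
#'
#' Fits the hierarchical CPUE trend model by adaptive Metropolis-within-
#' Gibbs MCMC (implemented in compiled code). Counts are modelled as
#' negative binomial with log mean
#' `beta0 + beta_gear * drumline + u_region + v_site + f_t + log(effort)`,
#' where `f` is the latent RW2 trajectory (shared or per region, depending
#' on the spec variant). The intrinsic trajectory is kept identified by
#' sum-to-zero translation moves that shift its level into the intercept
#' (global trend) or the region effects (regional trends).
#'
#' @param data Data frame with columns `catch` (or `count`), `effort` (> 0),
#'   `region`, `site`, `gear` (`"net"`/`"drumline"`) and `financial_year`.
#'   Typically one group's rows of a [compute_cpue()] series.
#' @param spec A [trend_model_spec()].
#' @param chains Number of MCMC chains (default 4).
#' @param iter Iterations per chain, including warmup (default 3000).
#' @param warmup Warmup iterations discarded and used for adaptation
#'   (default `iter / 2`).
#' @param thin Keep every `thin`-th post-warmup draw (default 1).
#' @param seed Integer seed.
#' @param rhat_threshold Convergence contract on split R-hat (default 1.05).
#' @return A `trend_fit` object: posterior `draws` (matrix, one column per
#'   parameter), `chain` ids, pointwise `loglik` (draws x observations),
#'   `diagnostics` (split R-hat and ESS per parameter), `converged` flag,
#'   plus the data and index maps needed by downstream summaries.
#' @export
fit_trend_model <- function(data, spec = trend_model_spec(), chains = 4,
                            iter = 3000, warmup = floor(iter / 2), thin = 1,
                            seed = 1, rhat_threshold = 1.05) {
  stopifnot(inherits(spec, "trend_model_spec"), is.data.frame(data))
  if (!"catch" %in% names(data) && "count" %in% names(data)) {
    data$catch <- data$count
  }
  need <- c("catch", "effort", "region", "site", "gear", "financial_year")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing columns: ", paste(miss, collapse = ", "))
  if (any(data$effort <= 0)) stop("every observation needs positive effort")
  if (any(data$catch < 0) || any(data$catch != floor(data$catch))) {
    stop("catch must be non-negative integers")
  }
  if (!all(data$gear %in% c("net", "drumline"))) {
    stop("gear must be 'net' or 'drumline' (resolve unknown gear first)")
  }

  region_levels <- sort(unique(data$region))
  site_key <- paste(data$region, data$site, sep = "\r")
  site_levels <- sort(unique(site_key))
  years <- seq(min(data$financial_year), max(data$financial_year))
  if (spec$variant == "regional_rw" && length(region_levels) < 2) {
    stop("regional_rw variant needs at least 2 regions")
  }
  if (spec$temporal == "rw2" && length(years) < 3) {
    stop("RW2 trend needs at least 3 years")
  }
  region_idx <- match(data$region, region_levels) - 1L
  site_idx <- match(site_key, site_levels) - 1L
  year_idx <- match(data$financial_year, years) - 1L
  site_region <- region_idx[match(site_levels, site_key)]
  regional <- spec$variant == "regional_rw"
  include_trend <- spec$temporal == "rw2"

  prior <- list(
    beta_sd = spec$beta_sd,
    pc_u_f = spec$pc_u, pc_alpha_f = spec$pc_alpha,
    pc_u_re = spec$pc_u_re, pc_alpha_re = spec$pc_alpha_re,
    ltheta_lo = log(spec$theta_range[1]), ltheta_hi = log(spec$theta_range[2])
  )

  draw_list <- vector("list", chains)
  ll_list <- vector("list", chains)
  set.seed(as.integer(seed))
  for (ch in seq_len(chains)) {
    res <- .nbrw2_mcmc(
      as.integer(data$catch), log(data$effort),
      region_idx, site_idx,
      as.integer(data$gear == "drumline"), year_idx,
      length(region_levels), length(site_levels), length(years),
      site_region, regional, include_trend,
      as.integer(iter), as.integer(warmup), as.integer(thin), prior
    )
    draw_list[[ch]] <- res$draws
    ll_list[[ch]] <- res$loglik
  }
  n_traj <- if (!include_trend) 0L else if (regional) length(region_levels) else 1L
  f_names <- if (n_traj == 0) character() else {
    if (regional) {
      as.vector(t(outer(region_levels, years,
                        function(r, y) paste0("f[", r, ",", y, "]"))))
    } else {
      paste0("f[", years, "]")
    }
  }
  par_names <- c(
    "beta0", "beta_gear",
    paste0("u[", region_levels, "]"),
    paste0("v[", sub("\r", ":", site_levels), "]"),
    f_names, "sigma_u", "sigma_v", "sigma_f", "theta"
  )
  for (ch in seq_len(chains)) colnames(draw_list[[ch]]) <- par_names

  # diagnostics per parameter across chains (constant columns get R-hat 1)
  diag <- data.frame(parameter = par_names, rhat = NA_real_, ess = NA_real_)
  for (j in seq_along(par_names)) {
    mat <- vapply(draw_list, function(m) m[, j], numeric(nrow(draw_list[[1]])))
    mat <- as.matrix(mat)
    if (all(apply(mat, 2, sd) == 0)) {
      diag$rhat[j] <- 1; diag$ess[j] <- NA
    } else {
      diag$rhat[j] <- split_rhat(mat)
      diag$ess[j] <- ess_basic(mat)
    }
  }
  draws <- do.call(rbind, draw_list)
  loglik <- do.call(rbind, ll_list)
  converged <- all(is.finite(diag$rhat)) & all(diag$rhat < rhat_threshold)
  if (!converged) {
    warning("trend model did not meet the convergence contract (max split R-hat ",
            sprintf("%.3f", max(diag$rhat, na.rm = TRUE)), ")")
  }
  structure(
    list(draws = draws, chain = rep(seq_len(chains), each = nrow(draw_list[[1]])),
         loglik = loglik, spec = spec, data = data,
         region_levels = region_levels, site_levels = site_levels,
         years = years, regional = regional, include_trend = include_trend,
         diagnostics = diag, converged = converged, seed = seed),
    class = "trend_fit"
  )
}

#' @exportS3Method base::print
print.trend_fit <- function(x, ...) {
  cat("Negative-binomial RW2 trend fit (", x$spec$variant, ")\n", sep = "")
  cat(sprintf("  %d observations, %d regions, %d sites, years %d-%d\n",
              nrow(x$data), length(x$region_levels), length(x$site_levels),
              min(x$years), max(x$years)))
  cat(sprintf("  %d posterior draws; max split R-hat %.3f; converged: %s\n",
              nrow(x$draws), max(x$diagnostics$rhat, na.rm = TRUE),
              x$converged))
  qs <- t(apply(x$draws[, c("beta0", "beta_gear", "sigma_f", "theta")], 2,
                quantile, c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "2.5%", "97.5%")
  print(round(qs, 3))
  invisible(x)
}

# posterior draws of the latent trajectory for one region (or the shared one)
.f_draws <- function(fit, region = NULL) {
  if (!fit$include_trend) stop("fit has no latent trend")
  if (fit$regional) {
    if (is.null(region)) stop("regional fit: specify `region`")
    if (!region %in% fit$region_levels) stop("unknown region: ", region)
    cols <- paste0("f[", region, ",", fit$years, "]")
  } else {
    cols <- paste0("f[", fit$years, "]")
  }
  fit$draws[, cols, drop = FALSE]
}

#' Fitted CPUE trajectory at unit effort
#'
#' Posterior summary of model-predicted CPUE per year at one unit of effort
#' of the requested gear, with region and site effects at their typical
#' (zero) level for `region = NULL` on a global-trend fit, at the region's
#' own effect otherwise. For a regional-trend fit without a `region`, the
#' program-wide curve is the mean of the region curves.
#'
#' @param fit A `trend_fit`.
#' @param gear `"net"` or `"drumline"`.
#' @param region Optional region name.
#' @param prob Credibility level of the central interval (default 0.95).
#' @return Data frame `year`, `mean`, `median`, `lower`, `upper`.
#' @export
fitted_cpue <- function(fit, gear = "net", region = NULL, prob = 0.95) {
  stopifnot(inherits(fit, "trend_fit"), gear %in% c("net", "drumline"))
  base <- fit$draws[, "beta0"] +
    if (gear == "drumline") fit$draws[, "beta_gear"] else 0
  curves <- .cpue_curve_draws(fit, region)
  mu <- exp(base) * curves
  a <- (1 - prob) / 2
  data.frame(
    year = fit$years,
    mean = colMeans(mu),
    median = apply(mu, 2, quantile, 0.5),
    lower = apply(mu, 2, quantile, a),
    upper = apply(mu, 2, quantile, 1 - a)
  )
}

# draws x years matrix of exp(u_r + f_{r,t}) averaged as requested
.cpue_curve_draws <- function(fit, region = NULL) {
  if (!fit$include_trend) stop("fit has no latent trend")
  if (!fit$regional) {
    if (!is.null(region) && !region %in% fit$region_levels) {
      stop("unknown region: ", region)
    }
    m <- exp(.f_draws(fit))
    if (!is.null(region)) {
      m <- m * exp(fit$draws[, paste0("u[", region, "]")])
    }
    return(m)
  }
  if (!is.null(region)) {
    return(exp(.f_draws(fit, region) + fit$draws[, paste0("u[", region, "]")]))
  }
  acc <- 0
  for (r in fit$region_levels) {
    acc <- acc + exp(.f_draws(fit, r) + fit$draws[, paste0("u[", r, "]")])
  }
  acc / length(fit$region_levels)
}

#' Percent decline between two endpoint CPUE levels
#'
#' `100 * (1 - mu_last / mu_first)`: the headline statistic summarizing a
#' long-term trend. The default method takes two endpoint means (e.g. the
#' printed first- and last-year catch rates); the `trend_fit` method
#' evaluates the ratio of the fitted smooth at the endpoint years for each
#' posterior draw and reports a posterior median and credible interval.
#' Negative values are increases.
#'
#' @param x First endpoint mean (> 0), or a `trend_fit`.
#' @param ... Passed to methods.
#' @return Default method: the percent decline (numeric). `trend_fit`
#'   method: list with `estimate` (posterior median), `mean`, `lower`,
#'   `upper`, and the per-draw values.
#' @examples
#' percent_decline(9.5, 0.8)   # 91.6 -> prints as 92%
#' percent_decline(18.3, 3.23) # 82.3
#' @export
percent_decline <- function(x, ...) UseMethod("percent_decline")

#' @rdname percent_decline
#' @param mu_last Last endpoint mean.
#' @export
percent_decline.default <- function(x, mu_last, ...) {
  mu_first <- x
  if (any(mu_first <= 0)) stop("`mu_first` must be strictly positive")
  100 * (1 - mu_last / mu_first)
}

#' @rdname percent_decline
#' @param year_first,year_last Endpoint years (default: first and last
#'   fitted year).
#' @param region Optional region (regional-trend fits).
#' @param prob Credibility level (default 0.95).
#' @export
percent_decline.trend_fit <- function(x, year_first = NULL, year_last = NULL,
                                      region = NULL, prob = 0.95, ...) {
  fit <- x
  if (is.null(year_first)) year_first <- min(fit$years)
  if (is.null(year_last)) year_last <- max(fit$years)
  if (!all(c(year_first, year_last) %in% fit$years)) {
    stop("endpoint years outside the fitted span")
  }
  curves <- .cpue_curve_draws(fit, region)
  j0 <- match(year_first, fit$years)
  j1 <- match(year_last, fit$years)
  dr <- 100 * (1 - curves[, j1] / curves[, j0])
  a <- (1 - prob) / 2
  list(
    estimate = unname(quantile(dr, 0.5)), mean = mean(dr),
    lower = unname(quantile(dr, a)), upper = unname(quantile(dr, 1 - a)),
    draws = dr
  )
}

#' Fold change between two probabilities
#'
#' `p_last / p_first`; used for reporting the rise of the annual zero-catch
#' probability over the program's span (e.g. a 4.8-fold increase).
#'
#' @param p_first First value, > 0.
#' @param p_last Last value.
#' @return The ratio.
#' @examples
#' fold_change(0.1, 0.48) # 4.8
#' @export
fold_change <- function(p_first, p_last) {
  if (any(p_first <= 0)) stop("`p_first` must be strictly positive")
  p_last / p_first
}

#' Annual zero-catch probability
#'
#' The model-derived probability of catching no sharks at a site in a given
#' year: for each posterior draw, each site's probability is the product
#' over its gears of `(theta / (theta + mu))^theta` with `mu` evaluated at
#' the site's actual annual effort, and the regional value is the average
#' over the region's sites with effort that year. Both the site-level and
#' region-aggregated outputs are returned.
#'
#' @param fit A `trend_fit`.
#' @param year Financial year within the fitted span.
#' @param region Region name.
#' @param prob Credibility level (default 0.95).
#' @return List with `mean`, `lower`, `upper` (region aggregate), `by_site`
#'   (data frame of per-site posterior means) and the per-draw values.
#' @export
zero_catch_probability <- function(fit, year, region, prob = 0.95) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!region %in% fit$region_levels) stop("unknown region: ", region)
  if (!year %in% fit$years) stop("year outside the fitted span")
  rows <- fit$data[fit$data$region == region & fit$data$financial_year == year, ,
                   drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no effort observed in region %s in %d", region, year))
  }
  theta <- fit$draws[, "theta"]
  f <- if (!fit$include_trend) 0 else {
    fcol <- if (fit$regional) paste0("f[", region, ",", year, "]") else
      paste0("f[", year, "]")
    fit$draws[, fcol]
  }
  u <- fit$draws[, paste0("u[", region, "]")]
  sites <- unique(rows$site)
  p_site <- matrix(1, nrow(fit$draws), length(sites))
  for (k in seq_along(sites)) {
    srows <- rows[rows$site == sites[k], , drop = FALSE]
    vcol <- paste0("v[", region, ":", sites[k], "]")
    v <- fit$draws[, vcol]
    for (i in seq_len(nrow(srows))) {
      g <- as.integer(srows$gear[i] == "drumline")
      mu <- exp(fit$draws[, "beta0"] + g * fit$draws[, "beta_gear"] +
                  u + v + f) * srows$effort[i]
      p_site[, k] <- p_site[, k] * (theta / (theta + mu))^theta
    }
  }
  p_region <- rowMeans(p_site)
  a <- (1 - prob) / 2
  list(
    mean = mean(p_region),
    lower = unname(quantile(p_region, a)),
    upper = unname(quantile(p_region, 1 - a)),
    by_site = data.frame(site = sites, mean = colMeans(p_site)),
    draws = p_region
  )
}

#' WAIC of a fitted trend model
#'
#' Convenience wrapper around [compute_waic()] using the fit's stored
#' pointwise log-likelihood matrix.
#'
#' @param fit A `trend_fit`.
#' @return List `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  compute_waic(fit$loglik)
}

#' Simulate observations directly from the trend model
#'
#' Generates a site x year x gear count table from the hierarchical
#' negative-binomial model itself: log mean =
#' `beta0 + beta_gear * drumline + u_region + v_site + f_{region, t} +
#' log(effort)`, counts drawn NB(mean, theta). Used for parameter-recovery
#' and model-selection studies where the generating trajectory must be
#' known exactly.
#'
#' @param n_region,sites_per_region,n_year Design dimensions.
#' @param f Latent trajectory: a vector of length `n_year` (shared across
#'   regions) or a matrix `n_region x n_year` (regional trends).
#' @param beta0 Intercept (log CPUE scale).
#' @param beta_gear Drumline effect on the log scale.
#' @param sigma_u,sigma_v Standard deviations of the region and site
#'   random intercepts.
#' @param theta NB size parameter.
#' @param effort Effort per observation (gear-years; default 1).
#' @param gears Gear types to include.
#' @param first_year First financial-year label (default 1962).
#' @param seed Integer seed.
#' @return A data frame suitable for [fit_trend_model()], with attributes
#'   `u`, `v` and `f` carrying the simulated truth.
#' @export
simulate_trend_data <- function(n_region, sites_per_region, n_year, f,
                                beta0 = log(5), beta_gear = log(0.4),
                                sigma_u = 0.3, sigma_v = 0.2, theta = 2,
                                effort = 1, gears = c("net", "drumline"),
                                first_year = 1962, seed = 1) {
  set.seed(as.integer(seed))
  if (is.matrix(f)) {
    stopifnot(nrow(f) == n_region, ncol(f) == n_year)
  } else {
    stopifnot(length(f) == n_year)
    f <- matrix(f, n_region, n_year, byrow = TRUE)
  }
  u <- rnorm(n_region, 0, sigma_u)
  v <- rnorm(n_region * sites_per_region, 0, sigma_v)
  grid <- expand.grid(
    gear = gears,
    site_in_region = seq_len(sites_per_region),
    region_i = seq_len(n_region),
    year_i = seq_len(n_year),
    stringsAsFactors = FALSE
  )
  site_i <- (grid$region_i - 1L) * sites_per_region + grid$site_in_region
  eta <- beta0 + beta_gear * (grid$gear == "drumline") + u[grid$region_i] +
    v[site_i] + f[cbind(grid$region_i, grid$year_i)] + log(effort)
  out <- data.frame(
    region = sprintf("region%d", grid$region_i),
    site = sprintf("R%d_S%d", grid$region_i, grid$site_in_region),
    gear = grid$gear,
    financial_year = first_year + grid$year_i - 1L,
    effort = effort,
    catch = rnbinom(nrow(grid), mu = exp(eta), size = theta)
  )
  attr(out, "u") <- u
  attr(out, "v") <- v
  attr(out, "f") <- f
  out
}

#' Linear latent trajectory with a given endpoint decline
#'
#' Convenience constructor for simulation studies: a log-linear trajectory
#' whose endpoint ratio `exp(f[n] - f[1])` equals `1 - decline / 100`,
#' centred to sum to zero.
#'
#' @param n_year Series length.
#' @param decline Endpoint percent decline (e.g. 80); negative = increase.
#' @return Numeric vector of length `n_year`.
#' @export
linear_trajectory <- function(n_year, decline) {
  stopifnot(n_year >= 2, decline < 100)
  slope <- log(1 - decline / 100) / (n_year - 1)
  f <- slope * (seq_len(n_year) - 1)
  f - mean(f)
}
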