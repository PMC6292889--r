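#' Build initial-catch records for the serial-depletion analysis
#'
#' One record per (site, gear, group): catch and effort summed over the
#' first `window` years with positive effort after the gear's installation
#' at that beach. Window sums (rather than a mean of annual ratios) keep
#' the response an integer count with a valid effort offset for the Poisson
#' model; the descriptive average CPUE over the window is also carried for
#' plotting. Sites with fewer than `window` observed years are flagged.
#'
#' @param series CPUE series from [compute_cpue()].
#' @param schedule Installation table `site`, `gear`, `installation_year`
#'   (e.g. [installation_years()]).
#' @param window Window length in years (default 5).
#' @return Data frame with `region`, `site`, `gear`, `group`,
#'   `installation_year`, `initial_catch`, `initial_effort`,
#'   `initial_cpue`, `short_window`.
#' @export
build_initial_records <- function(series, schedule, window = 5) {
  stopifnot(is.data.frame(series), is.data.frame(schedule))
  skey <- paste(schedule$site, schedule$gear, sep = "\r")
  cells <- unique(series[, c("region", "site", "gear", "group")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    inst <- schedule$installation_year[match(paste(cl$site, cl$gear, sep = "\r"),
                                             skey)]
    if (is.na(inst)) {
      stop(sprintf("site %s (%s) present in series but absent from schedule",
                   cl$site, cl$gear))
    }
    rows <- series[series$site == cl$site & series$gear == cl$gear &
                     series$group == cl$group &
                     series$financial_year >= inst, , drop = FALSE]
    rows <- rows[order(rows$financial_year), , drop = FALSE]
    if (nrow(rows) == 0) next # no post-installation effort; logged below
    take <- head(rows, window)
    out[[i]] <- data.frame(
      region = cl$region, site = cl$site, gear = cl$gear, group = cl$group,
      installation_year = inst,
      initial_catch = sum(take$catch),
      initial_effort = sum(take$effort),
      initial_cpue = mean(take$cpue),
      short_window = nrow(take) < window
    )
  }
  dropped <- cells[vapply(out, is.null, TRUE), , drop = FALSE]
  if (nrow(dropped)) {
    message("excluded ", nrow(dropped),
            " site x gear x group cell(s) with no post-installation effort")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- dropped
  res
}

#' Fit the initial-CPUE trend: a Bayesian Poisson mixed model
#'
#' Serial-depletion model for initial catch rates at newly installed
#' beaches: `initial_catch ~ Poisson(mu)` with
#' `log mu = beta0 + beta1 * (installation_year - year0) + u_region +
#' log(initial_effort)`. A negative `beta1` means beaches installed later
#' started with lower catch rates, the signature of region-wide depletion.
#' Fitted by the package's adaptive MCMC sampler.
#'
#' @param records Initial-catch records from [build_initial_records()],
#'   typically one group x gear subset.
#' @param seed Integer seed.
#' @param year0 Reference year for the slope (default: the earliest
#'   installation year present).
#' @param chains,iter,warmup,thin MCMC settings.
#' @param rhat_threshold Convergence contract (default 1.05).
#' @return An `initial_trend_fit`: posterior `draws` of `beta0`, `beta1`,
#'   region effects and `sigma_u`, with diagnostics.
#' @export
fit_initial_trend <- function(records, seed = 1, year0 = NULL,
                              chains = 4, iter = 4000,
                              warmup = floor(iter / 2), thin = 1,
                              rhat_threshold = 1.05) {
  stopifnot(is.data.frame(records))
  if (any(records$initial_effort <= 0)) stop("initial_effort must be positive")
  if (length(unique(records$installation_year)) < 2) {
    stop("slope unidentifiable: records span a single installation year")
  }
  if (is.null(year0)) year0 <- min(records$installation_year)
  region_levels <- sort(unique(records$region))
  prior <- list(beta_sd = 100, pc_u_re = 1, pc_alpha_re = 0.1)
  set.seed(as.integer(seed))
  draw_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- .pois_glmm_mcmc(
      as.integer(records$initial_catch), log(records$initial_effort),
      as.numeric(records$installation_year - year0),
      match(records$region, region_levels) - 1L, length(region_levels),
      as.integer(iter), as.integer(warmup), as.integer(thin), prior
    )
    draw_list[[ch]] <- res$draws
  }
  par_names <- c("beta0", "beta1", paste0("u[", region_levels, "]"), "sigma_u")
  for (ch in seq_len(chains)) colnames(draw_list[[ch]]) <- par_names
  diag <- data.frame(parameter = par_names, rhat = NA_real_, ess = NA_real_)
  for (j in seq_along(par_names)) {
    mat <- vapply(draw_list, function(m) m[, j], numeric(nrow(draw_list[[1]])))
    mat <- as.matrix(mat)
    if (all(apply(mat, 2, sd) == 0)) {
      diag$rhat[j] <- 1
    } else {
      diag$rhat[j] <- split_rhat(mat)
      diag$ess[j] <- ess_basic(mat)
    }
  }
  draws <- do.call(rbind, draw_list)
  converged <- all(is.finite(diag$rhat)) && all(diag$rhat < rhat_threshold)
  if (!converged) {
    warning("initial-trend model did not meet the convergence contract")
  }
  structure(
    list(draws = draws, year0 = year0, region_levels = region_levels,
         diagnostics = diag, converged = converged, records = records),
    class = "initial_trend_fit"
  )
}

#' @exportS3Method base::print
print.initial_trend_fit <- function(x, ...) {
  cat("Poisson initial-CPUE trend fit\n")
  qs <- t(apply(x$draws[, c("beta0", "beta1", "sigma_u")], 2,
                quantile, c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "2.5%", "97.5%")
  print(round(qs, 4))
  cat(sprintf("  P(beta1 < 0) = %.3f; converged: %s\n",
              mean(x$draws[, "beta1"] < 0), x$converged))
  invisible(x)
}

#' Percent decline in initial CPUE between two installation years
#'
#' `100 * (1 - exp(beta1 * (year1 - year0)))` per posterior draw: how much
#' lower the expected initial catch rate is at a beach installed in `year1`
#' than one installed in `year0`. Negative values (increases) are reported
#' as negative percent.
#'
#' @param fit An `initial_trend_fit`, or a numeric vector of slope values
#'   (per-year log rate), for which the transformation is applied directly.
#' @param year0,year1 Comparison years (defaults 1963 and 1998).
#' @param prob Credibility level (default 0.95).
#' @return List `estimate` (posterior median), `mean`, `lower`, `upper`,
#'   and the per-draw values.
#' @export
initial_decline_percent <- function(fit, year0 = 1963, year1 = 1998,
                                    prob = 0.95) {
  beta1 <- if (inherits(fit, "initial_trend_fit")) {
    fit$draws[, "beta1"]
  } else if (is.numeric(fit)) {
    fit
  } else {
    stop("`fit` must be an initial_trend_fit or numeric slope(s)")
  }
  dr <- 100 * (1 - exp(beta1 * (year1 - year0)))
  a <- (1 - prob) / 2
  list(
    estimate = unname(quantile(dr, 0.5)), mean = mean(dr),
    lower = unname(quantile(dr, a)), upper = unname(quantile(dr, 1 - a)),
    draws = dr
  )
}
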