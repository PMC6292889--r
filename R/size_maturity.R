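#' Linear mixed model for long-term body-size trends
#'
#' Models total length (cm) as a linear function of financial year with
#' gear and sex as fixed effects and site nested in region as random
#' intercepts, fitted by REML (or ML) through `lme4::lmer()`. With a single
#' site there is no grouping structure and the model reduces to ordinary
#' least squares via `lm()`. Records must already be length-cleaned
#' ([filter_lengths()]); rows with missing length or unknown sex are
#' dropped (unknown-sex records enter count models but not size models).
#'
#' @param records Catch records with `total_length`, `financial_year`,
#'   `gear`, `sex`, `region`, `site`.
#' @param use_reml Fit by REML (default) or ML.
#' @return A `size_trend_fit`: `slope` (cm/yr), `slope_se`, `p_value` and
#'   `stars` for the Wald test of the year slope, the full fixed-effect
#'   table, random-effect variances, a `singular` flag, and the underlying
#'   model object.
#' @export
fit_size_trend <- function(records, use_reml = TRUE) {
  stopifnot(is.data.frame(records))
  d <- records[!is.na(records$total_length) & records$sex %in% c("F", "M"), ,
               drop = FALSE]
  if (length(unique(d$financial_year)) < 2) {
    stop("size trend needs at least 2 distinct years")
  }
  d$year_c <- d$financial_year - min(d$financial_year)
  multi_gear <- length(unique(d$gear)) > 1
  multi_sex <- length(unique(d$sex)) > 1
  fixed <- paste(c("year_c", if (multi_gear) "gear", if (multi_sex) "sex"),
                 collapse = " + ")
  single_site <- length(unique(paste(d$region, d$site))) == 1
  if (single_site) {
    model <- lm(as.formula(paste("total_length ~", fixed)), data = d)
    smry <- summary(model)$coefficients
    re_var <- c(region = 0, site = 0)
    singular <- FALSE
    resid_var <- summary(model)$sigma^2
  } else {
    form <- as.formula(paste("total_length ~", fixed, "+ (1 | region / site)"))
    model <- lme4::lmer(form, data = d, REML = use_reml)
    smry <- coef(summary(model))
    vc <- as.data.frame(lme4::VarCorr(model))
    re_var <- c(
      region = vc$vcov[vc$grp == "region"],
      site = vc$vcov[vc$grp == "site:region"]
    )
    resid_var <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(model)
    if (singular) {
      message("random-effect structure is singular (a variance estimated at 0)")
    }
  }
  slope <- smry["year_c", "Estimate"]
  se <- smry["year_c", "Std. Error"]
  p <- 2 * (1 - stats::pnorm(abs(slope / se)))
  structure(
    list(slope = slope, slope_se = se, p_value = p, stars = .stars(p),
         fixed_effects = smry, random_variances = re_var,
         residual_variance = resid_var, singular = singular,
         n = nrow(d), year0 = min(d$financial_year), model = model),
    class = "size_trend_fit"
  )
}

.stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @exportS3Method base::print
print.size_trend_fit <- function(x, ...) {
  cat(sprintf("Size trend: %+.3f cm/yr (SE %.3f) %s  [n = %d]\n",
              x$slope, x$slope_se, x$stars, x$n))
  invisible(x)
}

#' Size change rate in centimetres per decade
#'
#' `10 * (first - last) / span_years`: the conventional reporting scale for
#' slow declines in mean body size (positive = shrinking).
#'
#' @param first_mean_cm,last_mean_cm Mean lengths at the endpoints (cm).
#' @param span_years Elapsed years between endpoints (> 0).
#' @return cm per decade.
#' @examples
#' decline_rate_cm_per_decade(272, 215, 55) # 10.4
#' @export
decline_rate_cm_per_decade <- function(first_mean_cm, last_mean_cm, span_years) {
  if (any(span_years <= 0)) stop("`span_years` must be positive")
  10 * (first_mean_cm - last_mean_cm) / span_years
}

#' Percent change in mean size between two endpoints
#'
#' `100 * (last - first) / first`; positive values are increases (e.g.
#' 210 -> 221 cm is +5%), negative values declines (274 -> 215 cm is -22%).
#'
#' @param first_mean_cm,last_mean_cm Mean lengths at the endpoints (cm).
#' @return Percent change.
#' @export
size_change_percent <- function(first_mean_cm, last_mean_cm) {
  if (any(first_mean_cm <= 0)) stop("`first_mean_cm` must be positive")
  100 * (last_mean_cm - first_mean_cm) / first_mean_cm
}

#' Read a size-at-maturity cutoff table
#'
#' Cutoffs are configuration data (columns `species`, `sex`, `cutoff_cm`,
#' optional `source`), not package constants: published estimates differ by
#' study and region, so the analyst supplies the table. A synthetic example
#' table ships at
#' `system.file("extdata", "synthetic_maturity_cutoffs.csv", package =
#' "sharktrend")`; its values are illustrative, not published estimates.
#'
#' @param path CSV path.
#' @return Data frame of cutoffs.
#' @export
read_maturity_cutoffs <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "sex", "cutoff_cm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cutoff table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$cutoff_cm <= 0)) stop("cutoffs must be positive")
  d
}

#' Classify a shark as mature or immature
#'
#' Length-at-maturity classification: an individual is mature iff its total
#' length is at least the species- and sex-specific cutoff (the boundary
#' itself counts as mature).
#'
#' @param length Total length (cm), vectorized.
#' @param species Species label (vectorized).
#' @param sex `"F"` or `"M"` (vectorized).
#' @param cutoffs Cutoff table (see [read_maturity_cutoffs()]).
#' @return Character vector `"mature"` / `"immature"`.
#' @export
classify_maturity <- function(length, species, sex, cutoffs) {
  key <- paste(species, sex, sep = "\r")
  ckey <- paste(cutoffs$species, cutoffs$sex, sep = "\r")
  cut <- cutoffs$cutoff_cm[match(key, ckey)]
  if (anyNA(cut)) {
    bad <- unique(paste0("(", species, ", ", sex, ")")[is.na(cut)])
    stop("no maturity cutoff for: ", paste(bad, collapse = ", "))
  }
  ifelse(length >= cut, "mature", "immature")
}

#' Binomial mixed model for the probability of catching mature individuals
#'
#' Logistic trend in the probability that a caught individual is mature:
#' `logit P(mature) = beta0 + beta1 * year` with random intercepts for site
#' nested in region (`lme4::glmer`); with a single site the model reduces
#' to an ordinary logistic GLM. Fitted separately per species and sex.
#' Complete separation (both classes present but perfectly split by year)
#' is detected and reported.
#'
#' @param records Records of one species x sex with `total_length`,
#'   `financial_year`, `region`, `site`, `sex`, `species`.
#' @param cutoffs Cutoff table (see [read_maturity_cutoffs()]).
#' @return A `maturity_trend_fit`: slope (logit/yr) with SE and p-value,
#'   predicted probabilities with confidence bands at the first and last
#'   year, a `separation` flag, and the model object.
#' @export
fit_maturity_trend <- function(records, cutoffs) {
  stopifnot(is.data.frame(records))
  d <- records[!is.na(records$total_length) & records$sex %in% c("F", "M"), ,
               drop = FALSE]
  if (length(unique(d$species)) != 1 || length(unique(d$sex)) != 1) {
    stop("fit one species x sex at a time")
  }
  d$mature <- as.integer(
    classify_maturity(d$total_length, d$species, d$sex, cutoffs) == "mature"
  )
  if (length(unique(d$mature)) < 2) {
    stop("both outcome classes (mature, immature) must be present")
  }
  d$year_c <- d$financial_year - min(d$financial_year)
  single_site <- length(unique(paste(d$region, d$site))) == 1
  if (single_site) {
    model <- glm(mature ~ year_c, family = binomial(), data = d)
    smry <- summary(model)$coefficients
    singular <- FALSE
  } else {
    model <- lme4::glmer(mature ~ year_c + (1 | region / site),
                         family = binomial(), data = d)
    smry <- coef(summary(model))
    singular <- lme4::isSingular(model)
  }
  slope <- smry["year_c", "Estimate"]
  se <- smry["year_c", "Std. Error"]
  separation <- abs(slope) > 15 || se > 100
  if (separation) warning("possible complete separation: slope poorly identified")
  p <- 2 * (1 - stats::pnorm(abs(slope / se)))

  # endpoint predictions on the fixed-effects (typical-site) scale, with a
  # delta-method confidence band on the logit
  b0 <- smry["(Intercept)", "Estimate"]
  V <- if (single_site) vcov(model) else as.matrix(vcov(model))
  endpoint <- function(yc) {
    eta <- b0 + slope * yc
    se_eta <- sqrt(V[1, 1] + yc^2 * V[2, 2] + 2 * yc * V[1, 2])
    c(prob = plogis(eta), lower = plogis(eta - 1.96 * se_eta),
      upper = plogis(eta + 1.96 * se_eta))
  }
  yrs <- range(d$financial_year)
  structure(
    list(slope = slope, slope_se = se, p_value = p, stars = .stars(p),
         first_year = yrs[1], last_year = yrs[2],
         prob_first = endpoint(0), prob_last = endpoint(yrs[2] - yrs[1]),
         separation = separation, singular = singular, n = nrow(d),
         model = model),
    class = "maturity_trend_fit"
  )
}

#' @exportS3Method base::print
print.maturity_trend_fit <- function(x, ...) {
  cat(sprintf(
    "Maturity trend: %+.4f logit/yr %s; P(mature) %d: %.2f -> %d: %.2f\n",
    x$slope, x$stars, x$first_year, x$prob_first["prob"],
    x$last_year, x$prob_last["prob"]
  ))
  invisible(x)
}
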