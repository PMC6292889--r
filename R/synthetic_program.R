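#' Build the effort table implied by a program's installation schedule
#'
#' Expands each beach's installation year and gear mix into an effort table:
#' one row per (site, financial year, gear with positive configured effort)
#' from the installation year through the end of the program span. Beaches
#' contribute no rows before installation.
#'
#' @param config A [program_config()].
#' @return Effort data frame: `region`, `site`, `financial_year`, `gear`,
#'   `effort`.
#' @export
build_installation_schedule <- function(config) {
  stopifnot(inherits(config, "program_config"))
  yrs <- config$years
  rows <- list()
  for (r in config$regions) {
    b <- r$beaches
    for (i in seq_len(nrow(b))) {
      span <- b$installation_year[i]:yrs[2]
      for (gear in c("net", "drumline")) {
        e <- if (gear == "net") b$net_effort[i] else b$drumline_effort[i]
        if (e <= 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          region = r$name, site = b$site[i], financial_year = span,
          gear = gear, effort = e
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Latent relative abundance trajectory for one region and group
#'
#' Without harvest feedback the trajectory is a deterministic exponential
#' decline, `N_t = N_0 * (1 - decline_rate)^(t - t0)`. With feedback the
#' program's own removals depress next year's abundance:
#' `N_{t+1} = max(0, N_t * (1 - decline_rate) - removal_coeff * catch_t)`,
#' which requires the yearly catch series. Abundance is never negative.
#'
#' @param config A [program_config()].
#' @param region Region name.
#' @param group Species group.
#' @param catches Optional numeric vector of total yearly catches (one per
#'   program year); required when harvest feedback is enabled.
#' @return Named numeric vector of relative abundance, one per financial
#'   year of the span.
#' @export
simulate_latent_abundance <- function(config, region, group, catches = NULL) {
  stopifnot(inherits(config, "program_config"))
  if (!region %in% names(config$abundance0)) stop("unknown region: ", region)
  if (!group %in% names(config$decline_rate)) stop("unknown group: ", group)
  yrs <- config$years[1]:config$years[2]
  n0 <- config$abundance0[[region]]
  d <- config$decline_rate[[group]]
  fb <- isTRUE(config$harvest_feedback$enabled)
  if (!fb) {
    N <- n0 * (1 - d)^(seq_along(yrs) - 1)
  } else {
    if (is.null(catches)) stop("harvest feedback requires the yearly catch series")
    if (length(catches) != length(yrs)) stop("catches must cover every program year")
    cc <- config$harvest_feedback$removal_coeff
    N <- numeric(length(yrs))
    N[1] <- n0
    for (i in seq_along(yrs)[-1]) {
      N[i] <- max(0, N[i - 1] * (1 - d) - cc * catches[i - 1])
    }
  }
  setNames(N, yrs)
}

# truncated-normal sampler: rejection while acceptance is high (exact and
# cheap for the wide bounds typical here), switching to the exact
# inverse-CDF construction for means far outside the bounds
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  for (round in 1:30) {
    if (!length(need)) return(out)
    cand <- rnorm(length(need), mean[need], sd)
    ok <- cand >= lower & cand <= upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  if (length(need)) {
    plo <- pnorm(lower, mean[need], sd)
    phi <- pnorm(upper, mean[need], sd)
    out[need] <- qnorm(plo + runif(length(need)) * (phi - plo),
                       mean[need], sd)
    out[need] <- pmin(pmax(out[need], lower), upper)
  }
  out
}

#' Simulate catch records from effort and latent abundance
#'
#' For each (site, year, gear, group) cell the catch count is drawn from a
#' negative binomial with mean `catchability * effort * N_t` and size
#' theta (the model the downstream analysis fits). Each simulated shark
#' receives a capture date within its financial year, a total length from a
#' truncated normal whose mean drifts linearly in time, and a sex. A
#' configurable fraction of records is relabelled with unknown gear, and
#' optionally corrupted with imperial-unit lengths, to exercise cleaning.
#'
#' @param config A [program_config()].
#' @param effort Effort table (normally from [build_installation_schedule()]).
#' @param abundance Nested list `abundance[[region]][[group]]` of yearly
#'   abundance vectors (normally from [simulate_latent_abundance()]).
#' @return Catch-record data frame (see [read_catch_table()] for columns).
#' @export
simulate_catches <- function(config, effort, abundance) {
  stopifnot(inherits(config, "program_config"))
  groups <- config$groups
  qkey <- paste(config$catchability$gear, config$catchability$group, sep = "\r")
  qmap <- setNames(config$catchability$q, qkey)

  cells <- merge(effort, data.frame(group = groups), by = NULL)
  cells <- cells[order(cells$region, cells$site, cells$gear, cells$group,
                       cells$financial_year), ]
  N <- numeric(nrow(cells))
  for (r in unique(cells$region)) {
    for (g in unique(cells$group)) {
      sel <- cells$region == r & cells$group == g
      if (!any(sel)) next
      ab <- abundance[[r]][[g]]
      idx <- match(as.character(cells$financial_year[sel]), names(ab))
      if (anyNA(idx)) {
        yr <- cells$financial_year[sel][which(is.na(idx))[1]]
        stop(sprintf("missing abundance for region %s year %d", r, yr))
      }
      N[sel] <- ab[idx]
    }
  }
  q <- qmap[paste(cells$gear, cells$group, sep = "\r")]
  if (anyNA(q)) stop("catchability table missing a gear x group entry")
  mu <- q * cells$effort * N
  theta <- config$dispersion[cells$group]
  y <- integer(nrow(cells))
  pos <- mu > 0
  y[pos] <- rnbinom(sum(pos), mu = mu[pos], size = theta[pos])

  idx <- rep(seq_len(nrow(cells)), y)
  n_rec <- length(idx)
  if (n_rec == 0) {
    return(data.frame(
      date = as.Date(character()), region = character(), site = character(),
      gear = character(), group = character(), species = character(),
      total_length = numeric(), sex = character(), financial_year = integer()
    ))
  }
  fy <- cells$financial_year[idx]
  day_offset <- floor(runif(n_rec, 0, 365))
  date <- as.Date(sprintf("%d-07-01", fy)) + day_offset
  t_rel <- fy - config$years[1]
  grp <- cells$group[idx]
  len <- numeric(n_rec)
  species <- rep(NA_character_, n_rec)
  for (g in groups) {
    sel <- grp == g
    if (!any(sel)) next
    sm <- config$size_model[[g]]
    len[sel] <- rtruncnorm_reject(
      sum(sel), sm$intercept + sm$slope * t_rel[sel], sm$sd,
      sm$min_tl, sm$tl_max
    )
    if (!is.null(sm$species)) species[sel] <- sm$species
  }
  sex <- ifelse(runif(n_rec) < config$sex_ratio, "F", "M")

  rec <- data.frame(
    date = date, region = cells$region[idx], site = cells$site[idx],
    gear = cells$gear[idx], group = grp, species = species,
    total_length = round(len, 1), sex = sex, financial_year = fy
  )
  if (config$unknown_gear_rate > 0) {
    relabel <- runif(n_rec) < config$unknown_gear_rate
    rec$gear[relabel] <- "unknown"
  }
  if (config$imperial_rate > 0) {
    corrupt <- runif(n_rec) < config$imperial_rate
    divisor <- ifelse(runif(n_rec) < 0.5, 2.54, 30.48)
    rec$total_length[corrupt] <- round(rec$total_length[corrupt] /
                                         divisor[corrupt], 1)
  }
  rownames(rec) <- NULL
  rec
}

#' Simulate a complete synthetic program
#'
#' Seeds the RNG from the config and runs schedule, abundance and catch
#' simulation end to end. With harvest feedback enabled, abundance and
#' catches are generated jointly year by year so that removals feed back
#' into next year's abundance.
#'
#' @param config A [program_config()].
#' @return A list with `catch` (records), `effort`, `abundance` (nested
#'   list region -> group -> yearly vector) and `config`.
#' @export
simulate_program <- function(config) {
  stopifnot(inherits(config, "program_config"))
  set.seed(config$seed)
  effort <- build_installation_schedule(config)
  region_names <- vapply(config$regions, function(r) r$name, "")
  yrs <- config$years[1]:config$years[2]

  if (!isTRUE(config$harvest_feedback$enabled)) {
    abundance <- lapply(setNames(region_names, region_names), function(r) {
      lapply(setNames(config$groups, config$groups), function(g) {
        simulate_latent_abundance(config, r, g)
      })
    })
    catch <- simulate_catches(config, effort, abundance)
  } else {
    # sequential generation: one year at a time, feeding catches back
    cc <- config$harvest_feedback$removal_coeff
    abundance <- lapply(setNames(region_names, region_names), function(r) {
      lapply(setNames(config$groups, config$groups), function(g) {
        setNames(c(config$abundance0[[r]], numeric(length(yrs) - 1)), yrs)
      })
    })
    parts <- list()
    for (i in seq_along(yrs)) {
      eff_y <- effort[effort$financial_year == yrs[i], , drop = FALSE]
      if (nrow(eff_y)) {
        rec_y <- simulate_catches(config, eff_y, abundance)
        parts[[length(parts) + 1L]] <- rec_y
      } else {
        rec_y <- NULL
      }
      if (i < length(yrs)) {
        for (r in region_names) for (g in config$groups) {
          d <- config$decline_rate[[g]]
          caught <- if (is.null(rec_y)) 0 else {
            sum(rec_y$region == r & rec_y$group == g)
          }
          N <- abundance[[r]][[g]]
          N[i + 1] <- max(0, N[i] * (1 - d) - cc * caught)
          abundance[[r]][[g]] <- N
        }
      }
    }
    catch <- do.call(rbind, parts)
    rownames(catch) <- NULL
  }
  list(catch = catch, effort = effort, abundance = abundance, config = config)
}

#' Write a simulated program to disk
#'
#' Writes the catch and effort tables as CSV, the configuration as YAML and
#' a run manifest (seed, config hash, row counts, timestamp) as JSON.
#'
#' @param sim Result of [simulate_program()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_program <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catch_path <- file.path(dir, "catch.csv")
  effort_path <- file.path(dir, "effort.csv")
  config_path <- file.path(dir, "config.yaml")
  write_catch_table(sim$catch, catch_path)
  write_effort_table(sim$effort, effort_path)
  write_program_config(sim$config, config_path)
  manifest <- list(
    package = "sharktrend",
    seed = sim$config$seed,
    config_md5 = unname(tools::md5sum(config_path)),
    input_md5 = list(
      catch = unname(tools::md5sum(catch_path)),
      effort = unname(tools::md5sum(effort_path))
    ),
    n_catch_records = nrow(sim$catch),
    n_effort_rows = nrow(sim$effort),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
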