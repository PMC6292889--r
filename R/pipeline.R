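#' Run the full analysis pipeline on a synthetic or loaded program
#'
#' Orchestrates the analysis end to end: simulate (or load) catch and
#' effort tables, clean lengths and reallocate unknown gear, compute CPUE,
#' fit the trend model per group and variant with a WAIC comparison table,
#' compute endpoint decline and zero-catch summaries, fit the
#' initial-CPUE depletion model per gear, and fit size (and, when species
#' labels and cutoffs are available, maturity) trends. Outputs are written
#' as CSV/JSON under `out_dir` together with a run manifest; any stage
#' failure halts with an error naming the stage.
#'
#' @param config A [program_config()] (the program is simulated), or a
#'   directory containing `catch.csv`, `effort.csv` and `config.yaml` from
#'   [write_program()].
#' @param out_dir Output directory.
#' @param groups Groups to analyse (default: all in the config).
#' @param variants Trend-model variants to fit and compare.
#' @param min_tl Minimum plausible length for cleaning (cm).
#' @param cutoffs Optional maturity-cutoff table; when `NULL` and records
#'   carry no species labels, maturity stages are skipped with a notice.
#' @param chains,iter MCMC settings passed to the model fits.
#' @param make_figures Write simple figures when ggplot2 is installed
#'   (figures are illustrative, not part of the tested surface).
#' @return A list with the cleaned tables, CPUE series, per-group trend
#'   fits and WAIC table, depletion fits, size/maturity fits and the
#'   manifest. Also written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, groups = NULL,
                         variants = c("global_rw", "regional_rw"),
                         min_tl = 30, cutoffs = NULL,
                         chains = 2, iter = 2000, make_figures = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- simulate or load -------------------------------------------------------
  sim <- stage("simulate", {
    if (inherits(config, "program_config")) {
      s <- simulate_program(config)
      write_program(s, file.path(out_dir, "program"))
      s
    } else if (is.character(config) && dir.exists(config)) {
      list(
        catch = read_catch_table(file.path(config, "catch.csv")),
        effort = read_effort_table(file.path(config, "effort.csv")),
        config = read_program_config(file.path(config, "config.yaml"))
      )
    } else {
      stop("`config` must be a program_config or a program directory")
    }
  })
  cfg <- sim$config
  if (is.null(groups)) groups <- cfg$groups

  # -- clean ------------------------------------------------------------------
  cleaned <- stage("clean", {
    tlmax <- data.frame(
      group = cfg$groups, species = NA_character_,
      tl_max = vapply(cfg$size_model[cfg$groups], `[[`, 0, "tl_max")
    )
    fl <- filter_lengths(sim$catch, tlmax, min_tl = min_tl)
    recs <- allocate_unknown_gear(fl$records, mode = "deterministic")
    write.csv(fl$exclusions, file.path(out_dir, "exclusion_log.csv"),
              row.names = FALSE)
    message(sprintf("clean: %d records in, %d excluded on length, %d kept",
                    nrow(sim$catch), nrow(fl$exclusions), nrow(recs)))
    list(records = recs, exclusions = fl$exclusions)
  })

  # -- cpue -------------------------------------------------------------------
  series <- stage("cpue", {
    s <- compute_cpue(cleaned$records, sim$effort, groups = groups)
    write.csv(s, file.path(out_dir, "cpue_series.csv"), row.names = FALSE)
    s
  })

  # -- trend fits + WAIC ------------------------------------------------------
  trend <- stage("fit-trend", {
    fits <- list()
    waic_rows <- list()
    for (g in groups) {
      dg <- series[series$group == g, ]
      for (v in variants) {
        fit <- fit_trend_model(
          dg, trend_model_spec(variant = v),
          chains = chains, iter = iter, seed = cfg$seed
        )
        fits[[paste(g, v, sep = ".")]] <- fit
        w <- waic(fit)
        waic_rows[[length(waic_rows) + 1L]] <- data.frame(
          group = g, variant = v, waic = w$waic, lppd = w$lppd,
          p_waic = w$p_waic, converged = fit$converged
        )
      }
    }
    waic_table <- do.call(rbind, waic_rows)
    write.csv(waic_table, file.path(out_dir, "waic_table.csv"),
              row.names = FALSE)
    list(fits = fits, waic_table = waic_table)
  })

  # -- decline + zero-catch summaries ----------------------------------------
  summaries <- stage("report-trend", {
    rows <- list()
    for (g in groups) {
      fit <- trend$fits[[paste(g, variants[1], sep = ".")]]
      pd <- percent_decline(fit)
      yr <- range(fit$years)
      z <- lapply(fit$region_levels, function(r) {
        zc <- try(list(
          first = zero_catch_probability(fit, yr[1], r),
          last = zero_catch_probability(fit, yr[2], r)
        ), silent = TRUE)
        if (inherits(zc, "try-error")) NULL else zc
      })
      z <- Filter(Negate(is.null), z)
      fold <- if (length(z)) {
        p0 <- mean(vapply(z, function(x) x$first$mean, 0))
        p1 <- mean(vapply(z, function(x) x$last$mean, 0))
        fold_change(p0, p1)
      } else NA_real_
      rows[[g]] <- data.frame(
        group = g, year_first = yr[1], year_last = yr[2],
        percent_decline = pd$estimate, decline_lower = pd$lower,
        decline_upper = pd$upper, zero_catch_fold_change = fold
      )
    }
    out <- do.call(rbind, rows)
    write.csv(out, file.path(out_dir, "trend_summary.csv"), row.names = FALSE)
    out
  })

  # -- depletion --------------------------------------------------------------
  depletion <- stage("fit-depletion", {
    sched <- installation_years(sim$effort)
    init <- build_initial_records(series, sched)
    write.csv(init, file.path(out_dir, "initial_records.csv"),
              row.names = FALSE)
    fits <- list()
    for (g in groups) {
      for (gear in unique(init$gear)) {
        recs <- init[init$group == g & init$gear == gear, ]
        if (length(unique(recs$installation_year)) < 2) next
        fits[[paste(g, gear, sep = ".")]] <- fit_initial_trend(
          recs, seed = cfg$seed, chains = chains, iter = iter
        )
      }
    }
    list(records = init, fits = fits)
  })

  # -- size and maturity ------------------------------------------------------
  size <- stage("fit-size", {
    fits <- list()
    for (g in groups) {
      recs <- cleaned$records[cleaned$records$group == g &
                                cleaned$records$length_valid &
                                cleaned$records$sex %in% c("F", "M"), ]
      if (nrow(recs) < 20 || length(unique(recs$financial_year)) < 2) {
        message("size stage skipped for group ", g, ": too few usable records")
        next
      }
      fits[[g]] <- fit_size_trend(recs)
    }
    fits
  })
  maturity <- stage("fit-maturity", {
    fits <- list()
    recs <- cleaned$records
    if (is.null(cutoffs) || !"species" %in% names(recs) ||
        all(is.na(recs$species))) {
      message("maturity stage skipped: no species labels or no cutoff table")
    } else {
      cells <- unique(recs[!is.na(recs$species) & recs$sex %in% c("F", "M"),
                           c("species", "sex")])
      for (i in seq_len(nrow(cells))) {
        sp <- cells$species[i]; sx <- cells$sex[i]
        if (!any(cutoffs$species == sp & cutoffs$sex == sx)) next
        d <- recs[!is.na(recs$species) & recs$species == sp &
                    recs$sex == sx & recs$length_valid, ]
        fit <- try(fit_maturity_trend(d, cutoffs), silent = TRUE)
        if (!inherits(fit, "try-error")) fits[[paste(sp, sx, sep = ".")]] <- fit
      }
    }
    fits
  })

  if (make_figures && requireNamespace("ggplot2", quietly = TRUE)) {
    stage("figures", .pipeline_figures(trend, depletion, out_dir))
  }

  manifest <- stage("manifest", {
    m <- list(
      package = "sharktrend",
      seed = cfg$seed,
      groups = groups, variants = variants,
      mcmc = list(chains = chains, iter = iter),
      n_records_in = nrow(sim$catch),
      n_records_kept = nrow(cleaned$records),
      n_length_exclusions = nrow(cleaned$exclusions),
      convergence = lapply(trend$fits, function(f) f$converged),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })

  list(catch = cleaned$records, exclusions = cleaned$exclusions,
       effort = sim$effort, series = series, trend = trend,
       trend_summary = summaries, depletion = depletion, size = size,
       maturity = maturity, manifest = manifest)
}

.pipeline_figures <- function(trend, depletion, out_dir) {
  for (nm in names(trend$fits)) {
    fit <- trend$fits[[nm]]
    fc <- fitted_cpue(fit, gear = "net")
    p <- ggplot2::ggplot(fc, ggplot2::aes(x = year, y = mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                           alpha = 0.3) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Financial year", y = "CPUE (sharks per net-year)",
                    title = nm)
    ggplot2::ggsave(file.path(out_dir, paste0("cpue_", nm, ".pdf")), p,
                    width = 6, height = 4)
  }
  invisible(NULL)
}
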