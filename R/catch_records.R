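#' Assign financial-year labels to calendar dates
#'
#' Shark catch peaks in the austral summer (November--February), so the
#' annual time step runs July--June rather than January--December: dates
#' from 1 July of year Y through 30 June of year Y+1 are labelled Y.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return Integer financial-year labels.
#' @examples
#' assign_financial_year(as.Date(c("1962-07-01", "1963-06-30", "1963-07-01")))
#' # 1962 1962 1963
#' @export
assign_financial_year <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("`date` contains values that are not valid dates")
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y - as.integer(m < 7L)
}

#' Filter implausible total lengths from catch records
#'
#' Excludes records whose total length exceeds the species' or group's
#' maximum recorded total length (TL_max), or falls below a minimum
#' plausible length. The lower cutoff targets measurements that were
#' apparently recorded in imperial units (a 7-foot shark entered as "7").
#' Records with missing length are kept for count analyses and flagged via
#' the `length_valid` column for size analyses. Every exclusion is logged
#' with its reason so the rule is auditable.
#'
#' @param records A catch-record data frame (see [read_catch_table()]).
#' @param tlmax A data frame with columns `group`, `species` (NA for
#'   group-level rows) and `tl_max` (cm). Species-level entries are used
#'   when the record carries a species; otherwise the group-level entry.
#' @param min_tl Minimum plausible total length in cm (default 30).
#' @return A list with `records` (kept rows, plus logical `length_valid`)
#'   and `exclusions` (excluded rows with a `reason` column).
#' @export
filter_lengths <- function(records, tlmax, min_tl = 30) {
  stopifnot(is.data.frame(records), is.data.frame(tlmax))
  if (!all(c("group", "tl_max") %in% names(tlmax))) {
    stop("`tlmax` needs columns group, species, tl_max")
  }
  if (!"species" %in% names(tlmax)) tlmax$species <- NA_character_
  has_len <- !is.na(records$total_length)

  limit <- rep(NA_real_, nrow(records))
  sp_rows <- !is.na(tlmax$species)
  sp_map <- setNames(tlmax$tl_max[sp_rows], tlmax$species[sp_rows])
  gr_map <- setNames(tlmax$tl_max[!sp_rows], tlmax$group[!sp_rows])
  if ("species" %in% names(records)) {
    use_sp <- !is.na(records$species) & records$species %in% names(sp_map)
    limit[use_sp] <- sp_map[records$species[use_sp]]
  } else {
    use_sp <- rep(FALSE, nrow(records))
  }
  need_gr <- !use_sp
  missing_gr <- need_gr & !(records$group %in% names(gr_map))
  if (any(missing_gr & has_len)) {
    stop(
      "no TL_max entry for group(s): ",
      paste(unique(records$group[missing_gr & has_len]), collapse = ", ")
    )
  }
  limit[need_gr] <- gr_map[records$group[need_gr]]

  too_small <- has_len & records$total_length < min_tl
  too_large <- has_len & !too_small & records$total_length > limit
  reason <- rep(NA_character_, nrow(records))
  reason[too_small] <- "below minimum plausible length"
  reason[too_large] <- "above maximum total length"
  drop <- too_small | too_large

  exclusions <- records[drop, , drop = FALSE]
  exclusions$reason <- reason[drop]
  kept <- records[!drop, , drop = FALSE]
  kept$length_valid <- !is.na(kept$total_length)
  rownames(kept) <- rownames(exclusions) <- NULL
  list(records = kept, exclusions = exclusions)
}

#' Reallocate records with unknown gear to nets or drumlines
#'
#' Early program records sometimes lack the gear type. Unknown-gear catch is
#' reassigned to net or drumline in proportion to the known-gear catch of
#' the same species group in the same region (the net share is
#' `n_net / (n_net + n_drumline)`). `mode = "deterministic"` apportions by
#' largest remainder (exact expected counts, ties to net);
#' `mode = "stochastic"` draws each record's gear as Bernoulli(net share).
#' Total catch per (group, region) is conserved exactly in both modes.
#'
#' @param records Catch-record data frame; `gear` values `"unknown"` are
#'   resolved to `"net"` or `"drumline"`.
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @param seed Optional integer seed for the stochastic mode.
#' @return The records with all gear values resolved.
#' @export
allocate_unknown_gear <- function(records, mode = c("deterministic", "stochastic"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  unk <- which(records$gear == "unknown")
  if (length(unk) == 0) return(records)
  if (!is.null(seed)) set.seed(seed)

  cells <- unique(records[unk, c("group", "region")])
  for (i in seq_len(nrow(cells))) {
    g <- cells$group[i]; r <- cells$region[i]
    in_cell <- records$group == g & records$region == r
    idx <- which(in_cell & records$gear == "unknown")
    n_net <- sum(in_cell & records$gear == "net")
    n_drum <- sum(in_cell & records$gear == "drumline")
    if (n_net + n_drum == 0) {
      stop(sprintf(
        "cannot allocate unknown gear for (group=%s, region=%s): no known-gear catch",
        g, r
      ))
    }
    p_net <- n_net / (n_net + n_drum)
    n_u <- length(idx)
    if (mode == "deterministic") {
      k_net <- floor(n_u * p_net)
      rem_net <- n_u * p_net - k_net
      rem_drum <- n_u * (1 - p_net) - floor(n_u * (1 - p_net))
      leftover <- n_u - k_net - floor(n_u * (1 - p_net))
      if (leftover > 0 && rem_net >= rem_drum) k_net <- k_net + leftover
      records$gear[idx] <- c(
        rep("net", k_net),
        rep("drumline", n_u - k_net)
      )
    } else {
      records$gear[idx] <- ifelse(runif(n_u) < p_net, "net", "drumline")
    }
  }
  records
}

#' Compute catch per unit effort
#'
#' Standardizes catch by effort at each site: one row per
#' (region, site, gear, group, financial year) with `cpue = catch / effort`
#' in sharks per gear-year. Every effort cell with positive effort yields a
#' row for every requested group (zero catch is data, not absence); cells
#' with zero effort and zero catch are omitted; catch recorded where no
#' positive effort exists is a data error and raises.
#'
#' @param catch Either a catch-record data frame (rows are individual
#'   sharks) or a pre-aggregated count table with columns `region`, `site`,
#'   `financial_year`, `gear`, `group`, `catch`.
#' @param effort Effort table: `region`, `site`, `financial_year`, `gear`,
#'   `effort` (gear-years).
#' @param groups Character vector of groups to emit; defaults to the groups
#'   present in `catch`.
#' @return A data frame with columns `region`, `site`, `gear`, `group`,
#'   `financial_year`, `catch`, `effort`, `cpue`.
#' @export
compute_cpue <- function(catch, effort, groups = NULL) {
  stopifnot(is.data.frame(catch), is.data.frame(effort))
  if (any(effort$effort < 0)) stop("effort must be non-negative")
  if (anyDuplicated(effort[, c("site", "financial_year", "gear")])) {
    stop("duplicate (site, financial_year, gear) keys in effort table")
  }
  counts <- if ("catch" %in% names(catch)) {
    catch
  } else {
    agg <- aggregate(
      list(catch = rep(1L, nrow(catch))),
      by = catch[, c("region", "site", "financial_year", "gear", "group")],
      FUN = sum
    )
    agg
  }
  if (is.null(groups)) groups <- sort(unique(counts$group))

  pos <- effort[effort$effort > 0, , drop = FALSE]
  key <- function(d) paste(d$site, d$financial_year, d$gear, sep = "\r")
  ckey <- key(counts)
  ekey <- key(pos)
  bad <- counts$catch > 0 & !(ckey %in% ekey)
  if (any(bad)) {
    b <- counts[which(bad)[1], ]
    stop(sprintf(
      "catch with no positive effort at (site=%s, year=%d, gear=%s)",
      b$site, as.integer(b$financial_year), b$gear
    ))
  }

  grid <- merge(pos, data.frame(group = groups), by = NULL)
  out <- merge(
    grid,
    counts[, c("site", "financial_year", "gear", "group", "catch")],
    by = c("site", "financial_year", "gear", "group"),
    all.x = TRUE
  )
  out$catch[is.na(out$catch)] <- 0L
  out$cpue <- out$catch / out$effort
  out <- out[order(out$region, out$site, out$gear, out$group, out$financial_year),
             c("region", "site", "gear", "group", "financial_year",
               "catch", "effort", "cpue")]
  rownames(out) <- NULL
  out
}

#' Installation year per site and gear
#'
#' First financial year with positive effort for each (region, site, gear).
#'
#' @param effort Effort table.
#' @return Data frame `region`, `site`, `gear`, `installation_year`.
#' @export
installation_years <- function(effort) {
  pos <- effort[effort$effort > 0, , drop = FALSE]
  if (nrow(pos) == 0) stop("effort table has no positive effort")
  agg <- aggregate(
    list(installation_year = pos$financial_year),
    by = pos[, c("region", "site", "gear")],
    FUN = min
  )
  agg[order(agg$region, agg$site, agg$gear), ]
}

#' Initial catch rates at newly installed beaches
#'
#' The average CPUE over the first five years following the installation of
#' gear at a beach — the quantity whose decline across later installation
#' years indicates serial regional depletion. The mean is the unweighted
#' mean of the annual CPUE values over the first `min(window, available)`
#' years with positive effort; sites with fewer than `window` years are
#' flagged.
#'
#' @param series CPUE series from [compute_cpue()].
#' @param installation Data frame `site`, `gear`, `installation_year`
#'   (e.g. from [installation_years()]).
#' @param window Number of years in the initial window (default 5).
#' @return Data frame with one row per (region, site, gear, group):
#'   `installation_year`, `initial_cpue`, `n_years`, `short_window`.
#' @export
initial_cpue <- function(series, installation, window = 5) {
  stopifnot(is.data.frame(series), is.data.frame(installation))
  out <- list()
  cells <- unique(series[, c("region", "site", "gear", "group")])
  ikey <- paste(installation$site, installation$gear, sep = "\r")
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    inst <- installation$installation_year[match(
      paste(cl$site, cl$gear, sep = "\r"), ikey
    )]
    if (is.na(inst)) {
      stop(sprintf("site %s (%s) missing from installation table", cl$site, cl$gear))
    }
    rows <- series[
      series$site == cl$site & series$gear == cl$gear &
        series$group == cl$group & series$financial_year >= inst, ,
      drop = FALSE
    ]
    rows <- rows[order(rows$financial_year), , drop = FALSE]
    if (nrow(rows) == 0) {
      stop(sprintf("site %s (%s) has no post-installation years", cl$site, cl$gear))
    }
    take <- head(rows, window)
    out[[i]] <- data.frame(
      region = cl$region, site = cl$site, gear = cl$gear, group = cl$group,
      installation_year = inst,
      initial_cpue = mean(take$cpue),
      n_years = nrow(take),
      short_window = nrow(take) < window
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- CSV interfaces ---------------------------------------------------------

#' Read and write catch and effort tables
#'
#' Plain-CSV interchange with documented headers. Catch tables carry one row
#' per captured shark: `date` (ISO-8601), `region`, `site`, `gear`
#' (`net`/`drumline`/`unknown`), `group`, `species` (optional), `total_length`
#' (cm, may be empty), `sex` (`F`/`M`/`unknown`), `financial_year`. Effort
#' tables carry `region`, `site`, `financial_year`, `gear`, `effort`
#' (gear-years).
#'
#' @param path File path.
#' @return The table as a data frame (readers) or `path`, invisibly (writers).
#' @name catch_io
NULL

#' @rdname catch_io
#' @export
read_catch_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "region", "site", "gear", "group", "total_length",
            "sex", "financial_year")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("catch table missing columns: ", paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  d$financial_year <- as.integer(d$financial_year)
  bad_fy <- d$financial_year != assign_financial_year(d$date)
  if (any(bad_fy)) stop("financial_year inconsistent with date in ", sum(bad_fy), " row(s)")
  d
}

#' @rdname catch_io
#' @param records Catch-record data frame.
#' @export
write_catch_table <- function(records, path) {
  records$date <- format(as.Date(records$date), "%Y-%m-%d")
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname catch_io
#' @export
read_effort_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "site", "financial_year", "gear", "effort")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("effort table missing columns: ", paste(miss, collapse = ", "))
  d$financial_year <- as.integer(d$financial_year)
  if (any(d$effort < 0)) stop("negative effort")
  d
}

#' @rdname catch_io
#' @param effort Effort data frame.
#' @export
write_effort_table <- function(effort, path) {
  write.csv(effort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
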