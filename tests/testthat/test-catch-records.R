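test_that("financial years follow the July-June rule and partition all dates", {
  expect_equal(assign_financial_year(as.Date("1962-07-01")), 1962L)
  expect_equal(assign_financial_year(as.Date("1963-06-30")), 1962L)
  expect_equal(assign_financial_year(as.Date("1963-07-01")), 1963L)
  # every date maps to exactly one label, and lies inside its label's window
  set.seed(5)
  dates <- as.Date("1962-01-01") + sample.int(20000, 300)
  fy <- assign_financial_year(dates)
  expect_true(all(dates >= as.Date(sprintf("%d-07-01", fy))))
  expect_true(all(dates <= as.Date(sprintf("%d-06-30", fy + 1))))
})

test_that("length filtering excludes out-of-range records with logged reasons", {
  tlmax <- rbind(default_tlmax(),
                 data.frame(group = "hammerhead",
                            species = "scalloped_hammerhead", tl_max = 430))
  recs <- rbind(
    make_records(1, group = "hammerhead", species = "scalloped_hammerhead",
                 total_length = 450),           # above species TL_max
    make_records(1, group = "tiger", total_length = 215),  # kept
    make_records(1, group = "tiger", total_length = 5),    # feet entry
    make_records(1, group = "tiger", total_length = NA)    # missing length
  )
  out <- filter_lengths(recs, tlmax, min_tl = 30)
  expect_equal(nrow(out$records), 2)
  expect_equal(nrow(out$exclusions), 2)
  expect_setequal(out$exclusions$reason,
                  c("above maximum total length",
                    "below minimum plausible length"))
  # missing length kept for counts but flagged for size analyses
  expect_equal(out$records$length_valid, c(TRUE, FALSE))
  # species-level limit applies when species is present: 450 > 430 even
  # though the hammerhead group limit (610) would keep it
  expect_equal(out$exclusions$total_length[
    out$exclusions$reason == "above maximum total length"], 450)
})

test_that("length filtering is idempotent on clean data and errors on unknown groups", {
  recs <- make_records(10, group = "tiger",
                       total_length = seq(60, 550, length.out = 10))
  out <- filter_lengths(recs, default_tlmax())
  expect_equal(nrow(out$records), 10)
  expect_equal(nrow(out$exclusions), 0)
  again <- filter_lengths(out$records, default_tlmax())
  expect_equal(again$records$total_length, out$records$total_length)

  bad <- make_records(1, group = "wobbegong", total_length = 120)
  expect_error(filter_lengths(bad, default_tlmax()), "wobbegong")
})

test_that("unknown gear is reallocated in proportion to known-gear catch", {
  cell <- rbind(
    make_records(30, gear = "net"),
    make_records(10, gear = "drumline"),
    make_records(4, gear = "unknown")
  )
  out <- allocate_unknown_gear(cell, mode = "deterministic")
  expect_equal(sum(out$gear == "net"), 33)       # 30 + 3
  expect_equal(sum(out$gear == "drumline"), 11)  # 10 + 1
  expect_true(all(out$gear != "unknown"))

  # no-op without unknowns
  known <- make_records(5, gear = "net")
  expect_identical(allocate_unknown_gear(known), known)

  # error when a cell has unknowns but no known-gear catch
  orphan <- make_records(2, gear = "unknown", group = "white")
  expect_error(allocate_unknown_gear(orphan), "white")
})

test_that("stochastic allocation is unbiased and conserves totals", {
  cell <- rbind(
    make_records(1, gear = "net"),
    make_records(1, gear = "drumline"),
    make_records(101, gear = "unknown")
  )
  n_net <- vapply(1:1000, function(s) {
    out <- allocate_unknown_gear(cell, mode = "stochastic", seed = s)
    # conservation: every record still present, same (group, region) totals
    expect_equal(nrow(out), nrow(cell))
    sum(out$gear == "net") - 1
  }, 0)
  se <- sqrt(101 * 0.25 / 1000)
  expect_lt(abs(mean(n_net) - 50.5), 3 * se)
})

test_that("allocation conserves per-cell totals across mixed regions", {
  set.seed(9)
  recs <- do.call(rbind, lapply(c("north", "south"), function(r) {
    rbind(make_records(12, region = r, gear = "net", group = "whaler"),
          make_records(6, region = r, gear = "drumline", group = "whaler"),
          make_records(7, region = r, gear = "unknown", group = "whaler"))
  }))
  out <- allocate_unknown_gear(recs, mode = "deterministic")
  for (r in c("north", "south")) {
    expect_equal(sum(out$region == r), 25)
  }
  expect_true(all(out$gear %in% c("net", "drumline")))
})

test_that("CPUE is catch standardized by effort, with contract violations caught", {
  effort <- data.frame(
    region = "regionA", site = "beach1",
    financial_year = c(1970L, 1971L, 1972L),
    gear = "net", effort = c(2, 5, 0)
  )
  counts <- data.frame(
    region = "regionA", site = "beach1", financial_year = 1970L,
    gear = "net", group = "tiger", catch = 19L
  )
  out <- compute_cpue(counts, effort)
  expect_equal(out$cpue[out$financial_year == 1970], 9.5)
  # zero catch in a year with effort is an observation, not a gap
  expect_equal(out$cpue[out$financial_year == 1971], 0)
  # zero-effort year is omitted entirely
  expect_false(1972 %in% out$financial_year)
  # catch against zero effort is a data error naming the cell
  bad <- counts; bad$financial_year <- 1972L
  expect_error(compute_cpue(bad, effort), "1972")
})

test_that("CPUE computation conserves total catch", {
  cfg <- tiny_config(years = c(1962, 1975), net = 2, drum = 3, theta = 1,
                     seed = 21)
  sim <- simulate_program(cfg)
  series <- compute_cpue(sim$catch, sim$effort)
  expect_equal(sum(series$catch), nrow(sim$catch))
  expect_equal(series$cpue, series$catch / series$effort)
})

test_that("initial CPUE averages the first window years", {
  series <- data.frame(
    region = "regionA", site = "beach1", gear = "net", group = "tiger",
    financial_year = 1970:1976,
    catch = c(10, 8, 6, 4, 2, 1, 1), effort = 1,
    cpue = c(10, 8, 6, 4, 2, 1, 1)
  )
  inst <- data.frame(region = "regionA", site = "beach1", gear = "net",
                     installation_year = 1970L)
  out <- initial_cpue(series, inst)
  expect_equal(out$initial_cpue, 6)   # mean of first five years
  expect_false(out$short_window)

  # constant CPUE returns the constant
  series$cpue <- 3; series$catch <- 3
  expect_equal(initial_cpue(series, inst)$initial_cpue, 3)

  # short windows are truncated means and flagged
  short <- series[1:3, ]; short$cpue <- c(3, 3, 6)
  out3 <- initial_cpue(short, inst)
  expect_equal(out3$initial_cpue, 4)
  expect_true(out3$short_window)
})

test_that("catch and effort tables round-trip through CSV", {
  cfg <- tiny_config(years = c(1962, 1966), seed = 4, drum = 1)
  sim <- simulate_program(cfg)
  tmp <- withr::local_tempdir()
  write_catch_table(sim$catch, file.path(tmp, "catch.csv"))
  write_effort_table(sim$effort, file.path(tmp, "effort.csv"))
  catch2 <- read_catch_table(file.path(tmp, "catch.csv"))
  effort2 <- read_effort_table(file.path(tmp, "effort.csv"))
  expect_equal(catch2$total_length, sim$catch$total_length)
  expect_equal(catch2$financial_year, sim$catch$financial_year)
  expect_equal(effort2$effort, sim$effort$effort)
  # inconsistent financial years are rejected on read
  bad <- sim$catch; bad$financial_year <- bad$financial_year + 1L
  write_catch_table(bad, file.path(tmp, "bad.csv"))
  expect_error(read_catch_table(file.path(tmp, "bad.csv")), "inconsistent")
})
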