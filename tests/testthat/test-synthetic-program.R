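test_that("installation schedule expands beaches into effort rows", {
  cfg <- tiny_config(years = c(1962, 1964), net = 1, drum = 0)
  eff <- build_installation_schedule(cfg)
  expect_equal(nrow(eff), 3)
  expect_true(all(eff$effort == 1))
  expect_true(all(eff$gear == "net"))

  # nothing before the installation year
  cfg2 <- tiny_config(years = c(1962, 2017), install = 1990)
  eff2 <- build_installation_schedule(cfg2)
  expect_equal(min(eff2$financial_year), 1990)

  # staggered beaches contribute span-length row counts
  cfg3 <- program_config(
    regions = list(list(
      name = "regionA",
      beaches = data.frame(site = c("b1", "b2"),
                           installation_year = c(1962, 1975),
                           net_effort = 1, drumline_effort = 0)
    )),
    years = c(1962, 2017),
    decline_rate = c(tiger = 0),
    catchability = data.frame(gear = "net", group = "tiger", q = 1),
    dispersion = c(tiger = 2),
    size_model = list(tiger = list(intercept = 272, slope = 0, sd = 55,
                                   min_tl = 50, tl_max = 600))
  )
  eff3 <- build_installation_schedule(cfg3)
  expect_equal(as.vector(table(eff3$site)), c(56, 43))

  # installation outside the span is a configuration error
  expect_error(tiny_config(years = c(1962, 1980), install = 1990),
               "installation year outside")
})

test_that("latent abundance follows the configured dynamics", {
  cfg <- tiny_config(years = c(1962, 1971), decline = 0)
  N <- simulate_latent_abundance(cfg, "regionA", "tiger")
  expect_true(all(N == N[1]))

  cfg2 <- program_config(
    regions = cfg$regions, years = c(1962, 1964),
    abundance0 = c(regionA = 100),
    decline_rate = c(tiger = 0.05),
    catchability = cfg$catchability, dispersion = cfg$dispersion,
    size_model = cfg$size_model
  )
  N2 <- simulate_latent_abundance(cfg2, "regionA", "tiger")
  expect_equal(unname(N2[3]), 90.25)  # 100 * 0.95^2

  # harvest feedback has an absorbing zero
  cfg3 <- program_config(
    regions = cfg$regions, years = c(1962, 1966),
    abundance0 = c(regionA = 10),
    decline_rate = c(tiger = 0.1),
    harvest_feedback = list(enabled = TRUE, removal_coeff = 1),
    catchability = cfg$catchability, dispersion = cfg$dispersion,
    size_model = cfg$size_model
  )
  N3 <- simulate_latent_abundance(cfg3, "regionA", "tiger",
                                  catches = c(20, 0, 0, 0, 0))
  expect_equal(unname(N3), c(10, 0, 0, 0, 0))
  expect_true(all(N3 >= 0))

  expect_error(tiny_config(decline = 1.2), "decline_rate")
  expect_error(simulate_latent_abundance(cfg, "nowhere", "tiger"), "region")
})

test_that("zero catchability yields no catches", {
  cfg <- tiny_config(years = c(1962, 1970), q_net = 0, q_drum = 0, drum = 1)
  sim <- simulate_program(cfg)
  expect_equal(nrow(sim$catch), 0)
})

test_that("simulated counts match the configured NB mean and variance", {
  # 10^4 one-year cells at mu = catchability * effort * N = 2
  cfg <- tiny_config(years = c(1, 10000), q_net = 2, net = 1, theta = 2,
                     decline = 0, seed = 66, size_slope = 0)
  sim <- simulate_program(cfg)
  counts <- table(factor(sim$catch$financial_year, levels = 1:10000))
  y <- as.vector(counts)
  n <- length(y)
  se_mean <- sd(y) / sqrt(n)
  expect_lt(abs(mean(y) - 2), 3 * se_mean)
  # variance ~ mu + mu^2/theta = 4; SE of the sample variance from moments
  v <- var(y)
  m4 <- mean((y - mean(y))^4)
  se_var <- sqrt((m4 - v^2) / n)
  expect_lt(abs(v - 4), 3 * se_var)
})

test_that("near-Poisson dispersion gives mean close to variance", {
  cfg <- tiny_config(years = c(1, 5000), q_net = 2, theta = 1e6,
                     decline = 0, seed = 8, size_slope = 0)
  sim <- simulate_program(cfg)
  y <- as.vector(table(factor(sim$catch$financial_year, levels = 1:5000)))
  expect_lt(abs(var(y) / mean(y) - 1), 0.1)
})

test_that("simulated lengths drift at the configured slope", {
  cfg <- tiny_config(years = c(1962, 2011), q_net = 20, theta = 10,
                     decline = 0, seed = 13)
  cfg$size_model$tiger$slope <- 0
  sim <- simulate_program(cfg)
  fit <- lm(total_length ~ financial_year, data = sim$catch)
  slope <- coef(summary(fit))["financial_year", ]
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"])

  cfg2 <- tiny_config(years = c(1962, 2011), q_net = 20, theta = 10,
                      decline = 0, seed = 14)
  sim2 <- simulate_program(cfg2)  # slope -1.04 cm/yr
  fit2 <- lm(total_length ~ financial_year, data = sim2$catch)
  slope2 <- coef(summary(fit2))["financial_year", ]
  expect_lt(abs(slope2["Estimate"] + 1.04), 3 * slope2["Std. Error"])
  # truncation bounds respected
  expect_true(all(sim2$catch$total_length >= 50 &
                    sim2$catch$total_length <= 600))
})

test_that("a fixed seed reproduces the program exactly", {
  cfg <- default_program_config(seed = 99, n_regions = 2,
                                beaches_per_region = 2, years = c(1962, 1985))
  s1 <- simulate_program(cfg)
  s2 <- simulate_program(cfg)
  expect_identical(s1$catch, s2$catch)
  expect_identical(s1$effort, s2$effort)
  expect_identical(s1$abundance, s2$abundance)
})

test_that("aggregate simulated CPUE tracks the configured abundance", {
  # aggregate = program-wide annual catch / effort, pooling sites and gears
  cfg <- default_program_config(seed = 31, n_regions = 2,
                                beaches_per_region = 5,
                                years = c(1962, 2011), groups = "tiger",
                                decline_rate = c(tiger = 0.03),
                                unknown_gear_rate = 0)
  for (r in seq_along(cfg$regions)) {
    cfg$regions[[r]]$beaches$installation_year <- 1962L
  }
  sim <- simulate_program(cfg)
  series <- compute_cpue(sim$catch, sim$effort)
  annual <- aggregate(cbind(catch, effort) ~ financial_year, series, sum)
  annual$cpue <- annual$catch / annual$effort
  N <- simulate_latent_abundance(cfg, "region1", "tiger")
  rho <- cor(annual$cpue, N[as.character(annual$financial_year)],
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("unknown-gear relabelling and imperial corruption hit their rates", {
  n_unknown <- 0; n_total <- 0; n_small <- 0
  for (s in 1:10) {
    cfg <- tiny_config(years = c(1962, 2011), q_net = 30, decline = 0,
                       unknown_gear_rate = 0.0241, imperial_rate = 0.05,
                       seed = 500 + s)
    sim <- simulate_program(cfg)
    n_total <- n_total + nrow(sim$catch)
    n_unknown <- n_unknown + sum(sim$catch$gear == "unknown")
    n_small <- n_small + sum(sim$catch$total_length < 30)
  }
  frac_unknown <- n_unknown / n_total
  expect_lt(abs(frac_unknown - 0.0241), 3 * sqrt(0.0241 * 0.9759 / n_total))
  # corrupted lengths fall below any plausible shark size
  expect_gt(n_small, 0)
})

test_that("written programs carry a complete manifest and reload identically", {
  cfg <- tiny_config(years = c(1962, 1970), drum = 1, seed = 12)
  sim <- simulate_program(cfg)
  tmp <- withr::local_tempdir()
  man <- write_program(sim, tmp)
  expect_true(file.exists(file.path(tmp, "manifest.json")))
  expect_equal(man$seed, 12)
  expect_equal(man$n_catch_records, nrow(sim$catch))
  cfg2 <- read_program_config(file.path(tmp, "config.yaml"))
  sim2 <- simulate_program(cfg2)
  expect_equal(sim2$catch$total_length, sim$catch$total_length)
})
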