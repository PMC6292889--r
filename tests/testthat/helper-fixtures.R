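# shared fixture builders; everything is generated in code

# minimal catch-record data frame
make_records <- function(n, region = "regionA", site = "beach1", gear = "net",
                         group = "tiger", species = NA_character_,
                         total_length = 200, sex = "F",
                         financial_year = 1970L) {
  date <- as.Date(sprintf("%d-08-15", financial_year))
  data.frame(
    date = rep(date, length.out = n), region = region, site = site,
    gear = gear, group = group, species = species,
    total_length = rep(total_length, length.out = n),
    sex = rep(sex, length.out = n),
    financial_year = rep(as.integer(financial_year), length.out = n)
  )
}

# one-region one-beach config for simulator unit tests
tiny_config <- function(years = c(1962, 1964), net = 1, drum = 0,
                        install = years[1], decline = 0, q_net = 1,
                        q_drum = 0.5, theta = 2, seed = 1,
                        unknown_gear_rate = 0, imperial_rate = 0,
                        size_slope = -1.04, ...) {
  program_config(
    regions = list(list(
      name = "regionA",
      beaches = data.frame(site = "beach1", installation_year = install,
                           net_effort = net, drumline_effort = drum)
    )),
    years = years,
    decline_rate = c(tiger = decline),
    catchability = data.frame(gear = c("net", "drumline"),
                              group = "tiger", q = c(q_net, q_drum)),
    dispersion = c(tiger = theta),
    size_model = list(tiger = list(intercept = 272, slope = size_slope,
                                   sd = 55, min_tl = 50, tl_max = 600)),
    unknown_gear_rate = unknown_gear_rate,
    imperial_rate = imperial_rate,
    seed = seed,
    ...
  )
}

default_tlmax <- function() {
  data.frame(
    group = c("hammerhead", "whaler", "tiger", "white"),
    species = NA_character_,
    tl_max = c(610, 400, 600, 650)
  )
}
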