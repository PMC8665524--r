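# Synthetic-data generators: determinism, planted truth, statistical sanity

test_that("all generators are pure functions of (config, seed)", {
  s1 <- simulate_trajectory(seed = 5); s2 <- simulate_trajectory(seed = 5)
  expect_identical(as.data.frame(s1$trajectory), as.data.frame(s2$trajectory))
  expect_identical(s1$truth$arrival_dates, s2$truth$arrival_dates)
  expect_false(identical(as.data.frame(s1$trajectory),
                         as.data.frame(simulate_trajectory(seed = 6)$trajectory)))

  cfg <- utils::modifyList(default_temperature_config(),
                           list(lon = 10, lat = 55, years = 2019, noise_sd = 1))
  t1 <- simulate_temperature(cfg, seed = 2)
  t2 <- simulate_temperature(cfg, seed = 2)
  expect_identical(t1$grid$temp, t2$grid$temp)

  r1 <- simulate_ring_recoveries(seed = 3)
  r2 <- simulate_ring_recoveries(seed = 3)
  expect_identical(r1$recoveries, r2$recoveries)

  a1 <- simulate_arrival_dataset(seed = 4)
  a2 <- simulate_arrival_dataset(seed = 4)
  expect_identical(a1$records, a2$records)

  h1 <- simulate_hmm_steps(default_hmm_params(), 100, seed = 9)
  h2 <- simulate_hmm_steps(default_hmm_params(), 100, seed = 9)
  expect_identical(h1, h2)
})

test_that("generators do not disturb the caller's RNG stream", {
  withr::with_seed(1, {
    x1 <- runif(1)
    invisible(simulate_trajectory(seed = 99))
    x2 <- runif(1)
  })
  withr::with_seed(1, {
    y1 <- runif(1)
    y2 <- runif(1)
  })
  expect_identical(c(x1, x2), c(y1, y2))
})

test_that("trajectory generator validates site spacing and plants its states", {
  bad <- default_trajectory_config()
  bad$sites <- data.frame(lon = c(10, 10.5), lat = c(52, 52.1))  # ~40 km
  bad$dwell_hours <- c(48, 48)
  expect_error(simulate_trajectory(bad, seed = 1), "2 \\* d_t")
  sim <- simulate_trajectory(seed = 8)
  t <- sim$trajectory
  expect_equal(length(sim$truth$states), nrow(t))
  # dwell-state frequencies approximate the configured mix
  dwell <- sim$truth$states[sim$truth$states != 4]
  freq <- tabulate(dwell, 3) / length(dwell)
  expect_true(all(abs(freq - default_trajectory_config()$site_state_probs) < 0.03))
  # migratory legs head between sites: state-4 steps are long
  ok <- which(sim$truth$states == 4 & !is.na(t$lon))
  ok <- ok[ok < nrow(t) & (ok + 1) %in% which(!is.na(t$lon))]
  steps <- geodesic_km(t$lon[ok], t$lat[ok], t$lon[ok + 1], t$lat[ok + 1])
  expect_gt(stats::median(steps), 50)  # full legs; only leg tails are shorter
})

test_that("HMM stream frequencies follow the transition structure", {
  p <- default_hmm_params()
  sim <- simulate_hmm_steps(p, 50000, seed = 1)
  # symmetric off-diagonal intercepts -> near-uniform occupancy
  freq <- tabulate(sim$states, 4) / 50000
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("zero-noise temperature crosses 5 C on the planted day", {
  cfg <- utils::modifyList(default_temperature_config(),
                           list(lon = 10, lat = 50, years = 2019, noise_sd = 0,
                                base_crossing = 100, lat_slope = 0,
                                year_effect = 0))
  sim <- simulate_temperature(cfg, seed = 1)
  daily <- daily_mean_temperature(sim$grid)
  tm <- daily$tmean[, 1, 1]
  expect_equal(tgs_onset(tm, rule = "persistence"), 100L)
  expect_equal(unname(sim$truth$crossing[1, 1, 1]), 100)
  # a warmer year starts earlier
  cfg2 <- utils::modifyList(cfg, list(year_effect = -10))
  sim2 <- simulate_temperature(cfg2, seed = 1)
  tm2 <- daily_mean_temperature(sim2$grid)$tmean[, 1, 1]
  expect_lt(tgs_onset(tm2, rule = "persistence"), 100L)
})

test_that("ring generator reproduces configured band means", {
  cfg <- list(sd_doy = 0, n_per_band = 3)
  sim <- simulate_ring_recoveries(cfg, seed = 7)
  s <- band_passage_summary(sim$recoveries)
  for (i in seq_len(nrow(s))) {
    expect_equal(s$mean_doy[i],
                 sim$truth$band_means[[paste(s$scheme[i], s$band[i], sep = "_")]])
  }
  # CLT check at n = 1000
  cfg2 <- list(sd_doy = 6, n_per_band = 1000, bands = c(20, 30),
               schemes = "Arnhem")
  sim2 <- simulate_ring_recoveries(cfg2, seed = 8)
  s2 <- band_passage_summary(sim2$recoveries, bands = c(20, 30))
  for (i in seq_len(nrow(s2))) {
    mu <- sim2$truth$band_means[[paste(s2$scheme[i], s2$band[i], sep = "_")]]
    expect_lt(abs(s2$mean_doy[i] - mu), 3 * 6 / sqrt(1000) + 0.5)
  }
})

test_that("arrival generator: zero variance is exactly linear; OU correlation", {
  sim <- simulate_arrival_dataset(list(s2_id = 0, s2_idyear = 0, s2_ou = 0,
                                       rho = 1, s2_e = 0), seed = 2)
  rec <- sim$records
  b <- sim$truth$config$beta
  eta <- ifelse(rec$capture_site == "NLD", b["intercept_NLD"], b["intercept_LTU"]) +
    b["tgs_deviation"] * rec$tgs_deviation_s +
    b["max_longitude"] * rec$max_longitude_s +
    ifelse(rec$capture_site == "NLD",
           b["max_longitude:distance_NLD"], b["max_longitude:distance_LTU"]) *
      rec$max_longitude_s * rec$distance_traveled_s
  expect_equal(rec$delta_arrival_d_s, unname(eta), tolerance = 1e-12)

  # empirical lag correlation of pure OU+nugget residuals vs closed form
  s2_ou <- 0.5; rho <- 8; s2_e <- 0.2
  sim2 <- simulate_arrival_dataset(
    list(n_individuals = 400, years_per_individual = 1, events_per_group = 2,
         beta = c(intercept_LTU = 0, intercept_NLD = 0, tgs_deviation = 0,
                  max_longitude = 0, `max_longitude:distance_LTU` = 0,
                  `max_longitude:distance_NLD` = 0),
         s2_id = 0, s2_idyear = 0, s2_ou = s2_ou, rho = rho, s2_e = s2_e),
    seed = 3)
  r2 <- sim2$records
  # pairs within group, correlation at their (variable) lags: standardise by
  # the expected kernel and compare the mean product to its expectation
  g <- split(r2, r2$individual_year)
  prods <- vapply(g, function(d) {
    k <- (s2_ou * exp(-abs(diff(d$arrival_doy)) / rho)) / (s2_ou + s2_e)
    d$delta_arrival_d_s[1] * d$delta_arrival_d_s[2] / (s2_ou + s2_e) - k
  }, numeric(1))
  expect_lt(abs(mean(prods)), 3 / sqrt(length(prods)))
})

test_that("generator outputs pass the consuming readers' validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_trajectory(seed = 12)
  write_movebank_csv(sim$trajectory, f)
  back <- read_movebank_csv(f)
  expect_length(back, 1)
  expect_equal(nrow(back[[1]]), nrow(sim$trajectory))
})
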