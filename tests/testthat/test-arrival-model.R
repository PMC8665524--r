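# Annotation, covariates, the OU mixed model, marginal R2, predictions

toy_phenology <- function() {
  sim <- simulate_temperature(
    utils::modifyList(default_temperature_config(),
                      list(lon = c(10, 30), lat = c(52, 60), years = 2016:2019,
                           noise_sd = 0)),
    seed = 5)
  phenology_grid(daily_mean_temperature(sim$grid))
}

toy_events <- function(phen) {
  data.frame(
    individual_year = c("a_2019", "a_2019", "b_2019"),
    site_id = c(1, 2, 1),
    arrival_date = as.Date(c("2019-04-20", "2019-05-15", "2019-05-01")),
    arrival_doy = c(110, 135, 121),
    lon = c(11, 29, 12), lat = c(53, 59, 53),
    proj_x = c(400, 1800, 500), proj_y = c(10, 40, 0),
    cum_distance_km = c(300, 700, 420))
}

test_that("annotation computes delay against the nearest cell's onset", {
  phen <- toy_phenology()
  ev <- toy_events(phen)
  rec <- annotate_arrivals(ev, phen)
  cell <- nearest_cell(phen, 11, 53)
  onset <- phen$onset[phen$years == 2019, cell$lat_idx, cell$lon_idx]
  expect_equal(rec$delta_arrival_d[1], 110 - onset)
  expect_equal(rec$tgs_onset[1], onset)
  expect_true(all(!is.na(rec$gdd_at_arrival)))
  # gdd accumulates onset..arrival over the same cell
  yr <- as.integer(format(phen$daily$date, "%Y")) == 2019
  tm <- phen$daily$tmean[yr, cell$lat_idx, cell$lon_idx]
  expect_equal(rec$gdd_at_arrival[1],
               growing_degree_days(tm, from = as.integer(onset), to = 111))
})

test_that("events over cells with undefined onset are dropped", {
  phen <- toy_phenology()
  # poison one cell-year
  phen$onset[phen$years == 2019, 1, 1] <- NA
  ev <- toy_events(phen)
  expect_message(rec <- annotate_arrivals(ev, phen), "dropped")
  expect_equal(nrow(rec), 1)  # the two events nearest cell (1,1) are gone
})

test_that("covariates: group maxima, distance naming, exact z-scaling", {
  phen <- toy_phenology()
  rec <- annotate_arrivals(toy_events(phen), phen)
  rec <- derive_covariates(
    rec, end_points = data.frame(individual_year = c("a_2019", "b_2019"),
                                 proj_x = c(2500, 450), proj_y = c(60, 20)))
  # end location dominates for a, an interior event for b's y
  expect_equal(unique(rec$max_longitude[rec$individual_year == "a_2019"]), 2500)
  expect_equal(unique(rec$max_longitude[rec$individual_year == "b_2019"]), 500)
  expect_equal(rec$distance_traveled, rec$cum_distance_km)
  for (v in c("delta_arrival_d_s", "max_longitude_s", "distance_traveled_s")) {
    expect_equal(mean(rec[[v]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(rec[[v]]), 1, tolerance = 1e-12)
  }
  sc <- attr(rec, "scaling")
  expect_equal(as.numeric(sc$max_longitude["mean"]), mean(rec$max_longitude))
})

test_that("with variances fixed at zero the fixed effects are OLS", {
  sim <- simulate_arrival_dataset(seed = 11)
  rec <- sim$records
  fit <- fit_lmm_ou(rec, fix = list(s2_id = 0, s2_idyear = 0, s2_ou = 0,
                                    rho = 1e-8))
  d <- wigeontrack:::.arrival_design(rec, "full", "max_longitude", "delta")
  ols <- stats::lm.fit(d$X, d$y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-6)
})

test_that("OU kernel is 1 at lag zero and decays exponentially", {
  K <- wigeontrack:::.ou_kernel(c(100, 103, 110), rho = 5)
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K[1, 2], exp(-3 / 5))
  expect_equal(K[1, 3], exp(-10 / 5))
})

test_that("rho -> 0 collapses the OU term into the residual variance", {
  sim <- simulate_arrival_dataset(seed = 21)
  rec <- sim$records
  f1 <- fit_lmm_ou(rec, fix = list(s2_id = 0.1, s2_idyear = 0.1,
                                   s2_ou = 0.25, rho = 1e-8, s2_e = 0.15))
  f2 <- fit_lmm_ou(rec, fix = list(s2_id = 0.1, s2_idyear = 0.1,
                                   s2_ou = 0, rho = 1e-8, s2_e = 0.40))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("random-intercept-only fit agrees with lme4 (dual route)", {
  skip_if_not_installed("lme4")
  sim <- simulate_arrival_dataset(list(s2_ou = 0, rho = 1), seed = 31)
  rec <- sim$records
  fit <- fit_lmm_ou(rec, components = c("individual", "individual_year"))
  lf <- lme4::lmer(
    delta_arrival_d_s ~ 0 + capture_site + tgs_deviation_s + max_longitude_s +
      max_longitude_s:distance_traveled_s:capture_site +
      (1 | individual_id / individual_year),
    data = rec, REML = FALSE)
  expect_equal(unname(fit$beta[c("intercept_LTU", "intercept_NLD",
                                 "tgs_deviation", "max_longitude")]),
               unname(lme4::fixef(lf)[1:4]), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-4)
})

test_that("marginal R2 hand cases and bounds", {
  expect_equal(marginal_r2(list(var_fixed = 1, var_random = 1,
                                var_residual = 2)), 0.25)
  expect_equal(marginal_r2(list(var_fixed = 0, var_random = 1,
                                var_residual = 1)), 0)
  expect_equal(marginal_r2(list(var_fixed = 3, var_random = 0,
                                var_residual = 0)), 1)
  expect_error(marginal_r2(list(var_fixed = 0, var_random = 0,
                                var_residual = 0)), "zero total")
  sim <- simulate_arrival_dataset(seed = 41)
  fit <- fit_lmm_ou(sim$records)
  r2 <- marginal_r2(fit)
  expect_gte(r2, 0); expect_lte(r2, 1)
})

test_that("z-values are invariant to rescaling the response", {
  sim <- simulate_arrival_dataset(list(n_individuals = 8,
                                       events_per_group = 5), seed = 51)
  rec <- sim$records
  f1 <- fit_lmm_ou(rec)
  rec2 <- rec
  rec2$delta_arrival_d_s <- rec2$delta_arrival_d_s * 7.3
  f2 <- fit_lmm_ou(rec2)
  expect_equal(f1$z, f2$z, tolerance = 1e-4)
})

test_that("population-level predictions back-transform and are monotone", {
  sim <- simulate_arrival_dataset(list(s2_id = 0, s2_idyear = 0, s2_ou = 0,
                                       rho = 1, s2_e = 0), seed = 61)
  rec <- sim$records
  fit <- fit_lmm_ou(rec, fix = list(s2_id = 0, s2_idyear = 0, s2_ou = 0,
                                    rho = 1e-8))
  beta <- sim$truth$config$beta
  # noise-free data: coefficients recovered exactly
  expect_equal(unname(fit$beta[names(beta)]), unname(beta), tolerance = 1e-6)
  sc <- data.frame(capture_site = "NLD",
                   max_longitude = c(0.5, 1.5, 2.5),
                   distance_traveled = 1, tgs_deviation = 0)
  pred <- predict_delta_arrival(fit, sc)
  hand <- beta["intercept_NLD"] +
    beta["max_longitude"] * sc$max_longitude +
    beta["max_longitude:distance_NLD"] * sc$max_longitude * 1
  expect_equal(pred, unname(hand), tolerance = 1e-6)
  # negative longitude coefficient: predictions decrease with max longitude
  expect_true(all(diff(pred) < 0))
})

test_that("last-arrival variant keeps one event per group, no OU", {
  sim <- simulate_arrival_dataset(seed = 71)
  fit <- fit_lmm_ou(sim$records, variant = "last_arrival")
  expect_named(fit$beta, c("intercept", "tgs_deviation", "max_longitude"))
  expect_equal(fit$varcomp$s2_ou, 0)
  n_groups <- length(unique(sim$records$individual_year))
  expect_equal(length(fit$y), n_groups)
})

test_that("fixed-effect bias is below 5% at n ~ 1000 records", {
  # beta estimates are GLS and should be unbiased; averaged over 20
  # seed-fixed replicates of ~1000 records the empirical bias of each
  # coefficient must stay under 5% of its true magnitude
  beta <- c(intercept_LTU = 1, intercept_NLD = -1, tgs_deviation = 0.8,
            max_longitude = -0.6, `max_longitude:distance_LTU` = 0.5,
            `max_longitude:distance_NLD` = -0.7)
  cfg <- list(n_individuals = 25, years_per_individual = 2,
              events_per_group = 20, beta = beta)
  err <- matrix(0, 20, length(beta))
  for (r in 1:20) {
    simr <- simulate_arrival_dataset(cfg, seed = 400 + r)
    fit <- suppressWarnings(fit_lmm_ou(simr$records, maxit = 150))
    err[r, ] <- fit$beta[names(beta)] - beta
  }
  bias <- colMeans(err)
  expect_true(all(abs(bias) < 0.05 * abs(beta)),
              label = paste(round(bias, 4), collapse = " "))
})
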