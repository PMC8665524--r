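# Seeded generators for every input the pipeline consumes, each returning
# its ground truth. All generators are pure functions of (config, seed):
# randomness is drawn inside withr::with_seed, so identical calls give
# identical output.

#' Default parameters of a well-separated 4-state movement HMM
#'
#' Step means/sds are on the sqrt-km scale; rest steps are tiny with a
#' point mass at zero, migratory steps centre near sqrt(50) ~ 7. Turning
#' angles become more directed (smaller) from rest to migratory flight.
#' Transition intercepts favour dwelling (diagonal); the cosinor terms give
#' a mild day/night switching rhythm.
#' @return `wt_hmm_params`.
#' @export
default_hmm_params <- function() {
  n <- 4
  beta <- matrix(-2.5, n * (n - 1), 3)
  beta[, 2] <- 0.4   # cos term
  beta[, 3] <- -0.2  # sin term
  hmm_params(
    step_mean = c(0.08, 0.45, 1.8, 6.5),
    step_sd = c(0.05, 0.25, 0.7, 1.2),
    step_zero_mass = c(0.3, 0.02, 0, 0),
    angle_shape = c(1.0, 1.1, 1.4, 2.6),
    angle_scale = c(1.8, 1.5, 1.0, 0.35),
    beta = beta,
    delta = c(0.4, 0.3, 0.2, 0.1)
  )
}

# Draw one observation (sqrt_step, turn_angle) from a state's emissions.
.sim_emission <- function(p, s) {
  shape <- p$step_mean[s]^2 / p$step_sd[s]^2
  scale <- p$step_sd[s]^2 / p$step_mean[s]
  step <- if (stats::runif(1) < p$step_zero_mass[s]) 0
          else stats::rgamma(1, shape = shape, scale = scale)
  # half-Weibull magnitude truncated to (0, pi], random sign
  repeat {
    a <- stats::rweibull(1, p$angle_shape[s], p$angle_scale[s])
    if (a <= pi) break
  }
  c(step, a * sample(c(-1, 1), 1))
}

#' Simulate an observation stream directly from the movement HMM
#'
#' States follow the time-varying Markov chain (solar hour cycling 0..23
#' from `start_hour`); observations are drawn from the state emissions.
#'
#' @param p `wt_hmm_params`.
#' @param n_steps Number of intervals.
#' @param seed Integer seed.
#' @param start_hour First solar hour.
#' @return List: `obs` (data.frame `sqrt_step`, `turn_angle`, `solar_hour`)
#'   and `states` (integer truth).
#' @export
simulate_hmm_steps <- function(p, n_steps, seed, start_hour = 0) {
  stopifnot(inherits(p, "wt_hmm_params"))
  withr::with_seed(seed, {
    hours <- (start_hour + seq_len(n_steps) - 1) %% 24
    states <- integer(n_steps)
    obs <- matrix(NA_real_, n_steps, 2)
    states[1] <- sample.int(p$n_states, 1, prob = p$delta)
    obs[1, ] <- .sim_emission(p, states[1])
    for (t in 2:n_steps) {
      G <- hmm_transition_matrix(p, hours[t])
      states[t] <- sample.int(p$n_states, 1, prob = G[states[t - 1], ])
      obs[t, ] <- .sim_emission(p, states[t])
    }
    list(obs = data.frame(sqrt_step = obs[, 1], turn_angle = obs[, 2],
                          solar_hour = hours),
         states = states)
  })
}

#' Default trajectory-simulation configuration
#'
#' A four-site spring itinerary along the NW-European / Siberian corridor,
#' sites far beyond 2 * d_t apart, with dwell times placing every arrival
#' before June 30. Within-site wander stays below d_t / 4.
#' @param d_t Threshold distance (default 50.184 km).
#' @return Config list for [simulate_trajectory()].
#' @export
default_trajectory_config <- function(d_t = 50.184) {
  list(
    sites = data.frame(lon = c(4.9, 13.0, 24.0, 40.0),
                       lat = c(52.4, 54.0, 56.0, 58.5)),
    dwell_hours = c(24 * 40, 24 * 12, 24 * 10, 24 * 30),
    start_time = as.POSIXct("2019-02-05 00:00:00", tz = "UTC"),
    d_t = d_t,
    wander_km = d_t / 8,
    migration_speed_kmh = 65,
    missing_rate = 0.05,
    site_state_probs = c(0.45, 0.45, 0.1)  # rest / non-flight / local flight
  )
}

#' Simulate an hourly GPS trajectory with a planted staging itinerary
#'
#' The bird dwells at each itinerary site (behavioural states 1-3, positions
#' wandering within `wander_km` of the site centre) and migrates between
#' sites in state 4, heading along the geodesic at `migration_speed_kmh`.
#' Missed fixes are injected at `missing_rate` (never the very first fix).
#' Ground truth records the per-fix state, the site centres, and the arrival
#' date at each site (date of the first *observed* non-migratory fix there,
#' so truth stays exact under missingness).
#'
#' @param config See [default_trajectory_config()].
#' @param seed Integer seed.
#' @param individual_id Identifier stored on the trajectory.
#' @return List: `trajectory` (`wt_trajectory`) and `truth` (list with
#'   `sites`, `arrival_dates`, `states`, `config`).
#' @export
simulate_trajectory <- function(config = default_trajectory_config(), seed = 1,
                                individual_id = "sim1") {
  sites <- config$sites
  ns <- nrow(sites)
  if (ns > 1) {
    d <- geodesic_km(sites$lon[-ns], sites$lat[-ns], sites$lon[-1], sites$lat[-1])
    if (any(d < 2 * config$d_t)) {
      stop("itinerary sites must be at least 2 * d_t apart", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    lon <- lat <- spd <- numeric(0)
    st <- integer(0)
    site_first_idx <- integer(ns)
    for (k in seq_len(ns)) {
      site_first_idx[k] <- length(lon) + 1L
      for (h in seq_len(config$dwell_hours[k])) {
        r <- config$wander_km * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- geodesic_destination(sites$lon[k], sites$lat[k], th, r)
        s <- sample.int(3, 1, prob = config$site_state_probs)
        lon <- c(lon, p$lon); lat <- c(lat, p$lat)
        st <- c(st, s)
        spd <- c(spd, if (s == 1) 0 else stats::runif(1, 0.5, 8))
      }
      if (k < ns) {
        cur <- list(lon = lon[length(lon)], lat = lat[length(lat)])
        repeat {
          gap <- geodesic_km(cur$lon, cur$lat, sites$lon[k + 1], sites$lat[k + 1])
          if (gap <= config$wander_km) break
          brg <- initial_bearing(cur$lon, cur$lat, sites$lon[k + 1], sites$lat[k + 1])
          stepk <- min(config$migration_speed_kmh, gap)
          cur <- geodesic_destination(cur$lon, cur$lat, brg, stepk)
          lon <- c(lon, cur$lon); lat <- c(lat, cur$lat)
          st <- c(st, 4L)
          spd <- c(spd, stepk / 3.6)
        }
      }
    }
    n <- length(lon)
    ts <- config$start_time + 3600 * (seq_len(n) - 1)
    miss <- stats::runif(n) < config$missing_rate
    miss[1] <- FALSE
    lon[miss] <- NA_real_; lat[miss] <- NA_real_; spd[miss] <- NA_real_
    traj <- .new_trajectory(
      data.frame(timestamp = ts, lon = lon, lat = lat, ground_speed = spd),
      individual_id,
      as.POSIXlt(config$start_time, tz = "UTC")$year + 1900L
    )
    arrival_dates <- as.Date(vapply(seq_len(ns), function(k) {
      ix <- site_first_idx[k]
      while (miss[ix] || st[ix] == 4L) ix <- ix + 1L
      format(as.Date(as.POSIXlt(ts[ix], tz = "UTC")))
    }, character(1)))
    list(trajectory = traj,
         truth = list(sites = sites, arrival_dates = arrival_dates,
                      states = st, config = config, seed = seed))
  })
}

#' Default temperature-simulation configuration
#'
#' A small gridded world: the noise-free daily mean crosses the 5 deg C
#' reference on an analytically planted day that increases with latitude
#' (later springs further north) and shifts with a per-year effect.
#' @return Config list for [simulate_temperature()].
#' @export
default_temperature_config <- function() {
  list(
    lon = seq(5, 50, by = 5), lat = seq(50, 68, by = 2),
    years = 2016:2020,
    base_crossing = 70,        # DOY at the southernmost row, reference year
    lat_slope = 3.5,           # days later per degree latitude
    year_effect = c(0, 4, -3, 5, -2),  # recycled over years
    amplitude = 12,            # deg C seasonal half-range
    diurnal_amplitude = 3,     # deg C day/night half-range
    noise_sd = 0               # hourly noise, deg C
  )
}

#' Simulate hourly gridded 2-m temperature with known 5 deg C crossing days
#'
#' Daily-mean skeleton per cell and year:
#' `T(d) = 5 + A * sin(2*pi*(d - c + 0.5)/365.25)` where `c` is the planted
#' crossing day, so the noise-free daily mean first exceeds 5 deg C on day
#' `c` exactly. Hourly values add a diurnal cosine (mean zero over 24 h) and
#' optional Gaussian noise.
#'
#' @param config See [default_temperature_config()].
#' @param seed Integer seed.
#' @return List: `grid` (`wt_temp_grid`) and `truth` (list with
#'   `crossing[year, lat, lon]` and the config).
#' @export
simulate_temperature <- function(config = default_temperature_config(), seed = 1) {
  withr::with_seed(seed, {
    nlon <- length(config$lon); nlat <- length(config$lat)
    years <- config$years
    yeff <- rep_len(config$year_effect, length(years))
    crossing <- array(NA_real_, c(length(years), nlat, nlon))
    all_time <- NULL; chunks <- list()
    for (yi in seq_along(years)) {
      y <- years[yi]
      d0 <- as.Date(sprintf("%d-01-01", y))
      nd <- as.integer(as.Date(sprintf("%d-12-31", y)) - d0) + 1L
      tim <- as.POSIXct(d0, tz = "UTC") + 3600 * (seq_len(nd * 24) - 1)
      arr <- array(NA_real_, c(nd * 24, nlat, nlon))
      hour_of <- rep(0:23, nd)
      day_of <- rep(seq_len(nd), each = 24)
      diur <- config$diurnal_amplitude * cos(2 * pi * (hour_of - 14) / 24)
      for (jl in seq_len(nlon)) for (jb in seq_len(nlat)) {
        cr <- config$base_crossing +
          config$lat_slope * (config$lat[jb] - min(config$lat)) + yeff[yi]
        crossing[yi, jb, jl] <- round(cr)
        daily <- 5 + config$amplitude *
          sin(2 * pi * (seq_len(nd) - round(cr) + 0.5) / 365.25)
        v <- daily[day_of] + diur
        if (config$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, config$noise_sd)
        arr[, jb, jl] <- v
      }
      chunks[[yi]] <- arr
      all_time <- c(all_time, tim)
    }
    temp <- array(NA_real_,
                  c(sum(vapply(chunks, function(x) dim(x)[1], integer(1))),
                    nlat, nlon))
    off <- 0
    for (ch in chunks) {
      temp[off + seq_len(dim(ch)[1]), , ] <- ch
      off <- off + dim(ch)[1]
    }
    grid <- temperature_grid(config$lon, config$lat,
                             as.POSIXct(all_time, origin = "1970-01-01", tz = "UTC"),
                             temp)
    list(grid = grid, truth = list(crossing = crossing, config = config, seed = seed))
  })
}

#' Simulate ring recoveries around band-specific mean passage dates
#'
#' Recovery day of year is Normal(mean_doy(band), sd), rounded to whole
#' days; longitudes are uniform within the band.
#'
#' @param config List: `schemes` (character), `bands` (lower edges),
#'   `n_per_band`, `sd_doy`, `mean_doy_fun(band, scheme)` returning the mean
#'   passage DOY, `year`.
#' @param seed Integer seed.
#' @return List: `recoveries` (data.frame `scheme`, `ring_id`, `event_type`,
#'   `date`, `lon`, `lat`) and `truth` (band means).
#' @export
simulate_ring_recoveries <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    schemes = c("Arnhem", "London", "Moscow"),
    bands = seq(0, 70, by = 10),
    n_per_band = 25,
    sd_doy = 7,
    mean_doy_fun = function(band, scheme) 75 + 1.2 * band,
    year = 2010
  ), config)
  withr::with_seed(seed, {
    rows <- list(); truth <- list(); id <- 0
    for (sch in cfg$schemes) for (b in cfg$bands) {
      mu <- cfg$mean_doy_fun(b, sch)
      truth[[paste(sch, b, sep = "_")]] <- mu
      doy <- round(stats::rnorm(cfg$n_per_band, mu, cfg$sd_doy))
      rows[[length(rows) + 1]] <- data.frame(
        scheme = sch,
        ring_id = sprintf("%s%05d", substr(sch, 1, 2), id + seq_along(doy)),
        event_type = "recovery",
        date = as.Date(sprintf("%d-01-01", cfg$year)) + doy - 1,
        lon = stats::runif(cfg$n_per_band, b, b + 10),
        lat = stats::runif(cfg$n_per_band, 50, 65)
      )
      id <- id + cfg$n_per_band
    }
    list(recoveries = do.call(rbind, rows),
         truth = list(band_means = truth, config = cfg, seed = seed))
  })
}

#' Simulate an arrival-record dataset with known mixed-model structure
#'
#' Response = fixed linear predictor + individual intercept + year-within-
#' individual intercept + OU-correlated residual over arrival days + iid
#' noise. Covariates are generated on the standardised scale and the records
#' carry an identity scaling attribute, so [fit_lmm_ou()] applies directly.
#'
#' @param config List overriding: `n_individuals`, `years_per_individual`,
#'   `events_per_group`, `beta` (named vector: `intercept_LTU`,
#'   `intercept_NLD`, `tgs_deviation`, `max_longitude`,
#'   `max_longitude:distance_LTU`, `max_longitude:distance_NLD`), `s2_id`,
#'   `s2_idyear`, `s2_ou`, `rho`, `s2_e`.
#' @param seed Integer seed.
#' @return List: `records` (ready for [fit_lmm_ou()]) and `truth`.
#' @export
simulate_arrival_dataset <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_individuals = 15, years_per_individual = 2, events_per_group = 7,
    beta = c(intercept_LTU = 0.06, intercept_NLD = 0.52,
             tgs_deviation = -0.30, max_longitude = -0.48,
             `max_longitude:distance_LTU` = -0.17,
             `max_longitude:distance_NLD` = -0.26),
    s2_id = 0.1, s2_idyear = 0.1, s2_ou = 0.3, rho = 6, s2_e = 0.2
  ), config)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(cfg$n_individuals)) {
      site <- if (i %% 2 == 0) "NLD" else "LTU"
      b_id <- stats::rnorm(1, 0, sqrt(cfg$s2_id))
      for (yidx in seq_len(cfg$years_per_individual)) {
        year <- 2017 + yidx
        m <- cfg$events_per_group
        b_iy <- stats::rnorm(1, 0, sqrt(cfg$s2_idyear))
        days <- sort(sample(60:181, m))
        maxlon <- stats::rnorm(1)
        dev <- stats::rnorm(1)
        dist <- sort(stats::rnorm(m))
        Sig <- cfg$s2_ou * .ou_kernel(days, rho = cfg$rho) +
          diag(cfg$s2_e, m)
        eps <- if (all(Sig == 0)) rep(0, m)
               else drop(t(chol(Sig)) %*% stats::rnorm(m))
        eta <- cfg$beta[paste0("intercept_", site)] +
          cfg$beta["tgs_deviation"] * dev +
          cfg$beta["max_longitude"] * maxlon +
          cfg$beta[paste0("max_longitude:distance_", site)] * maxlon * dist
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = sprintf("ind%02d", i),
          year = year,
          individual_year = sprintf("ind%02d_%d", i, year),
          capture_site = site,
          arrival_doy = days,
          delta_arrival_d_s = as.numeric(eta) + b_id + b_iy + eps,
          tgs_deviation_s = dev,
          max_longitude_s = maxlon,
          distance_traveled_s = dist
        )
      }
    }
    rec <- do.call(rbind, rows)
    attr(rec, "scaling") <- list(
      delta_arrival_d = c(mean = 0, sd = 1),
      tgs_deviation = c(mean = 0, sd = 1),
      max_longitude = c(mean = 0, sd = 1),
      distance_traveled = c(mean = 0, sd = 1)
    )
    list(records = rec, truth = list(config = cfg, seed = seed))
  })
}

#' Write trajectories to a Movebank-style CSV
#'
#' Inverse of [read_movebank_csv()]; missed fixes get blank coordinates.
#' @param trajectories A `wt_trajectory` or list of them.
#' @param path Output path.
#' @export
write_movebank_csv <- function(trajectories, path) {
  if (inherits(trajectories, "wt_trajectory")) trajectories <- list(trajectories)
  rows <- lapply(trajectories, function(t) {
    data.frame(
      `individual-local-identifier` = attr(t, "individual_id"),
      timestamp = format(t$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      `location-long` = t$lon, `location-lat` = t$lat,
      `ground-speed` = t$ground_speed,
      check.names = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
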