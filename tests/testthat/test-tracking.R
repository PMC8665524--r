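# Movebank reading, cleaning, hourly regularisation, step series

make_traj <- function(ts, lon, lat, speed = NULL, id = "w1") {
  if (is.null(speed)) speed <- rep(1, length(ts))
  wigeontrack:::.new_trajectory(
    data.frame(timestamp = ts, lon = lon, lat = lat, ground_speed = speed),
    id, as.POSIXlt(ts[1], tz = "UTC")$year + 1900L)
}

hours <- function(start, n) as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)

test_that("read_movebank_csv parses, sorts and preserves missing fixes", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_movebank_fixture(f, c(
    "w1,2019-03-01 10:00:00,10.0,52.0,3.2",
    "w1,2019-03-01 12:00:00,10.2,52.1,2.0",
    "w1,2019-03-01 11:00:00,,,",
    "w2,2019-03-01 10:00:00,11.0,53.0,1.0"
  ))
  tr <- read_movebank_csv(f)
  expect_length(tr, 2)
  t1 <- tr[["w1_2019"]]
  expect_equal(nrow(t1), 3)
  expect_true(!is.unsorted(t1$timestamp))
  expect_true(is.na(t1$lon[2]))          # blank coordinates -> missed fix
  expect_false(anyNA(t1$timestamp))
})

test_that("read_movebank_csv errors on missing columns and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,location-long,location-lat", "2019-01-01,1,2"), f)
  expect_error(read_movebank_csv(f), "individual identifier")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_movebank_fixture(f2, c(
    "w1,2019-03-01 10:00:00,10.0,52.0,1",
    "w1,2019-03-01 10:00:00,10.1,52.1,1"
  ))
  expect_error(read_movebank_csv(f2), "duplicate")
})

test_that("clean_trajectory removes only the trailing zero-speed run", {
  ts <- hours("2019-03-01 00:00:00", 10)
  sp <- c(1, 0, 0, 2, 1, 1, 0, 0, 0, 0)   # interior zeros kept, last 4 dropped
  t <- make_traj(ts, 10 + 1:10 / 10, rep(52, 10), sp)
  out <- clean_trajectory(t)
  expect_equal(nrow(out), 6)
  expect_equal(out$ground_speed, sp[1:6])
  # unchanged when the final speed is non-zero
  t2 <- make_traj(ts, 10 + 1:10 / 10, rep(52, 10), rep(1, 10))
  expect_equal(nrow(clean_trajectory(t2)), 10)
})

test_that("clean_trajectory collapses 1 Hz bursts to their first fix", {
  base <- as.POSIXct("2019-03-01 10:00:00", tz = "UTC")
  ts <- c(base + 0:14, base + 3600)        # 15-fix burst then a normal fix
  t <- make_traj(ts, 10 + seq_along(ts) / 100, rep(52, 16), rep(1, 16))
  out <- clean_trajectory(t)
  expect_equal(nrow(out), 2)
  expect_equal(out$timestamp[1], base)
})

test_that("regularize_hourly inserts missed fixes, snaps, and is idempotent", {
  base <- as.POSIXct("2019-03-01 10:00:00", tz = "UTC")
  # fixes at 10:04, 13:00 -> snap to 10:00; fill 11:00, 12:00 as missing
  t <- make_traj(c(base + 240, base + 3 * 3600),
                 c(10.0, 10.3), c(52.0, 52.1), c(1, 1))
  out <- regularize_hourly(t)
  expect_equal(nrow(out), 4)
  expect_equal(out$timestamp[1], base)
  expect_true(all(diff(as.numeric(out$timestamp)) == 3600))
  expect_true(all(is.na(out$lon[2:3])))
  expect_identical(as.data.frame(regularize_hourly(out)), as.data.frame(out))
  # already-hourly input is unchanged
  t2 <- make_traj(hours("2019-03-01 00:00:00", 5), 10 + 1:5 / 10, rep(52, 5))
  expect_equal(as.data.frame(regularize_hourly(t2))[, 1:3],
               as.data.frame(t2)[, 1:3])
})

test_that("regularize_hourly keeps the nearer of two colliding fixes", {
  base <- as.POSIXct("2019-03-01 10:00:00", tz = "UTC")
  t <- make_traj(c(base + 60, base + 240), c(10.0, 10.5), c(52.0, 52.5), c(1, 1))
  expect_message(out <- regularize_hourly(t), "same grid hour")
  expect_equal(nrow(out), 1)
  expect_equal(out$lon, 10.0)  # the 10:01 fix is nearer 10:00 than 10:04
})

test_that("cleaning and regularisation never add located fixes", {
  sim <- simulate_trajectory(seed = 4)
  t <- sim$trajectory
  n0 <- sum(!is.na(t$lon))
  t1 <- clean_trajectory(t)
  t2 <- regularize_hourly(t1)
  expect_lte(sum(!is.na(t1$lon)), n0)
  expect_lte(sum(!is.na(t2$lon)), sum(!is.na(t1$lon)))
})

test_that("compute_steps matches hand values and the bearing oracle", {
  # ~10 km due north from 52N: 10 km / 111.195 km/deg on a sphere; use the
  # package geodesic itself to plant an exact 10 km step
  p0 <- list(lon = 10, lat = 52)
  p1 <- geodesic_destination(p0$lon, p0$lat, 0, 10)
  p2 <- geodesic_destination(p1$lon, p1$lat, 0, 10)
  ts <- hours("2019-03-01 00:00:00", 3)
  t <- make_traj(ts, c(p0$lon, p1$lon, p2$lon), c(p0$lat, p1$lat, p2$lat))
  st <- compute_steps(t)
  expect_equal(nrow(st), 2)
  expect_equal(st$sqrt_step[1], sqrt(10), tolerance = 1e-9)
  expect_true(is.na(st$turn_angle[1]))          # no prior step
  expect_equal(st$turn_angle[2], 0, tolerance = 1e-6)  # collinear
})

test_that("exact reversal gives turn angle +pi and zero steps give NA", {
  # along the equator bearings are exactly 90/270 deg, so the heading change
  # is exactly pi and must take the positive sign by convention
  ts <- hours("2019-03-01 00:00:00", 4)
  t <- make_traj(ts, c(0, 0.1, 0, 0), c(0, 0, 0, 0))
  st <- compute_steps(t)
  expect_identical(st$turn_angle[2], pi)
  expect_equal(st$sqrt_step[3], 0)
  expect_true(is.na(st$turn_angle[3]))          # flanking zero-length step
  # off the equator a reversal is within numerical convergence of |pi|
  p0 <- list(lon = 10, lat = 52)
  p1 <- geodesic_destination(p0$lon, p0$lat, pi / 2, 5)
  t2 <- make_traj(ts[1:3], c(p0$lon, p1$lon, p0$lon), c(p0$lat, p1$lat, p0$lat))
  expect_equal(abs(compute_steps(t2)$turn_angle[2]), pi, tolerance = 1e-3)
})

test_that("turning angles match an independent local-ENU bearing oracle", {
  # ~100-200 m steps: the local tangent-plane bearing (ellipsoidal radii of
  # curvature) approximates the geodesic initial bearing to ~1e-5 rad
  lons <- c(10, 10.001, 10.0025, 10.002)
  lats <- c(52, 52.0005, 52.0, 52.001)
  ts <- hours("2019-03-01 00:00:00", 4)
  t <- make_traj(ts, lons, lats)
  st <- compute_steps(t)
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  bear <- function(i, j) {
    phi <- lats[i] * pi / 180
    Nr <- a / sqrt(1 - e2 * sin(phi)^2)
    Mr <- a * (1 - e2) / (1 - e2 * sin(phi)^2)^1.5
    dx <- (lons[j] - lons[i]) * pi / 180 * Nr * cos(phi)
    dy <- (lats[j] - lats[i]) * pi / 180 * Mr
    atan2(dx, dy)
  }
  for (k in 2:3) {
    d <- (bear(k, k + 1) - bear(k - 1, k) + pi) %% (2 * pi) - pi
    expect_equal(st$turn_angle[k], d, tolerance = 1e-4)
  }
})

test_that("compute_steps demands at least three located fixes", {
  ts <- hours("2019-03-01 00:00:00", 2)
  t <- make_traj(ts, c(10, 10.1), c(52, 52.1))
  expect_error(compute_steps(t), "3 located fixes")
})
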