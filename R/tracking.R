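# Trajectory ingestion and preparation: Movebank-style CSV -> cleaned,
# hourly-regularised individual-year trajectories -> HMM observation stream.
#
# A trajectory is a data.frame with columns
#   timestamp (POSIXct UTC), lon, lat (NA for missed fixes),
#   ground_speed (m/s, NA allowed), solar_hour (fractional hours)
# and attributes individual_id / year, class "wt_trajectory".

.new_trajectory <- function(df, individual_id, year) {
  stopifnot(all(c("timestamp", "lon", "lat", "ground_speed") %in% names(df)))
  df$solar_hour <- ifelse(is.na(df$lon), NA_real_,
                          solar_hour(df$timestamp, ifelse(is.na(df$lon), 0, df$lon)))
  attr(df, "individual_id") <- individual_id
  attr(df, "year") <- year
  class(df) <- c("wt_trajectory", "data.frame")
  df
}

#' @export
print.wt_trajectory <- function(x, ...) {
  cat(sprintf("<wt_trajectory> individual %s, year %d: %d fixes (%d with location)\n",
              attr(x, "individual_id"), attr(x, "year"),
              nrow(x), sum(!is.na(x$lon))))
  invisible(x)
}

# Movebank export column names and accepted aliases
.movebank_aliases <- list(
  individual = c("individual-local-identifier", "individual_local_identifier",
                 "individual.local.identifier", "individual_id", "id"),
  timestamp  = c("timestamp", "study-local-timestamp"),
  lon        = c("location-long", "location_long", "location.long", "lon"),
  lat        = c("location-lat", "location_lat", "location.lat", "lat"),
  speed      = c("ground-speed", "ground_speed", "ground.speed", "speed")
)

.find_col <- function(nms, aliases, what, required = TRUE) {
  hit <- intersect(aliases, nms)
  if (length(hit) == 0) {
    if (required) stop("missing mandatory column for ", what,
                       " (expected one of: ", paste(aliases, collapse = ", "), ")",
                       call. = FALSE)
    return(NA_character_)
  }
  hit[1]
}

#' Read a Movebank-style GPS tracking CSV
#'
#' Reads a tracking CSV (Movebank export dialect; configurable aliases are
#' recognised for the standard headers) and returns one trajectory per
#' individual and calendar year, points sorted by timestamp. Rows whose
#' coordinates do not parse become missed fixes: the timestamp is kept, the
#' location is `NA`.
#'
#' @param path Path to the CSV file.
#' @param aliases Optional named list overriding the recognised column
#'   aliases (names `individual`, `timestamp`, `lon`, `lat`, `speed`).
#' @return A list of `wt_trajectory` objects, one per individual-year.
#' @export
read_movebank_csv <- function(path, aliases = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  al <- .movebank_aliases
  if (!is.null(aliases)) al[names(aliases)] <- aliases
  nms <- names(raw)
  c_id <- .find_col(nms, al$individual, "individual identifier")
  c_ts <- .find_col(nms, al$timestamp, "timestamp")
  c_lo <- .find_col(nms, al$lon, "longitude")
  c_la <- .find_col(nms, al$lat, "latitude")
  c_sp <- .find_col(nms, al$speed, "ground speed", required = FALSE)

  ts <- as.POSIXct(raw[[c_ts]], tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(ts)) stop("unparseable timestamps in ", path, call. = FALSE)
  df <- data.frame(
    individual_id = as.character(raw[[c_id]]),
    timestamp = ts,
    lon = suppressWarnings(as.numeric(raw[[c_lo]])),
    lat = suppressWarnings(as.numeric(raw[[c_la]])),
    ground_speed = if (is.na(c_sp)) NA_real_
                   else suppressWarnings(as.numeric(raw[[c_sp]]))
  )
  # a row missing either coordinate is a missed fix
  miss <- is.na(df$lon) | is.na(df$lat)
  df$lon[miss] <- NA_real_
  df$lat[miss] <- NA_real_
  .check_coords(df$lon, df$lat)
  if (anyDuplicated(df[c("individual_id", "timestamp")])) {
    stop("duplicate (individual, timestamp) rows in ", path, call. = FALSE)
  }
  df$year <- as.POSIXlt(df$timestamp, tz = "UTC")$year + 1900L
  out <- list()
  for (key in split(seq_len(nrow(df)),
                    interaction(df$individual_id, df$year, drop = TRUE))) {
    sub <- df[key, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    rownames(sub) <- NULL
    tr <- .new_trajectory(sub[c("timestamp", "lon", "lat", "ground_speed")],
                          sub$individual_id[1], sub$year[1])
    out[[paste(sub$individual_id[1], sub$year[1], sep = "_")]] <- tr
  }
  out[order(names(out))]
}

#' Clean a raw trajectory
#'
#' Two cleaning rules applied prior to regularisation: (i) the maximal
#' trailing run of fixes with ground speed exactly 0 m/s is removed (a tag
#' lying still at the end of a track, e.g. after death or tag loss); interior
#' zero-speed fixes are kept; (ii) each high-frequency GPS burst (consecutive
#' fixes within `burst_gap_s` seconds, from the 15-s 1 Hz recording bouts) is
#' collapsed to its first fix.
#'
#' @param t A `wt_trajectory`.
#' @param burst_gap_s Fixes closer together than this many seconds belong to
#'   the same burst. Default 20 s.
#' @return The cleaned `wt_trajectory`.
#' @export
clean_trajectory <- function(t, burst_gap_s = 20) {
  stopifnot(inherits(t, "wt_trajectory"))
  n <- nrow(t)
  if (n == 0) stop("empty trajectory", call. = FALSE)
  # (i) trailing zero-speed run
  zero <- !is.na(t$ground_speed) & t$ground_speed == 0
  keep_to <- n
  while (keep_to >= 1 && zero[keep_to]) keep_to <- keep_to - 1
  if (keep_to == 0) stop("trajectory empty after cleaning", call. = FALSE)
  t <- t[seq_len(keep_to), , drop = FALSE]
  # (ii) bursts: group consecutive fixes < burst_gap_s apart, keep first
  dt <- c(Inf, diff(as.numeric(t$timestamp)))
  grp <- cumsum(dt >= burst_gap_s)
  first <- !duplicated(grp)
  t <- t[first, , drop = FALSE]
  rownames(t) <- NULL
  t
}

#' Snap a trajectory to the hourly grid and insert missed fixes
#'
#' Fixes within `tol_s` seconds of a whole hour are snapped to that hour;
#' off-schedule fixes are dropped with a message. When two fixes snap to the
#' same hour the one nearer the grid time is kept. Every absent hour between
#' the first and last retained fix is filled with a missed fix (timestamp,
#' no location), so consecutive rows always differ by exactly one hour.
#' Idempotent.
#'
#' @param t A cleaned `wt_trajectory`.
#' @param tol_s Snap tolerance in seconds (default 300 = 5 min).
#' @return Hourly-regularised `wt_trajectory`.
#' @export
regularize_hourly <- function(t, tol_s = 300) {
  stopifnot(inherits(t, "wt_trajectory"))
  secs <- as.numeric(t$timestamp)
  grid <- round(secs / 3600) * 3600
  off <- abs(secs - grid)
  ok <- off <= tol_s
  if (any(!ok)) message(sum(!ok), " off-schedule fix(es) dropped during regularisation")
  t <- t[ok, , drop = FALSE]
  grid <- grid[ok]; off <- off[ok]
  if (nrow(t) == 0) stop("no fixes on the hourly grid", call. = FALSE)
  # resolve collisions: keep the fix nearest its grid hour
  ord <- order(grid, off)
  t <- t[ord, , drop = FALSE]; grid <- grid[ord]
  dup <- duplicated(grid)
  if (any(dup)) message(sum(dup), " fix(es) discarded (same grid hour)")
  t <- t[!dup, , drop = FALSE]; grid <- grid[!dup]
  t$timestamp <- as.POSIXct(grid, origin = "1970-01-01", tz = "UTC")
  full <- seq(grid[1], grid[length(grid)], by = 3600)
  out <- data.frame(
    timestamp = as.POSIXct(full, origin = "1970-01-01", tz = "UTC"),
    lon = NA_real_, lat = NA_real_, ground_speed = NA_real_
  )
  idx <- match(grid, full)
  out$lon[idx] <- t$lon
  out$lat[idx] <- t$lat
  out$ground_speed[idx] <- t$ground_speed
  .new_trajectory(out, attr(t, "individual_id"), attr(t, "year"))
}

#' Derive the HMM observation stream from a regularised trajectory
#'
#' Step i spans fixes i -> i+1: `sqrt_step` is the square root of the
#' geodesic step length in km; `turn_angle` (radians, in (-pi, pi], exact
#' reversals mapped to +pi) is the signed change of initial geodesic bearing
#' between step i-1 and step i, so it is `NA` for the first interval and
#' whenever a flanking step is missing or has zero length. `solar_hour` is
#' the mean solar hour at the interval's starting fix (the state-transition
#' covariate); for missed fixes it is carried from the timestamp at the
#' trajectory's median longitude.
#'
#' @param t A regularised `wt_trajectory` with at least 3 located fixes.
#' @return A data.frame (`wt_steps`) with columns `sqrt_step`, `turn_angle`,
#'   `solar_hour`, plus the interval start `timestamp`.
#' @export
compute_steps <- function(t) {
  stopifnot(inherits(t, "wt_trajectory"))
  if (sum(!is.na(t$lon)) < 3) stop("need at least 3 located fixes", call. = FALSE)
  n <- nrow(t)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  have <- !is.na(t$lon[i1]) & !is.na(t$lon[i2])
  step_km <- rep(NA_real_, n - 1)
  bear <- rep(NA_real_, n - 1)
  if (any(have)) {
    step_km[have] <- geodesic_km(t$lon[i1][have], t$lat[i1][have],
                                 t$lon[i2][have], t$lat[i2][have])
    bear[have] <- initial_bearing(t$lon[i1][have], t$lat[i1][have],
                                  t$lon[i2][have], t$lat[i2][have])
  }
  turn <- rep(NA_real_, n - 1)
  if (n >= 3) {
    j <- 2:(n - 1)
    ok <- !is.na(bear[j]) & !is.na(bear[j - 1])  # zero steps have NA bearing
    d <- (bear[j] - bear[j - 1])[ok]
    d <- ((d + pi) %% (2 * pi)) - pi   # wrap to [-pi, pi)
    d[d == -pi] <- pi                  # reversal convention: +pi
    turn[j][ok] <- d
  }
  ref_lon <- stats::median(t$lon, na.rm = TRUE)
  sh <- solar_hour(t$timestamp[i1], ref_lon)
  out <- data.frame(
    timestamp = t$timestamp[i1],
    sqrt_step = sqrt(step_km),
    turn_angle = turn,
    solar_hour = sh
  )
  class(out) <- c("wt_steps", "data.frame")
  out
}

#' Write a regularised trajectory to CSV
#'
#' One row per hour; missed fixes have blank coordinates.
#' @param t A `wt_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(t, path) {
  df <- as.data.frame(t)
  df$individual_id <- attr(t, "individual_id")
  df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
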