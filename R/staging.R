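# Migration windows, staging-site segmentation and arrival events.
#
# The threshold distance d_t is the distance a slow migratory wigeon
# (mean airspeed minus two standard deviations) covers in one hour of
# still-air flight; it separates "same staging site" from "moved on" and
# detects departure from / arrival at the migration endpoints.

#' Threshold distance from airspeed estimates
#'
#' `d_t = (mean - 2*sd) * 3600` metres, returned in km: the distance a bird
#' flying at two standard deviations below the mean airspeed covers in one
#' hour without wind. With the published wigeon airspeed estimates the
#' effective speed is 13.94 m/s, giving 50.184 km.
#'
#' @param airspeed_mean Mean airspeed, m/s.
#' @param airspeed_sd Airspeed standard deviation, m/s; must satisfy
#'   `airspeed_mean > 2 * airspeed_sd`.
#' @return Threshold distance in km.
#' @examples
#' threshold_distance(13.94, 0)  # 50.184
#' @export
threshold_distance <- function(airspeed_mean, airspeed_sd) {
  eff <- airspeed_mean - 2 * airspeed_sd
  if (any(eff <= 0)) stop("effective airspeed (mean - 2 sd) must be positive",
                          call. = FALSE)
  eff * 3600 / 1000
}

#' Seasonal endpoints of a spring trajectory
#'
#' The starting location is the "south-westernmost" point used during
#' February-April and the end location the "north-easternmost" point reached
#' during May-July, both operationalised as the minimum / maximum coordinate
#' along the corridor axis of the two-point equidistant projection. Ties are
#' broken toward the earlier timestamp.
#'
#' @param t A `wt_trajectory`.
#' @param anchors Projection anchors, see [project_two_point()].
#' @return List with `start` and `end`, each a list
#'   (`lon`, `lat`, `timestamp`, `x`).
#' @export
find_endpoints <- function(t, anchors = default_anchors()) {
  stopifnot(inherits(t, "wt_trajectory"))
  ok <- !is.na(t$lon)
  mon <- as.POSIXlt(t$timestamp, tz = "UTC")$mon + 1L
  early <- ok & mon %in% 2:4
  late <- ok & mon %in% 5:7
  if (!any(early)) stop("no located fixes in February-April", call. = FALSE)
  if (!any(late)) stop("no located fixes in May-July", call. = FALSE)
  px <- rep(NA_real_, nrow(t))
  px[ok] <- project_two_point(t$lon[ok], t$lat[ok], anchors)$x
  pick <- function(idx, which_fun) {
    xt <- px[idx]
    extreme <- which_fun(xt)
    cand <- which(idx)[xt == extreme]
    i <- cand[which.min(as.numeric(t$timestamp[cand]))]
    list(lon = t$lon[i], lat = t$lat[i], timestamp = t$timestamp[i], x = px[i])
  }
  list(start = pick(early, min), end = pick(late, max))
}

#' Determine the migration window
#'
#' Start of migration: the last instant the individual is within `d_t` of
#' the starting location before leaving for good (never again within `d_t`
#' of the start until reaching the end). End of migration: the first instant
#' the individual is observed within `d_t` of the end location.
#'
#' @param t A `wt_trajectory`.
#' @param start,end Endpoint locations (lists with `lon`, `lat`), e.g. from
#'   [find_endpoints()].
#' @param d_t Threshold distance, km.
#' @return A list (`start_time`, `end_time`) of POSIXct instants, or `NULL`
#'   if the individual never moves beyond `d_t` of the start (no migration).
#' @export
migration_window <- function(t, start, end, d_t) {
  stopifnot(inherits(t, "wt_trajectory"))
  ok <- which(!is.na(t$lon))
  if (length(ok) == 0) return(NULL)
  d_start <- geodesic_km(start$lon, start$lat, t$lon[ok], t$lat[ok])
  d_end <- geodesic_km(end$lon, end$lat, t$lon[ok], t$lat[ok])
  if (all(d_start <= d_t)) return(NULL)  # never departs
  i_end <- which(d_end <= d_t)[1]
  if (is.na(i_end)) i_end <- length(ok)  # end never reached: use last fix
  before <- which(d_start <= d_t & seq_along(ok) <= i_end)
  if (length(before) == 0) {
    # never seen near the start: migration begins at the first fix
    start_time <- t$timestamp[ok[1]]
  } else {
    start_time <- t$timestamp[ok[max(before)]]
  }
  end_time <- t$timestamp[ok[i_end]]
  if (start_time >= end_time) return(NULL)
  list(start_time = start_time, end_time = end_time)
}

#' Segment non-migratory locations into staging sites
#'
#' Sequential scan over the temporally ordered non-migratory locations
#' (migratory-flight fixes and missed fixes removed): whenever the geodesic
#' distance between consecutive retained locations exceeds `d_t`, a new
#' staging site is opened. Site centroid is the arithmetic mean of member
#' coordinates; arrival date is the UTC calendar date of the first member
#' fix, departure date that of the last.
#'
#' @param points data.frame with `timestamp`, `lon`, `lat` (rows with `NA`
#'   coordinates are ignored), ordered by time.
#' @param d_t Threshold distance, km.
#' @return data.frame (`wt_staging_sites`): `site_id`, `centroid_lon`,
#'   `centroid_lat`, `arrival_date`, `departure_date`, `n_points`,
#'   `first_lon`, `first_lat`.
#' @export
segment_staging_sites <- function(points, d_t) {
  pts <- points[!is.na(points$lon) & !is.na(points$lat), , drop = FALSE]
  if (nrow(pts) == 0) stop("no located non-migratory points to segment",
                           call. = FALSE)
  n <- nrow(pts)
  gap <- rep(FALSE, n)
  if (n > 1) {
    i1 <- seq_len(n - 1)
    d <- geodesic_km(pts$lon[i1], pts$lat[i1], pts$lon[i1 + 1], pts$lat[i1 + 1])
    gap[-1] <- d > d_t
  }
  site <- cumsum(gap) + 1L
  agg <- lapply(split(seq_len(n), site), function(ix) {
    data.frame(
      centroid_lon = mean(pts$lon[ix]),
      centroid_lat = mean(pts$lat[ix]),
      arrival_date = as.Date(as.POSIXlt(pts$timestamp[ix[1]], tz = "UTC")),
      departure_date = as.Date(as.POSIXlt(pts$timestamp[ix[length(ix)]], tz = "UTC")),
      n_points = length(ix),
      first_lon = pts$lon[ix[1]],
      first_lat = pts$lat[ix[1]]
    )
  })
  out <- do.call(rbind, agg)
  out <- cbind(site_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("wt_staging_sites", "data.frame")
  out
}

#' Extract arrival events from staging sites
#'
#' An arrival event is the first day of observations at a staging site.
#' Sites within `d_t` of the starting location and sites first reached after
#' the cutoff date (June 30 by default; the cutoff day itself is kept) are
#' excluded. The cumulative geodesic distance is accumulated along surviving
#' events, starting at the start location.
#'
#' @param sites `wt_staging_sites` (ordered by arrival date).
#' @param start Start location (list with `lon`, `lat`).
#' @param d_t Threshold distance, km.
#' @param cutoff Cutoff `Date`; events strictly after it are dropped. If
#'   `NULL`, June 30 of each event's year.
#' @param anchors Projection anchors for the projected event coordinates.
#' @return data.frame (`wt_arrival_events`): `site_id`, `arrival_date`,
#'   `arrival_doy`, `lon`, `lat`, `proj_x`, `proj_y`, `cum_distance_km`.
#' @export
extract_arrival_events <- function(sites, start, d_t, cutoff = NULL,
                                   anchors = default_anchors()) {
  stopifnot(inherits(sites, "data.frame"))
  if (nrow(sites) == 0) return(.empty_events())
  d0 <- geodesic_km(start$lon, start$lat, sites$centroid_lon, sites$centroid_lat)
  yr <- as.integer(format(sites$arrival_date, "%Y"))
  cut <- if (is.null(cutoff)) as.Date(sprintf("%d-06-30", yr)) else rep(cutoff, nrow(sites))
  keep <- d0 > d_t & sites$arrival_date <= cut
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0) return(.empty_events())
  sites <- sites[order(sites$arrival_date), , drop = FALSE]
  lons <- c(start$lon, sites$centroid_lon)
  lats <- c(start$lat, sites$centroid_lat)
  legs <- geodesic_km(lons[-length(lons)], lats[-length(lats)],
                      lons[-1], lats[-1])
  pr <- project_two_point(sites$centroid_lon, sites$centroid_lat, anchors)
  out <- data.frame(
    site_id = sites$site_id,
    arrival_date = sites$arrival_date,
    arrival_doy = as.integer(format(sites$arrival_date, "%j")),
    lon = sites$centroid_lon, lat = sites$centroid_lat,
    proj_x = pr$x, proj_y = pr$y,
    cum_distance_km = cumsum(legs)
  )
  class(out) <- c("wt_arrival_events", "data.frame")
  out
}

.empty_events <- function() {
  out <- data.frame(site_id = integer(0), arrival_date = as.Date(character(0)),
                    arrival_doy = integer(0), lon = numeric(0), lat = numeric(0),
                    proj_x = numeric(0), proj_y = numeric(0),
                    cum_distance_km = numeric(0))
  class(out) <- c("wt_arrival_events", "data.frame")
  out
}

#' Remove migratory locations from a decoded trajectory
#'
#' Drops fixes decoded as migratory flight before staging-site segmentation.
#' By default only state 4 (migratory flight) is removed; set
#' `remove_states = 3:4` to also drop local flight.
#'
#' @param t A `wt_trajectory`.
#' @param states Decoded states per interval (length `nrow(t) - 1`); the
#'   state of interval i is attributed to fix i.
#' @param remove_states States to drop (default 4).
#' @return data.frame of retained fixes (`timestamp`, `lon`, `lat`).
#' @export
drop_migratory <- function(t, states, remove_states = 4L) {
  stopifnot(inherits(t, "wt_trajectory"), length(states) == nrow(t) - 1)
  fix_state <- c(states, states[length(states)])  # last fix inherits last interval
  keep <- !(fix_state %in% remove_states)
  data.frame(timestamp = t$timestamp[keep], lon = t$lon[keep], lat = t$lat[keep])
}
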