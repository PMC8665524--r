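# Geodesy primitives shared by every downstream module: WGS84 geodesics
# (Vincenty), the two-point equidistant projection used to define the
# migration-corridor axis, and mean solar time.

WGS84_A <- 6378137.0          # semi-major axis [m]
WGS84_F <- 1 / 298.257223563  # flattening
WGS84_B <- WGS84_A * (1 - WGS84_F)
EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius, spherical fallback

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_coords <- function(lon, lat) {
  bad <- !is.na(lon) & !is.na(lat) &
    (lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (any(bad)) {
    stop("coordinates out of range: lon must lie in [-180, 180], lat in [-90, 90]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Geodesic distance between points
#'
#' Distance between pairs of longitude/latitude points, in kilometres.
#' The default reference surface is the WGS84 ellipsoid (Vincenty's inverse
#' formula); `method = "sphere"` uses the haversine great-circle distance on a
#' sphere of radius 6371.0088 km, which admits closed-form expected values.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84,
#'   longitude east, latitude north). Vectors are recycled pairwise.
#' @param method `"ellipsoid"` (default) or `"sphere"`.
#' @return Numeric vector of distances in km. Symmetric, non-negative, and
#'   zero exactly when the two points coincide.
#' @examples
#' geodesic_km(4.9, 52.5, 21.3, 55.3)        # Netherlands -> Nemunas delta
#' geodesic_km(0, 0, 1, 0, method = "sphere") # 111.195 km
#' @export
geodesic_km <- function(lon1, lat1, lon2, lat2,
                        method = c("ellipsoid", "sphere")) {
  method <- match.arg(method)
  .check_coords(lon1, lat1)
  .check_coords(lon2, lat2)
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  lon1 <- rep_len(lon1, n); lat1 <- rep_len(lat1, n)
  lon2 <- rep_len(lon2, n); lat2 <- rep_len(lat2, n)
  if (method == "sphere") {
    p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
    dphi <- p2 - p1
    dlam <- .deg2rad(lon2 - lon1)
    h <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
    return(2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h))))
  }
  .vincenty_inverse(lon1, lat1, lon2, lat2)$distance_m / 1000
}

# Vectorised Vincenty inverse: distance [m] and initial bearing [rad, from
# north, clockwise]. Non-convergent (near-antipodal) pairs fall back to the
# spherical great-circle value; the study corridor (0-80E, 45-75N) never
# triggers this.
.vincenty_inverse <- function(lon1, lat1, lon2, lat2) {
  n <- length(lon1)
  L <- .deg2rad(lon2 - lon1)
  U1 <- atan((1 - WGS84_F) * tan(.deg2rad(lat1)))
  U2 <- atan((1 - WGS84_F) * tan(.deg2rad(lat2)))
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)

  lambda <- L
  active <- rep(TRUE, n)
  sinSigma <- cosSigma <- sigma <- numeric(n)
  cosSqAlpha <- rep(1, n)
  cos2SigmaM <- numeric(n)
  for (iter in seq_len(200)) {
    if (!any(active)) break
    sinL <- sin(lambda[active]); cosL <- cos(lambda[active])
    sS <- sqrt((cosU2[active] * sinL)^2 +
                 (cosU1[active] * sinU2[active] -
                    sinU1[active] * cosU2[active] * cosL)^2)
    cS <- sinU1[active] * sinU2[active] +
      cosU1[active] * cosU2[active] * cosL
    sg <- atan2(sS, cS)
    sinAlpha <- ifelse(sS == 0, 0,
                       cosU1[active] * cosU2[active] * sinL / sS)
    c2a <- 1 - sinAlpha^2
    c2sm <- ifelse(c2a == 0, 0,
                   cS - 2 * sinU1[active] * sinU2[active] / pmax(c2a, .Machine$double.eps))
    C <- WGS84_F / 16 * c2a * (4 + WGS84_F * (4 - 3 * c2a))
    lamNew <- L[active] + (1 - C) * WGS84_F * sinAlpha *
      (sg + C * sS * (c2sm + C * cS * (-1 + 2 * c2sm^2)))
    conv <- abs(lamNew - lambda[active]) < 1e-12 | sS == 0
    sinSigma[active] <- sS; cosSigma[active] <- cS; sigma[active] <- sg
    cosSqAlpha[active] <- c2a; cos2SigmaM[active] <- c2sm
    lambda[active] <- lamNew
    idx <- which(active)
    active[idx[conv]] <- FALSE
  }
  if (any(active)) {
    # near-antipodal: spherical fallback for those pairs
    warning("Vincenty did not converge for ", sum(active),
            " near-antipodal pair(s); using spherical distance there")
    sph <- geodesic_km(lon1[active], lat1[active],
                       lon2[active], lat2[active], method = "sphere") * 1000
  }
  uSq <- cosSqAlpha * (WGS84_A^2 - WGS84_B^2) / WGS84_B^2
  A <- 1 + uSq / 16384 * (4096 + uSq * (-768 + uSq * (320 - 175 * uSq)))
  B <- uSq / 1024 * (256 + uSq * (-128 + uSq * (74 - 47 * uSq)))
  deltaSigma <- B * sinSigma *
    (cos2SigmaM + B / 4 * (cosSigma * (-1 + 2 * cos2SigmaM^2) -
       B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) * (-3 + 4 * cos2SigmaM^2)))
  dist <- WGS84_B * A * (sigma - deltaSigma)
  if (any(active)) dist[active] <- sph
  bearing <- atan2(cosU2 * sin(lambda),
                   cosU1 * sinU2 - sinU1 * cosU2 * cos(lambda))
  coincident <- lon1 == lon2 & lat1 == lat2
  dist[coincident] <- 0
  bearing[coincident] <- NA_real_
  list(distance_m = dist, bearing_rad = bearing %% (2 * pi))
}

#' Initial bearing of the geodesic from point 1 to point 2
#'
#' Radians clockwise from true north, in `[0, 2*pi)`; `NA` for coincident
#' points. Used to derive turning angles on the ellipsoid.
#' @inheritParams geodesic_km
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  .check_coords(lon1, lat1)
  .check_coords(lon2, lat2)
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  .vincenty_inverse(rep_len(lon1, n), rep_len(lat1, n),
                    rep_len(lon2, n), rep_len(lat2, n))$bearing_rad
}

#' Destination point of a geodesic (Vincenty direct)
#'
#' Moves `distance_km` from (`lon`, `lat`) along initial bearing
#' `bearing_rad` on the WGS84 ellipsoid. Used by the trajectory simulator to
#' construct migration legs.
#'
#' @param lon,lat Start coordinates, decimal degrees.
#' @param bearing_rad Initial bearing, radians clockwise from north.
#' @param distance_km Distance to travel, km.
#' @return A list with components `lon` and `lat` (degrees).
#' @export
geodesic_destination <- function(lon, lat, bearing_rad, distance_km) {
  .check_coords(lon, lat)
  s <- distance_km * 1000
  alpha1 <- bearing_rad
  U1 <- atan((1 - WGS84_F) * tan(.deg2rad(lat)))
  sigma1 <- atan2(tan(U1), cos(alpha1))
  sinAlpha <- cos(U1) * sin(alpha1)
  cosSqAlpha <- 1 - sinAlpha^2
  uSq <- cosSqAlpha * (WGS84_A^2 - WGS84_B^2) / WGS84_B^2
  A <- 1 + uSq / 16384 * (4096 + uSq * (-768 + uSq * (320 - 175 * uSq)))
  B <- uSq / 1024 * (256 + uSq * (-128 + uSq * (74 - 47 * uSq)))
  sigma <- s / (WGS84_B * A)
  for (i in seq_len(200)) {
    cos2SigmaM <- cos(2 * sigma1 + sigma)
    sinSigma <- sin(sigma); cosSigma <- cos(sigma)
    deltaSigma <- B * sinSigma *
      (cos2SigmaM + B / 4 * (cosSigma * (-1 + 2 * cos2SigmaM^2) -
         B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) * (-3 + 4 * cos2SigmaM^2)))
    sigmaNew <- s / (WGS84_B * A) + deltaSigma
    if (all(abs(sigmaNew - sigma) < 1e-12)) { sigma <- sigmaNew; break }
    sigma <- sigmaNew
  }
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinSigma <- sin(sigma); cosSigma <- cos(sigma)
  cos2SigmaM <- cos(2 * sigma1 + sigma)
  tmp <- sinU1 * sinSigma - cosU1 * cosSigma * cos(alpha1)
  lat2 <- atan2(sinU1 * cosSigma + cosU1 * sinSigma * cos(alpha1),
                (1 - WGS84_F) * sqrt(sinAlpha^2 + tmp^2))
  lambda <- atan2(sinSigma * sin(alpha1),
                  cosU1 * cosSigma - sinU1 * sinSigma * cos(alpha1))
  C <- WGS84_F / 16 * cosSqAlpha * (4 + WGS84_F * (4 - 3 * cosSqAlpha))
  L <- lambda - (1 - C) * WGS84_F * sinAlpha *
    (sigma + C * sinSigma * (cos2SigmaM + C * cosSigma * (-1 + 2 * cos2SigmaM^2)))
  lon2 <- .deg2rad(lon) + L
  list(lon = ((.rad2deg(lon2) + 540) %% 360) - 180, lat = .rad2deg(lat2))
}

#' Default projection anchors: the two capture sites
#'
#' Krommeniedijk (Netherlands) and the Nemunas delta (Lithuania), the anchors
#' of the corridor-axis projection. Override for other flyways.
#' @return A list of two lists, each with `lon` and `lat`.
#' @export
default_anchors <- function() {
  list(list(lon = 4.77, lat = 52.49), list(lon = 21.3, lat = 55.3))
}

#' Two-point equidistant projection
#'
#' Projects longitude/latitude points to planar km coordinates such that the
#' planar distance from every projected point to each projected anchor equals
#' the geodesic distance from the geographic point to that anchor (the
#' defining property of the two-point equidistant projection). Anchor 1 maps
#' to (0, 0) and anchor 2 to (d, 0) where d is the anchor separation, so the
#' x axis ("longitude" of the projection) runs along the migration corridor.
#'
#' @param lon,lat Coordinates to project, decimal degrees.
#' @param anchors List of two anchor points (each a list with `lon`, `lat`);
#'   defaults to [default_anchors()]. Must be distinct and not antipodal.
#' @return A data.frame with columns `x` and `y` in km.
#' @export
project_two_point <- function(lon, lat, anchors = default_anchors()) {
  stopifnot(length(anchors) == 2)
  a <- anchors[[1]]; b <- anchors[[2]]
  .check_coords(a$lon, a$lat); .check_coords(b$lon, b$lat)
  d_sph <- geodesic_km(a$lon, a$lat, b$lon, b$lat, method = "sphere")
  if (d_sph < 1e-9) stop("projection anchors are coincident", call. = FALSE)
  anti <- geodesic_km(a$lon, a$lat,
                      ifelse(b$lon > 0, b$lon - 180, b$lon + 180), -b$lat,
                      method = "sphere")
  if (anti < 1) stop("projection anchors are antipodal", call. = FALSE)
  d <- geodesic_km(a$lon, a$lat, b$lon, b$lat)
  .check_coords(lon, lat)
  rA <- geodesic_km(a$lon, a$lat, lon, lat)
  rB <- geodesic_km(b$lon, b$lat, lon, lat)
  x <- (rA^2 - rB^2 + d^2) / (2 * d)
  y2 <- pmax(rA^2 - x^2, 0)
  # side of the anchor great circle via the spherical triple product
  side <- .gc_side(a, b, lon, lat)
  data.frame(x = x, y = sqrt(y2) * side)
}

.unit_ecef <- function(lon, lat) {
  lam <- .deg2rad(lon); phi <- .deg2rad(lat)
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.gc_side <- function(a, b, lon, lat) {
  va <- .unit_ecef(a$lon, a$lat)[1, ]
  vb <- .unit_ecef(b$lon, b$lat)[1, ]
  nrm <- c(va[2] * vb[3] - va[3] * vb[2],
           va[3] * vb[1] - va[1] * vb[3],
           va[1] * vb[2] - va[2] * vb[1])
  p <- .unit_ecef(lon, lat)
  s <- sign(p %*% nrm)
  s[s == 0] <- 1
  as.numeric(s)
}

#' Mean solar time in fractional hours
#'
#' Mean solar time at a longitude: UTC clock time shifted by 4 minutes per
#' degree east (1 h per 15 degrees), modulo 24. Hours are counted from solar
#' midnight. No equation-of-time correction is applied by default; set
#' `apparent = TRUE` for apparent solar time (adds the equation of time,
#' about +/- 15 min over the year).
#'
#' @param timestamp POSIXct, UTC.
#' @param lon Longitude, decimal degrees east.
#' @param apparent Apply the equation-of-time correction? Default `FALSE`.
#' @return Fractional hours in `[0, 24)`.
#' @export
solar_hour <- function(timestamp, lon, apparent = FALSE) {
  stopifnot(inherits(timestamp, "POSIXct"))
  .check_coords(lon, rep(0, length(lon)))
  tt <- as.POSIXlt(timestamp, tz = "UTC")
  utc_h <- tt$hour + tt$min / 60 + tt$sec / 3600
  h <- utc_h + lon / 15
  if (apparent) {
    doy <- tt$yday + 1
    bang <- 2 * pi * (doy - 81) / 364
    eot_min <- 9.87 * sin(2 * bang) - 7.53 * cos(bang) - 1.5 * sin(bang)
    h <- h + eot_min / 60
  }
  h %% 24
}
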