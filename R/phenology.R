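# Thermal-growing-season phenology from hourly gridded 2-m temperature.
#
# No NetCDF reader is available in the supported dependency set, so the
# hourly grid travels as a long-format CSV (time, lon, lat, t2m) or is built
# in memory; the container below mirrors an (time, lat, lon) array.

#' Construct an hourly temperature grid
#'
#' @param lon,lat Cell-centre coordinate vectors (degrees), strictly
#'   increasing.
#' @param time POSIXct UTC vector of hourly instants.
#' @param temp Array `[time, lat, lon]` of 2-m air temperature. Values are
#'   auto-detected as Kelvin when the median exceeds 100 and converted to
#'   Celsius (with a message).
#' @return `wt_temp_grid` object.
#' @export
temperature_grid <- function(lon, lat, time, temp) {
  stopifnot(inherits(time, "POSIXct"),
            identical(dim(temp), c(length(time), length(lat), length(lon))))
  if (stats::median(temp, na.rm = TRUE) > 100) {
    message("temperature values look like Kelvin; converting to Celsius")
    temp <- temp - 273.15
  }
  structure(list(lon = lon, lat = lat, time = time, temp = temp),
            class = "wt_temp_grid")
}

#' Read an hourly temperature grid from long-format CSV
#'
#' Columns: `time` (ISO-8601 UTC), `lon`, `lat`, `t2m`.
#' @param path CSV path.
#' @return `wt_temp_grid`.
#' @export
read_temperature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "lon", "lat", "t2m") %in% names(df)))
  tt <- as.POSIXct(df$time, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS"))
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  time <- sort(unique(tt))
  arr <- array(NA_real_, c(length(time), length(lat), length(lon)))
  arr[cbind(match(tt, time), match(df$lat, lat), match(df$lon, lon))] <- df$t2m
  temperature_grid(lon, lat, time, arr)
}

#' Write an hourly temperature grid to long-format CSV
#' @param g `wt_temp_grid`.
#' @param path Output path.
#' @export
write_temperature_csv <- function(g, path) {
  idx <- which(!is.na(g$temp), arr.ind = TRUE)
  df <- data.frame(time = format(g$time[idx[, 1]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   lon = g$lon[idx[, 3]], lat = g$lat[idx[, 2]],
                   t2m = g$temp[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Daily mean temperature per grid cell
#'
#' Arithmetic mean over the UTC day; days with fewer than `min_hours` of the
#' 24 hours present are flagged missing.
#'
#' @param g `wt_temp_grid`.
#' @param min_hours Minimum hourly coverage per day (default 20).
#' @return `wt_daily_grid`: list with `lon`, `lat`, `date` (Date vector) and
#'   `tmean` array `[day, lat, lon]` in deg C.
#' @export
daily_mean_temperature <- function(g, min_hours = 20) {
  stopifnot(inherits(g, "wt_temp_grid"))
  day <- as.Date(as.POSIXlt(g$time, tz = "UTC"))
  days <- sort(unique(day))
  di <- match(day, days)
  nd <- length(days); nlat <- length(g$lat); nlon <- length(g$lon)
  tmean <- array(NA_real_, c(nd, nlat, nlon))
  for (jl in seq_len(nlon)) for (jb in seq_len(nlat)) {
    v <- g$temp[, jb, jl]
    cnt <- tapply(!is.na(v), di, sum)
    mu <- tapply(v, di, mean, na.rm = TRUE)
    mu[cnt < min_hours] <- NA_real_
    tmean[as.integer(names(mu)), jb, jl] <- mu
  }
  structure(list(lon = g$lon, lat = g$lat, date = days, tmean = tmean),
            class = "wt_daily_grid")
}

#' Thermal growing season onset for one year of daily means
#'
#' Default rule (`"degree_day_minimum"`): the onset is the day after the
#' within-year minimum of the cumulative sum of `(t_mean - t_ref)` (with the
#' pre-season empty sum 0 as a candidate, so a year that is warm from day 1
#' has onset 1). This is the robust degree-day balance criterion: before the
#' onset the balance is falling, after it it rises for good. Alternative
#' rule (`"persistence"`): the first day of at least `persist_days`
#' consecutive days with `t_mean > t_ref`. Both rules return `NA` when the
#' daily mean never exceeds `t_ref` or when the season never turns.
#'
#' @param tmean Numeric vector of daily mean temperatures (deg C) for one
#'   calendar year (365/366 values; `NA` allowed for missing days).
#' @param t_ref Reference temperature, deg C (default 5).
#' @param rule `"degree_day_minimum"` (default) or `"persistence"`.
#' @param persist_days Run length for the persistence rule (default 5).
#' @return Onset day of year (integer) or `NA`.
#' @export
tgs_onset <- function(tmean, t_ref = 5,
                      rule = c("degree_day_minimum", "persistence"),
                      persist_days = 5) {
  rule <- match.arg(rule)
  nd <- length(tmean)
  if (all(is.na(tmean)) || max(tmean, na.rm = TRUE) <= t_ref) return(NA_integer_)
  has_na <- anyNA(tmean)
  if (rule == "degree_day_minimum") {
    x <- tmean
    x[is.na(x)] <- t_ref  # neutral fill; flagged below if near the onset
    s <- c(0, cumsum(x - t_ref))   # s[d + 1] = balance after day d
    m <- which.min(s)              # earliest minimum
    onset <- m                     # day after the minimum (s index offset)
    if (onset > nd) return(NA_integer_)  # balance still falling at year end
  } else {
    above <- !is.na(tmean) & tmean > t_ref
    r <- rle(above)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= persist_days)
    if (length(hit) == 0) return(NA_integer_)
    onset <- ends[hit[1]] - r$lengths[hit[1]] + 1
  }
  if (has_na && any(is.na(tmean[max(1, onset - 3):min(nd, onset + 3)]))) {
    warning("missing days span the candidate onset; onset undefined")
    return(NA_integer_)
  }
  as.integer(onset)
}

#' Mean onset over the climatology window
#'
#' Arithmetic mean of the defined yearly onsets (years with undefined onset
#' are skipped).
#' @param onsets Numeric vector of yearly onset DOYs (`NA` allowed).
#' @return Mean onset DOY.
#' @export
tgs_climatology <- function(onsets) {
  if (all(is.na(onsets))) stop("no defined onsets in climatology window",
                               call. = FALSE)
  mean(onsets, na.rm = TRUE)
}

#' Deviation of a year's onset from the climatological mean
#'
#' Positive values mean the growing season started later than average.
#' @param onset_year Onset DOY of the focal year.
#' @param tgs_mean Climatological mean onset DOY.
#' @return Signed deviation in days.
#' @export
tgs_deviation <- function(onset_year, tgs_mean) {
  if (anyNA(onset_year) || anyNA(tgs_mean)) {
    stop("tgs_deviation requires defined onset and climatology", call. = FALSE)
  }
  onset_year - tgs_mean
}

#' Growing degree days over a day-of-year window
#'
#' Sum of `max(0, t_mean - t_ref)` over days `from .. to - 1` (half-open
#' window `[from, to)`), so `from == to` gives 0.
#'
#' @param tmean Daily mean temperature vector (deg C), indexed by DOY.
#' @param t_ref Reference temperature (default 5).
#' @param from,to Day-of-year window bounds, `from <= to`.
#' @return Accumulated degree days, or `NA` (with a warning) if the window
#'   contains missing days.
#' @export
growing_degree_days <- function(tmean, t_ref = 5, from = 1,
                                to = length(tmean) + 1) {
  stopifnot(from <= to, from >= 1, to <= length(tmean) + 1)
  if (from == to) return(0)
  x <- tmean[from:(to - 1)]
  if (anyNA(x)) {
    warning("missing days in GDD window")
    return(NA_real_)
  }
  sum(pmax(0, x - t_ref))
}

#' Per-cell phenology summaries for a multi-year daily grid
#'
#' Computes the yearly TGS onset per cell, the climatological mean over
#' `clim_years`, and the deviation per year.
#'
#' @param daily `wt_daily_grid` spanning one or more calendar years.
#' @param clim_years Years entering the climatological mean (default: all
#'   years present).
#' @param t_ref,rule,persist_days Passed to [tgs_onset()].
#' @return `wt_phenology`: list with `lon`, `lat`, `years`,
#'   `onset[year, lat, lon]`, `tgs_mean[lat, lon]`,
#'   `deviation[year, lat, lon]`, and the daily grid (for GDD lookups).
#' @export
phenology_grid <- function(daily, clim_years = NULL, t_ref = 5,
                           rule = "degree_day_minimum", persist_days = 5) {
  stopifnot(inherits(daily, "wt_daily_grid"))
  yr <- as.integer(format(daily$date, "%Y"))
  years <- sort(unique(yr))
  if (is.null(clim_years)) clim_years <- years
  nlat <- length(daily$lat); nlon <- length(daily$lon)
  onset <- array(NA_real_, c(length(years), nlat, nlon))
  for (k in seq_along(years)) {
    ix <- which(yr == years[k])
    for (jl in seq_len(nlon)) for (jb in seq_len(nlat)) {
      onset[k, jb, jl] <- suppressWarnings(
        tgs_onset(daily$tmean[ix, jb, jl], t_ref = t_ref, rule = rule,
                  persist_days = persist_days))
    }
  }
  ck <- years %in% clim_years
  tgs_mean <- apply(onset[ck, , , drop = FALSE], c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  deviation <- sweep(onset, c(2, 3), tgs_mean, "-")
  structure(list(lon = daily$lon, lat = daily$lat, years = years,
                 onset = onset, tgs_mean = tgs_mean, deviation = deviation,
                 daily = daily, t_ref = t_ref),
            class = "wt_phenology")
}

#' Nearest grid cell to a point
#'
#' Nearest cell centre by great-circle distance; ties resolved toward the
#' lower cell index (latitude index first, then longitude).
#' @param grid Object with `lon` and `lat` cell-centre vectors.
#' @param lon,lat Query point (degrees).
#' @return List with `lon_idx`, `lat_idx`.
#' @export
nearest_cell <- function(grid, lon, lat) {
  cells <- expand.grid(lat_idx = seq_along(grid$lat),
                       lon_idx = seq_along(grid$lon))
  d <- geodesic_km(lon, lat, grid$lon[cells$lon_idx], grid$lat[cells$lat_idx],
                   method = "sphere")
  i <- which(d == min(d))[1]
  list(lon_idx = cells$lon_idx[i], lat_idx = cells$lat_idx[i])
}
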