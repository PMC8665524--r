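# Ring-recovery passage timing in 10-degree longitudinal bands, and the
# model for the delay of tagged birds relative to ring-marked birds.
#
# Bands use *geographic* longitude (half-open [lo, lo + 10) degrees east,
# lo in 0, 10, ..., 70), unlike the projected corridor "longitude" of the
# arrival model; this distinction is deliberate and logged in both places.

#' Band lower edge for a longitude
#'
#' Half-open assignment: lon 19.999 is in band 10, lon 20.0 in band 20.
#' Longitudes outside `[min(bands), max(bands) + width)` return `NA`.
#' @param lon Longitude, degrees east.
#' @param bands Vector of band lower edges (default `seq(0, 70, 10)`).
#' @param width Band width in degrees (default 10).
#' @return Band lower edge or `NA`.
#' @export
band_of <- function(lon, bands = seq(0, 70, by = 10), width = 10) {
  b <- bands[findInterval(lon, c(bands, max(bands) + width),
                          rightmost.closed = FALSE)]
  b[lon < min(bands) | lon >= max(bands) + width] <- NA
  b
}

#' Mean passage date of ring recoveries per scheme and band
#'
#' Restricts recoveries to the spring window and computes mean, sd and count
#' of the recovery day of year per ringing scheme and longitudinal band.
#' Empty scheme-band combinations are absent from the output (undefined).
#'
#' @param recoveries data.frame with columns `scheme`, `date` (Date or
#'   ISO-8601 string), `lon`; optionally `event_type` (rows with
#'   `event_type == "control"` are kept only when `include_controls`).
#' @param spring_window Length-2 integer DOY window (inclusive); default
#'   Feb 1 - Jun 30, i.e. `c(32, 181)`.
#' @param bands Band lower edges.
#' @param include_controls Include spring-marked control points? Default
#'   `FALSE`.
#' @return data.frame (`wt_band_summary`): `scheme`, `band`, `mean_doy`,
#'   `sd_doy`, `n`.
#' @export
band_passage_summary <- function(recoveries, spring_window = c(32, 181),
                                 bands = seq(0, 70, by = 10),
                                 include_controls = FALSE) {
  rec <- as.data.frame(recoveries)
  stopifnot(all(c("scheme", "date", "lon") %in% names(rec)))
  if ("event_type" %in% names(rec) && !include_controls) {
    rec <- rec[is.na(rec$event_type) | rec$event_type != "control", , drop = FALSE]
  }
  d <- as.Date(rec$date)
  doy <- as.integer(format(d, "%j"))
  keep <- !is.na(doy) & doy >= spring_window[1] & doy <= spring_window[2]
  rec <- rec[keep, , drop = FALSE]; doy <- doy[keep]
  band <- band_of(rec$lon, bands)
  ok <- !is.na(band)
  key <- interaction(rec$scheme[ok], band[ok], drop = TRUE)
  agg <- lapply(split(doy[ok], key), function(v) {
    c(mean_doy = mean(v), sd_doy = stats::sd(v), n = length(v))
  })
  ids <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  out <- data.frame(scheme = ids[, 1], band = as.numeric(ids[, 2]),
                    do.call(rbind, agg), row.names = NULL)
  out <- out[order(out$scheme, out$band), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wt_band_summary", "data.frame")
  out
}

#' First band crossings of an individual-year
#'
#' For each band lower edge L, the date of the earliest arrival event whose
#' *geographic* longitude is at least L; bands never surpassed are absent.
#' Crossing dates are non-decreasing in L.
#'
#' @param events Arrival events (`arrival_date`, `lon`), one individual-year.
#' @param bands Band lower edges.
#' @return data.frame with `band`, `date`, `doy`.
#' @export
first_band_crossings <- function(events, bands = seq(0, 70, by = 10)) {
  ev <- as.data.frame(events)
  ev <- ev[order(ev$arrival_date), , drop = FALSE]
  out <- lapply(bands, function(L) {
    hit <- which(ev$lon >= L)
    if (length(hit) == 0) return(NULL)
    i <- hit[1]
    data.frame(band = L, date = ev$arrival_date[i],
               doy = as.integer(format(ev$arrival_date[i], "%j")))
  })
  do.call(rbind, out)
}

#' Delay of tracked birds relative to the ring-recovery climatology
#'
#' One record per (individual-year, band, scheme): the tracked crossing DOY
#' minus the scheme's mean recovery DOY in that band. Bands without a
#' defined scheme mean are skipped.
#'
#' @param crossings Named list of crossing tables (one per individual-year,
#'   from [first_band_crossings()]), or a single table with an
#'   `individual_year` column.
#' @param summaries `wt_band_summary`.
#' @return data.frame (`wt_ring_delays`): `individual_year`, `band`,
#'   `scheme`, `delay_days`.
#' @export
delta_arrival_ring <- function(crossings, summaries) {
  if (is.data.frame(crossings)) {
    stopifnot("individual_year" %in% names(crossings))
    crossings <- split(crossings, crossings$individual_year)
  }
  out <- list()
  for (iy in names(crossings)) {
    cr <- crossings[[iy]]
    if (is.null(cr) || nrow(cr) == 0) next
    m <- merge(cr, summaries, by = "band")
    if (nrow(m) == 0) next
    out[[iy]] <- data.frame(individual_year = iy, band = m$band,
                            scheme = m$scheme,
                            delay_days = m$doy - m$mean_doy)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(individual_year = character(0),
                                      band = numeric(0), scheme = character(0),
                                      delay_days = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("wt_ring_delays", "data.frame")
  res
}

#' Mixed model for the ring-comparison delay
#'
#' Fixed effects: cell-means intercept per ringing scheme plus a
#' scheme-specific slope in (scaled) band longitude; random intercept per
#' individual-year; maximum likelihood. Optional extra fixed terms (sex,
#' capture site, TGS deviation) can be supplied as additional columns and
#' named in `extra_terms`; the headline model drops them.
#'
#' @param delays `wt_ring_delays` (columns `individual_year`, `band`,
#'   `scheme`, `delay_days`), with delays for at least two schemes.
#' @param extra_terms Character vector of extra covariate columns in
#'   `delays` to add as fixed effects.
#' @return `wt_lmm`; coefficient names `intercept_<scheme>` and
#'   `<scheme>:longitude`.
#' @export
fit_ring_model <- function(delays, extra_terms = character(0)) {
  d <- as.data.frame(delays)
  if (length(unique(d$scheme)) < 2) stop("need delays for at least 2 schemes",
                                         call. = FALSE)
  scheme <- factor(d$scheme)
  lon_s <- as.numeric(scale(d$band))
  Xs <- stats::model.matrix(~ 0 + scheme)
  colnames(Xs) <- paste0("intercept_", levels(scheme))
  Xi <- Xs * lon_s
  colnames(Xi) <- paste0(levels(scheme), ":longitude")
  X <- cbind(Xs, Xi)
  for (v in extra_terms) X <- cbind(X, stats::setNames(d[v], v))
  X <- as.matrix(X)
  fit <- fit_mvn_lmm(d$delay_days, X,
                     individual = d$individual_year,
                     individual_year = d$individual_year,
                     components = "individual")
  attr(fit, "lon_scaling") <- c(mean = mean(d$band), sd = stats::sd(d$band))
  fit
}
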