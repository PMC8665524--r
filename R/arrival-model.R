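# Arrival-delay modelling: annotate arrival events with phenology, derive
# the covariates (maximum corridor longitude, distance traveled, z-scaled
# copies), fit the mixed model with OU residual correlation, and make
# population-level scenario predictions in days.

#' Annotate arrival events with phenology
#'
#' Looks up the TGS onset and deviation of the event's year at the nearest
#' grid cell and derives the arrival delay
#' `delta_arrival_d = arrival_doy - tgs_onset` (signed by default; set
#' `absolute = TRUE` for |days|). Events over cells with undefined onset are
#' dropped (with a message). GDD accumulated between onset and arrival is
#' added when the daily grid is present.
#'
#' @param events `wt_arrival_events` with an `individual_year` column (or
#'   supplied via `individual_year`).
#' @param phen `wt_phenology`.
#' @param individual_year Optional key (recycled) if not a column.
#' @param absolute Use absolute days? Default `FALSE`.
#' @return data.frame of arrival records with `tgs_onset`, `tgs_deviation`,
#'   `delta_arrival_d`, `gdd_at_arrival`.
#' @export
annotate_arrivals <- function(events, phen, individual_year = NULL,
                              absolute = FALSE) {
  stopifnot(inherits(phen, "wt_phenology"))
  ev <- as.data.frame(events)
  if (!is.null(individual_year)) ev$individual_year <- individual_year
  stopifnot("individual_year" %in% names(ev))
  yr <- as.integer(format(ev$arrival_date, "%Y"))
  ki <- match(yr, phen$years)
  if (anyNA(ki)) stop("phenology grid lacks year(s): ",
                      paste(unique(yr[is.na(ki)]), collapse = ", "), call. = FALSE)
  onset <- dev <- gdd <- rep(NA_real_, nrow(ev))
  yr_dates <- as.integer(format(phen$daily$date, "%Y"))
  for (i in seq_len(nrow(ev))) {
    cell <- nearest_cell(phen, ev$lon[i], ev$lat[i])
    onset[i] <- phen$onset[ki[i], cell$lat_idx, cell$lon_idx]
    dev[i] <- phen$deviation[ki[i], cell$lat_idx, cell$lon_idx]
    if (!is.na(onset[i])) {
      if (ev$arrival_doy[i] < onset[i]) {
        gdd[i] <- 0  # arrived before the growing season started
      } else {
        dix <- which(yr_dates == yr[i])
        tm <- phen$daily$tmean[dix, cell$lat_idx, cell$lon_idx]
        gdd[i] <- suppressWarnings(
          growing_degree_days(tm, t_ref = phen$t_ref,
                              from = as.integer(onset[i]),
                              to = ev$arrival_doy[i] + 1L))
      }
    }
  }
  ev$tgs_onset <- onset
  ev$tgs_deviation <- dev
  ev$delta_arrival_d <- ev$arrival_doy - onset
  if (absolute) ev$delta_arrival_d <- abs(ev$delta_arrival_d)
  ev$gdd_at_arrival <- gdd
  drop_n <- sum(is.na(onset))
  if (drop_n > 0) message(drop_n, " event(s) dropped: no environmental data")
  ev[!is.na(onset), , drop = FALSE]
}

#' Derive model covariates and z-scaled copies
#'
#' Adds per-individual-year `max_longitude` (largest projected corridor-axis
#' coordinate over the spring, including the end location when supplied),
#' `max_latitude` (cross-axis analogue), renames the cumulative distance to
#' `distance_traveled`, and z-scales response and predictors over the final
#' modelling dataset (columns suffixed `_s`). The scaling constants are
#' attached as `attr(, "scaling")` and reused for prediction
#' back-transformation.
#'
#' @param records Annotated arrival records (from [annotate_arrivals()]).
#' @param end_points Optional data.frame (`individual_year`, `proj_x`,
#'   `proj_y`) of the projected end locations, entering the maxima.
#' @return Arrival records with covariates and scaled copies.
#' @export
derive_covariates <- function(records, end_points = NULL) {
  rec <- as.data.frame(records)
  stopifnot(all(c("individual_year", "proj_x", "proj_y",
                  "cum_distance_km", "delta_arrival_d") %in% names(rec)))
  mx <- tapply(rec$proj_x, rec$individual_year, max)
  my <- tapply(rec$proj_y, rec$individual_year, max)
  if (!is.null(end_points)) {
    i <- match(names(mx), end_points$individual_year)
    mx <- pmax(mx, end_points$proj_x[i], na.rm = TRUE)
    my <- pmax(my, end_points$proj_y[i], na.rm = TRUE)
  }
  rec$max_longitude <- as.numeric(mx[rec$individual_year])
  rec$max_latitude <- as.numeric(my[rec$individual_year])
  rec$distance_traveled <- rec$cum_distance_km
  scaling <- list()
  for (v in c("delta_arrival_d", "tgs_deviation", "max_longitude",
              "max_latitude", "distance_traveled", "gdd_at_arrival")) {
    if (!v %in% names(rec) || all(is.na(rec[[v]]))) next
    mu <- mean(rec[[v]], na.rm = TRUE)
    sd <- stats::sd(rec[[v]], na.rm = TRUE)
    if (!is.finite(sd) || sd == 0) sd <- 1
    rec[[paste0(v, "_s")]] <- (rec[[v]] - mu) / sd
    scaling[[v]] <- c(mean = mu, sd = sd)
  }
  attr(rec, "scaling") <- scaling
  rec
}

# Design matrix for a model variant. Cell-means coding for capture site;
# the three-way interaction enters as one max_longitude:distance_traveled
# slope per capture site (the identifiable three-way interaction coding).
.arrival_design <- function(rec, variant, predictor, response) {
  pv <- paste0(predictor, "_s")
  rv <- switch(response, delta = "delta_arrival_d_s", gdd = "gdd_at_arrival_s")
  stopifnot(pv %in% names(rec), rv %in% names(rec))
  y <- rec[[rv]]
  if (variant == "full") {
    site <- factor(rec$capture_site)
    Xs <- stats::model.matrix(~ 0 + site)
    colnames(Xs) <- paste0("intercept_", levels(site))
    inter <- rec[[pv]] * rec$distance_traveled_s * Xs
    colnames(inter) <- paste0(predictor, ":distance_", levels(site))
    X <- cbind(Xs, tgs_deviation = rec$tgs_deviation_s, rec[[pv]], inter)
    colnames(X)[ncol(Xs) + 2] <- predictor
  } else { # last_arrival
    X <- cbind(intercept = 1, tgs_deviation = rec$tgs_deviation_s,
               rec[[pv]])
    colnames(X)[3] <- predictor
  }
  list(y = y, X = X, response = rv)
}

#' Fit the arrival-delay mixed model
#'
#' The full model regresses scaled arrival delay on capture-site cell-means
#' intercepts, scaled TGS deviation, scaled maximum longitude, and a
#' maximum-longitude x distance-traveled slope per capture site; random
#' intercepts for individual and year-within-individual; OU residual
#' correlation over arrival day within individual-year plus a residual
#' nugget; maximum likelihood. The `last_arrival` variant keeps only the
#' final arrival event of each individual-year, drops the site terms, the
#' interaction and the OU component, and uses a random intercept per
#' individual.
#'
#' @param records Records from [derive_covariates()] (needs columns
#'   `individual_id`, `individual_year`, `capture_site`, `arrival_doy` and
#'   the scaled covariates).
#' @param variant `"full"` (default) or `"last_arrival"`.
#' @param response `"delta"` (arrival delay, default) or `"gdd"`.
#' @param predictor `"max_longitude"` (default) or `"max_latitude"`.
#' @param fix Passed to [fit_mvn_lmm()] (fix variance components).
#' @param components Override the variance components to estimate.
#' @param reml,maxit Passed to [fit_mvn_lmm()].
#' @return `wt_lmm` with the scaling attribute and variant metadata attached.
#' @export
fit_lmm_ou <- function(records,
                       variant = c("full", "last_arrival"),
                       response = c("delta", "gdd"),
                       predictor = c("max_longitude", "max_latitude"),
                       fix = list(), components = NULL, reml = FALSE,
                       maxit = 1000) {
  variant <- match.arg(variant)
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  rec <- as.data.frame(records)
  if (variant == "last_arrival") {
    ord <- order(rec$individual_year, rec$arrival_doy)
    rec <- rec[ord, , drop = FALSE]
    rec <- rec[!duplicated(rec$individual_year, fromLast = TRUE), , drop = FALSE]
  }
  if (length(unique(rec$individual_year)) < 2) {
    stop("need at least 2 individual-year groups", call. = FALSE)
  }
  d <- .arrival_design(rec, variant, predictor, response)
  if (is.null(components)) {
    components <- if (variant == "full") c("individual", "individual_year", "ou")
                  else "individual"
  }
  fit <- fit_mvn_lmm(d$y, d$X, rec$individual_id, rec$individual_year,
                     times = rec$arrival_doy, components = components,
                     fix = fix, reml = reml, maxit = maxit)
  attr(fit, "scaling") <- attr(records, "scaling")
  attr(fit, "variant") <- variant
  attr(fit, "response") <- response
  attr(fit, "predictor") <- predictor
  fit
}

#' Predict arrival delay for hypothetical breeding scenarios
#'
#' Population-level prediction (random effects at zero) for scenarios given
#' in natural units; covariates are z-scaled with the constants stored in
#' the fit and the prediction is back-transformed to days with the stored
#' response mean/sd.
#'
#' @param fit A `wt_lmm` from [fit_lmm_ou()].
#' @param scenarios data.frame with `capture_site`, `max_longitude` (km,
#'   projected), `distance_traveled` (km) and `tgs_deviation` (days).
#' @return Numeric vector of predicted arrival delays in days.
#' @export
predict_delta_arrival <- function(fit, scenarios) {
  sc <- attr(fit, "scaling")
  if (is.null(sc)) stop("fit carries no scaling information", call. = FALSE)
  predictor <- attr(fit, "predictor")
  z <- function(v, nm) (v - sc[[nm]]["mean"]) / sc[[nm]]["sd"]
  pv <- z(scenarios[[predictor]], predictor)
  dv <- z(scenarios$tgs_deviation, "tgs_deviation")
  for (nm in c(predictor, "tgs_deviation")) {
    rng <- sc[[nm]]
    zz <- z(scenarios[[nm]], nm)
    if (any(abs(zz) > 4)) warning("scenario ", nm, " far outside the scaling context")
  }
  if (attr(fit, "variant") == "full") {
    dt <- z(scenarios$distance_traveled, "distance_traveled")
    site <- factor(scenarios$capture_site,
                   levels = sub("^intercept_", "",
                                grep("^intercept_", names(fit$beta), value = TRUE)))
    Xs <- stats::model.matrix(~ 0 + site)
    inter <- pv * dt * Xs
    X <- cbind(Xs, dv, pv, inter)
  } else {
    X <- cbind(1, dv, pv)
  }
  eta <- drop(X %*% fit$beta)
  rnm <- if (attr(fit, "response") == "delta") "delta_arrival_d" else "gdd_at_arrival"
  as.numeric(eta * sc[[rnm]]["sd"] + sc[[rnm]]["mean"])
}
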