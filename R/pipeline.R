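# Configuration-driven orchestration of the full analysis, plus a thin CLI.
# Every stage reads its inputs from the paths in the config, writes its
# artifacts under `out_dir`, and records a manifest with the config hash so
# re-runs with an identical config are recognisably identical.

#' Default pipeline configuration
#'
#' All parameters default to the package's documented design choices:
#' airspeed 13.94 / 0 m/s (so d_t = 50.184 km), 5 deg C reference
#' temperature, degree-day-minimum onset rule, June 30 arrival cutoff,
#' capture-site projection anchors, 10-degree bands over 0-70 E, spring
#' recovery window Feb 1 - Jun 30, full model variant. HMM fitting inside
#' the pipeline is off by default (decoding uses `hmm_params_json` if given,
#' else the generator defaults); set `hmm$fit = TRUE` to fit.
#'
#' @param out_dir Output directory.
#' @param seed Root seed; all stage randomness derives from it.
#' @return Nested config list.
#' @export
default_pipeline_config <- function(out_dir = "wigeontrack-out", seed = 1) {
  list(
    paths = list(
      out_dir = out_dir,
      tracking_csv = file.path(out_dir, "tracking.csv"),
      temperature_csv = file.path(out_dir, "temperature.csv"),
      ring_csv = file.path(out_dir, "ring_recoveries.csv"),
      hmm_params_json = NULL
    ),
    params = list(
      airspeed_mean = 13.94, airspeed_sd = 0,
      t_ref = 5, onset_rule = "degree_day_minimum",
      cutoff = NULL,                       # June 30 of the event year
      anchors = default_anchors(),
      bands = seq(0, 70, by = 10),
      spring_window = c(32, 181),
      clim_years = NULL,                   # default: all non-focal handling below
      model_variant = "full",
      remove_states = 4L
    ),
    hmm = list(fit = FALSE, n_states = 4, cosinor = TRUE, restarts = 2,
               maxit = 200),
    simulate = list(n_birds = 6,
                    temperature = list(lon = c(5, 20, 40), lat = c(51, 55, 60),
                                       years = 2016:2019,
                                       base_crossing = 70, lat_slope = 3.5,
                                       year_effect = c(-2, 3, 0, 4),
                                       amplitude = 12, diurnal_amplitude = 3,
                                       noise_sd = 0.5)),
    seed = seed
  )
}

.log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

.write_manifest <- function(cfg, stage) {
  man <- list(stage = stage,
              config_hash = rlang::hash(cfg),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("wigeontrack")))
  jsonlite::write_json(man, file.path(cfg$paths$out_dir,
                                      paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  man
}

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing input for this stage: ", what, " (", path %||% "<unset>", ")",
         call. = FALSE)
  }
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic tracking, temperature, ring CSVs with truth
#' sidecars), `preprocess` (clean + hourly regularise), `states` (HMM decode,
#' optionally fit), `stage-sites` (segmentation and arrival events),
#' `phenology`, `annotate`, `fit-arrival`, `ring-compare`, `all`. Each stage
#' writes its artifacts plus a manifest carrying the config hash.
#'
#' @param stage Stage name.
#' @param config Config list, see [default_pipeline_config()].
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(stage = "all", config = default_pipeline_config()) {
  stages <- c("simulate", "preprocess", "states", "stage-sites", "phenology",
              "annotate", "fit-arrival", "ring-compare", "all")
  stage <- match.arg(stage, stages)
  cfg <- config
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  todo <- if (stage == "all") stages[stages != "all"] else stage

  d_t <- threshold_distance(cfg$params$airspeed_mean, cfg$params$airspeed_sd)

  if ("simulate" %in% todo) {
    .log_msg("INFO", "simulate: ", cfg$simulate$n_birds, " birds")
    trajs <- list()
    base <- default_trajectory_config(d_t)
    master <- data.frame(lon = c(4.9, 13.0, 24.0, 33.0, 44.0, 55.0),
                         lat = c(52.4, 54.0, 56.0, 57.0, 58.5, 60.5))
    for (b in seq_len(cfg$simulate$n_birds)) {
      nsite <- 2 + (b - 1) %% 4 + 1
      bc <- base
      bc$sites <- master[seq_len(nsite), , drop = FALSE]
      # final dwell extends into May-July so seasonal endpoints exist
      bc$dwell_hours <- c(24 * 40, rep(24 * 8, nsite - 2), 24 * 60)
      sim <- simulate_trajectory(bc, seed = cfg$seed * 1000 + b,
                                 individual_id = sprintf("bird%02d", b))
      trajs[[b]] <- sim
    }
    write_movebank_csv(lapply(trajs, `[[`, "trajectory"), cfg$paths$tracking_csv)
    tcfg <- utils::modifyList(default_temperature_config(),
                              cfg$simulate$temperature)
    tsim <- simulate_temperature(tcfg, seed = cfg$seed * 1000 + 777)
    write_temperature_csv(tsim$grid, cfg$paths$temperature_csv)
    rsim <- simulate_ring_recoveries(seed = cfg$seed * 1000 + 888)
    utils::write.csv(rsim$recoveries, cfg$paths$ring_csv, row.names = FALSE)
    truth <- list(arrival_dates = lapply(trajs, function(s)
                    format(s$truth$arrival_dates)),
                  crossing_days = tsim$truth$crossing,
                  band_means = rsim$truth$band_means)
    jsonlite::write_json(truth, file.path(cfg$paths$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    res$simulate <- list(trajectories = trajs, temperature = tsim, rings = rsim)
    .write_manifest(cfg, "simulate")
  }

  if ("preprocess" %in% todo) {
    .need_file(cfg$paths$tracking_csv, "tracking CSV")
    .log_msg("INFO", "preprocess")
    trajs <- read_movebank_csv(cfg$paths$tracking_csv)
    trajs <- lapply(trajs, function(t) regularize_hourly(clean_trajectory(t)))
    res$preprocess <- trajs
    for (t in trajs) {
      write_trajectory_csv(t, file.path(cfg$paths$out_dir,
        sprintf("traj_%s_%d.csv", attr(t, "individual_id"), attr(t, "year"))))
    }
    .write_manifest(cfg, "preprocess")
  }

  if ("states" %in% todo) {
    trajs <- res$preprocess %||% stop("run preprocess first (or `all`)")
    .log_msg("INFO", "states: decoding ", length(trajs), " trajectories")
    steps <- lapply(trajs, compute_steps)
    if (isTRUE(cfg$hmm$fit)) {
      fit <- fit_hmm(steps, n_states = cfg$hmm$n_states,
                     cosinor = cfg$hmm$cosinor,
                     seeds = cfg$seed + seq_len(cfg$hmm$restarts),
                     maxit = cfg$hmm$maxit)
      params <- relabel_hmm_params(fit$params, label_states(fit$params))
      res$hmm_fit <- fit
    } else if (!is.null(cfg$paths$hmm_params_json)) {
      params <- read_hmm_params_json(.need_file(cfg$paths$hmm_params_json,
                                                "HMM parameter JSON"))
    } else {
      params <- default_hmm_params()
    }
    write_hmm_params_json(params, file.path(cfg$paths$out_dir, "hmm_params.json"))
    res$states <- lapply(steps, viterbi_decode, p = params)
    res$steps <- steps
    res$hmm_params <- params
    .write_manifest(cfg, "states")
  }

  if ("stage-sites" %in% todo) {
    trajs <- res$preprocess %||% stop("run preprocess first (or `all`)")
    states <- res$states %||% stop("run states first (or `all`)")
    .log_msg("INFO", "stage-sites: d_t = ", round(d_t, 3), " km")
    ev_all <- list(); ends <- list()
    for (nm in names(trajs)) {
      t <- trajs[[nm]]
      ep <- find_endpoints(t, cfg$params$anchors)
      w <- migration_window(t, ep$start, ep$end, d_t)
      if (is.null(w)) next
      nonmig <- drop_migratory(t, states[[nm]], cfg$params$remove_states)
      sites <- segment_staging_sites(nonmig, d_t)
      ev <- extract_arrival_events(sites, ep$start, d_t,
                                   cutoff = cfg$params$cutoff,
                                   anchors = cfg$params$anchors)
      if (nrow(ev) == 0) next
      ev$individual_year <- nm
      ev$individual_id <- attr(t, "individual_id")
      ev$year <- attr(t, "year")
      ev_all[[nm]] <- ev
      pe <- project_two_point(ep$end$lon, ep$end$lat, cfg$params$anchors)
      ends[[nm]] <- data.frame(individual_year = nm, proj_x = pe$x, proj_y = pe$y)
    }
    events <- do.call(rbind, ev_all)
    if (is.null(events)) stop("no arrival events found", call. = FALSE)
    rownames(events) <- NULL
    res$events <- events
    res$end_points <- do.call(rbind, ends)
    utils::write.csv(events, file.path(cfg$paths$out_dir, "arrival_events.csv"),
                     row.names = FALSE)
    .write_manifest(cfg, "stage-sites")
  }

  if ("phenology" %in% todo) {
    .need_file(cfg$paths$temperature_csv, "temperature CSV")
    .log_msg("INFO", "phenology")
    grid <- read_temperature_csv(cfg$paths$temperature_csv)
    daily <- daily_mean_temperature(grid)
    phen <- phenology_grid(daily, clim_years = cfg$params$clim_years,
                           t_ref = cfg$params$t_ref,
                           rule = cfg$params$onset_rule)
    res$phenology <- phen
    onset_df <- do.call(rbind, lapply(seq_along(phen$years), function(k) {
      g <- expand.grid(lat = phen$lat, lon = phen$lon)
      g$year <- phen$years[k]
      g$tgs_onset <- as.vector(phen$onset[k, , ])
      g$tgs_deviation <- as.vector(phen$deviation[k, , ])
      g
    }))
    utils::write.csv(onset_df, file.path(cfg$paths$out_dir, "phenology.csv"),
                     row.names = FALSE)
    .write_manifest(cfg, "phenology")
  }

  if ("annotate" %in% todo) {
    events <- res$events %||% stop("run stage-sites first (or `all`)")
    phen <- res$phenology %||% stop("run phenology first (or `all`)")
    .log_msg("INFO", "annotate")
    recs <- annotate_arrivals(events, phen)
    recs$capture_site <- ifelse(
      as.integer(sub("^bird", "", sub("_.*$", "", recs$individual_id))) %% 2 == 0,
      "NLD", "LTU")
    recs <- derive_covariates(recs, end_points = res$end_points)
    res$records <- recs
    utils::write.csv(recs, file.path(cfg$paths$out_dir, "arrival_records.csv"),
                     row.names = FALSE)
    .write_manifest(cfg, "annotate")
  }

  if ("fit-arrival" %in% todo) {
    recs <- res$records %||% stop("run annotate first (or `all`)")
    .log_msg("INFO", "fit-arrival (", cfg$params$model_variant, ")")
    fit <- fit_lmm_ou(recs, variant = cfg$params$model_variant)
    res$arrival_fit <- fit
    out <- list(beta = as.list(fit$beta), se = as.list(fit$se),
                z = as.list(fit$z), varcomp = fit$varcomp,
                loglik = fit$loglik, marginal_r2 = marginal_r2(fit))
    jsonlite::write_json(out, file.path(cfg$paths$out_dir, "arrival_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_manifest(cfg, "fit-arrival")
  }

  if ("ring-compare" %in% todo) {
    events <- res$events %||% stop("run stage-sites first (or `all`)")
    .need_file(cfg$paths$ring_csv, "ring recovery CSV")
    .log_msg("INFO", "ring-compare")
    recov <- utils::read.csv(cfg$paths$ring_csv, stringsAsFactors = FALSE)
    summ <- band_passage_summary(recov, spring_window = cfg$params$spring_window,
                                 bands = cfg$params$bands)
    cross <- lapply(split(events, events$individual_year),
                    first_band_crossings, bands = cfg$params$bands)
    delays <- delta_arrival_ring(cross, summ)
    res$ring_delays <- delays
    utils::write.csv(delays, file.path(cfg$paths$out_dir, "ring_delays.csv"),
                     row.names = FALSE)
    if (length(unique(delays$scheme)) >= 2 && nrow(delays) >= 8) {
      rfit <- fit_ring_model(delays)
      res$ring_fit <- rfit
      jsonlite::write_json(list(beta = as.list(rfit$beta), se = as.list(rfit$se)),
                           file.path(cfg$paths$out_dir, "ring_fit.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      .log_msg("WARN", "too few ring delays for the mixed model; skipped fit")
    }
    .write_manifest(cfg, "ring-compare")
  }

  invisible(res)
}

#' Command-line entry point
#'
#' Parses `--stage`, `--config` (JSON overriding the defaults), `--seed`,
#' `--out` and `--log-level`, then calls [run_pipeline()]. Installed as
#' `inst/cli/wigeontrack`.
#'
#' @param args Character vector of CLI arguments (default: the command line).
#' @return Exit status 0 invisibly; errors propagate (non-zero exit under
#'   Rscript).
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--stage", type = "character", default = "all"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "wigeontrack-out"),
    optparse::make_option("--log-level", type = "character", default = "INFO")
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  cfg <- default_pipeline_config(out_dir = opt$out, seed = opt$seed)
  if (!is.null(opt$config)) {
    user <- jsonlite::read_json(.need_file(opt$config, "config JSON"),
                                simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
  }
  run_pipeline(opt$stage, cfg)
  invisible(0L)
}
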