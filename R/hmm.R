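# Four-state hidden Markov model of hourly movement behaviour.
#
# Observations per interval: sqrt-transformed step length in km (gamma
# emission with a per-state point mass at exactly zero) and turning angle in
# radians (Weibull density on |angle|, renormalised over (0, pi], sign
# symmetric). State switching follows a multinomial-logit transition model
# with a first-harmonic cosinor in mean solar hour, so switching
# probabilities vary over the day. Missing observations contribute emission
# density 1 and are propagated through the transition model.
#
# States are labelled post hoc by increasing mean sqrt-step:
#   1 rest, 2 non-flight, 3 local flight, 4 migratory flight.

#' Construct HMM parameters
#'
#' @param step_mean,step_sd Gamma mean and sd of sqrt-step (sqrt-km) per
#'   state; positive.
#' @param step_zero_mass Probability of an exactly-zero step per state, in
#'   `[0, 1)`.
#' @param angle_shape,angle_scale Weibull shape/scale of |turning angle|
#'   (radians) per state; positive.
#' @param beta Transition coefficients: matrix with `N*(N-1)` rows (ordered
#'   by origin state, then destination, skipping the diagonal) and 1 column
#'   (intercepts only) or 3 columns (intercept, cos, sin of `2*pi*h/24`).
#' @param delta Initial state distribution (sums to 1).
#' @return An object of class `wt_hmm_params`.
#' @export
hmm_params <- function(step_mean, step_sd, step_zero_mass,
                       angle_shape, angle_scale, beta, delta) {
  n <- length(step_mean)
  stopifnot(
    n >= 1,
    length(step_sd) == n, length(step_zero_mass) == n,
    length(angle_shape) == n, length(angle_scale) == n,
    length(delta) == n,
    all(step_mean > 0), all(step_sd > 0),
    all(step_zero_mass >= 0), all(step_zero_mass < 1),
    all(angle_shape > 0), all(angle_scale > 0)
  )
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == n * (n - 1) || n == 1,
            ncol(beta) %in% c(1, 3))
  stopifnot(abs(sum(delta) - 1) < 1e-8, all(delta >= 0))
  structure(list(n_states = n, step_mean = step_mean, step_sd = step_sd,
                 step_zero_mass = step_zero_mass,
                 angle_shape = angle_shape, angle_scale = angle_scale,
                 beta = beta, delta = delta / sum(delta)),
            class = "wt_hmm_params")
}

#' Transition probability matrix at a given solar hour
#'
#' Multinomial logit with the diagonal as reference category and a
#' first-harmonic cosinor covariate. Rows sum to 1.
#' @param p `wt_hmm_params`.
#' @param hour Solar hour(s) in `[0, 24)`.
#' @return An `N x N` matrix (or a list of matrices for vector `hour`).
#' @export
hmm_transition_matrix <- function(p, hour) {
  stopifnot(inherits(p, "wt_hmm_params"))
  one <- function(h) {
    n <- p$n_states
    covs <- if (ncol(p$beta) == 3) c(1, cos(2 * pi * h / 24), sin(2 * pi * h / 24)) else 1
    eta <- matrix(0, n, n)
    r <- 1
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      eta[i, j] <- sum(p$beta[r, ] * covs)
      r <- r + 1
    }
    g <- exp(eta)
    g / rowSums(g)
  }
  if (length(hour) == 1) one(hour) else lapply(hour, one)
}

# Emission probability matrix (T x N); missing parts contribute 1.
.hmm_emissions <- function(obs, p) {
  n <- p$n_states
  T_ <- nrow(obs)
  shape <- p$step_mean^2 / p$step_sd^2
  scale <- p$step_sd^2 / p$step_mean
  wnorm <- stats::pweibull(pi, p$angle_shape, p$angle_scale)
  f <- matrix(1, T_, n)
  s <- obs$sqrt_step
  a <- abs(obs$turn_angle)
  for (k in seq_len(n)) {
    fs <- rep(1, T_)
    pos <- !is.na(s) & s > 0
    zer <- !is.na(s) & s == 0
    fs[pos] <- (1 - p$step_zero_mass[k]) *
      stats::dgamma(s[pos], shape = shape[k], scale = scale[k])
    fs[zer] <- p$step_zero_mass[k]
    fa <- rep(1, T_)
    ha <- !is.na(a)
    fa[ha] <- 0.5 * stats::dweibull(a[ha], p$angle_shape[k], p$angle_scale[k]) / wnorm[k]
    f[, k] <- fs * fa
  }
  f
}

.obs_list <- function(obs) {
  if (inherits(obs, "data.frame")) list(obs) else obs
}

# Flatten a list of step streams for the C++ likelihood. Solar hours are
# quantised to the integer grid 0..23 for the transition covariate (the data
# are hourly; sub-hour resolution carries no information), and logs of the
# observations are precomputed once.
.pool_obs <- function(obs_list) {
  lens <- vapply(obs_list, nrow, integer(1))
  step <- unlist(lapply(obs_list, `[[`, "sqrt_step"), use.names = FALSE)
  angle <- abs(unlist(lapply(obs_list, `[[`, "turn_angle"), use.names = FALSE))
  hour <- unlist(lapply(obs_list, `[[`, "solar_hour"), use.names = FALSE)
  hour_idx <- as.integer(round(ifelse(is.na(hour), 0, hour)) %% 24)
  list(
    step = step, angle = angle, hour = hour, hour_idx = hour_idx,
    log_step = suppressWarnings(log(step)),
    log_angle = suppressWarnings(log(angle)),
    stream_start = as.integer(cumsum(c(0, lens[-length(lens)])))
  )
}

#' Forward-algorithm log-likelihood
#'
#' Exact scaled forward log-likelihood of one or more observation streams
#' under the movement HMM. Missing observations contribute emission density
#' 1; the state path is still propagated through the time-varying transition
#' matrix. Multiple streams are treated as independent, each restarting from
#' the initial distribution.
#'
#' @param obs A `wt_steps` data.frame (columns `sqrt_step`, `turn_angle`,
#'   `solar_hour`) or a list of them.
#' @param p `wt_hmm_params`.
#' @return Log-likelihood (scalar).
#' @export
hmm_forward_loglik <- function(obs, p) {
  stopifnot(inherits(p, "wt_hmm_params"))
  if (any(!is.finite(unlist(p[c("step_mean", "step_sd", "step_zero_mass",
                                "angle_shape", "angle_scale", "beta", "delta")])))) {
    stop("non-finite parameter values", call. = FALSE)
  }
  po <- .pool_obs(.obs_list(obs))
  nll <- hmm_nll_cpp(po$step, po$log_step, po$angle, po$log_angle,
                     po$hour_idx, po$stream_start,
                     p$step_mean, p$step_sd, p$step_zero_mass,
                     p$angle_shape, p$angle_scale,
                     p$beta, p$delta)
  -nll
}

# ---- working-scale parameter transforms -------------------------------------

.pack_params <- function(p, fit_zero) {
  n <- p$n_states
  c(log(p$step_mean), log(p$step_sd),
    if (fit_zero) stats::qlogis(pmin(pmax(p$step_zero_mass, 1e-8), 1 - 1e-8)),
    log(p$angle_shape), log(p$angle_scale),
    as.vector(p$beta),
    if (n > 1) log(p$delta[-1] / p$delta[1]))
}

.unpack_params <- function(w, n, n_beta_col, fit_zero) {
  i <- 0
  take <- function(k) { v <- w[(i + 1):(i + k)]; i <<- i + k; v }
  step_mean <- exp(take(n))
  step_sd <- exp(take(n))
  zero <- if (fit_zero) stats::plogis(take(n)) else rep(0, n)
  angle_shape <- exp(take(n))
  angle_scale <- exp(take(n))
  beta <- matrix(take(n * (n - 1) * n_beta_col), ncol = n_beta_col)
  if (n > 1) {
    ld <- take(n - 1)
    delta <- c(1, exp(ld)); delta <- delta / sum(delta)
  } else delta <- 1
  hmm_params(step_mean, step_sd, zero, angle_shape, angle_scale,
             if (n == 1) matrix(0, 0, n_beta_col) else beta, delta)
}

# Data-driven starting values: state means at spread quantiles of sqrt-step.
.hmm_default_init <- function(po, n, n_beta_col) {
  s <- po$step[!is.na(po$step) & po$step > 0]
  qs <- stats::quantile(s, probs = seq(0.15, 0.95, length.out = n), names = FALSE)
  qs <- pmax(qs, 1e-3)
  hmm_params(
    step_mean = qs,
    step_sd = pmax(qs * 0.5, 1e-3),
    step_zero_mass = rep(0.05, n),
    angle_shape = seq(0.8, 1.6, length.out = n),
    angle_scale = seq(1.5, 0.5, length.out = n),
    beta = matrix(c(rep(-2, n * (n - 1)), rep(0, n * (n - 1) * (n_beta_col - 1))),
                  ncol = n_beta_col),
    delta = rep(1 / n, n)
  )
}

.jitter_params <- function(p, sd = 0.25) {
  n <- p$n_states
  hmm_params(
    step_mean = p$step_mean * exp(stats::rnorm(n, 0, sd)),
    step_sd = p$step_sd * exp(stats::rnorm(n, 0, sd)),
    step_zero_mass = pmin(pmax(p$step_zero_mass * exp(stats::rnorm(n, 0, sd)), 0), 0.5),
    angle_shape = p$angle_shape * exp(stats::rnorm(n, 0, sd / 2)),
    angle_scale = p$angle_scale * exp(stats::rnorm(n, 0, sd / 2)),
    beta = p$beta + stats::rnorm(length(p$beta), 0, sd),
    delta = p$delta
  )
}

#' Fit the movement HMM by direct likelihood maximisation
#'
#' Maximises the pooled forward log-likelihood over all observation streams
#' (one shared parameter set) on the working scale (log for positive
#' parameters, logit for the zero mass, multinomial logit for delta), using
#' quasi-Newton optimisation with seeded random restarts. The best converged
#' restart is returned. Zero-step point masses are only estimated when the
#' pooled data contain exact zeros; otherwise they are fixed at 0.
#'
#' @param obs A `wt_steps` data.frame or list of them (pooled streams).
#' @param n_states Number of states (default 4).
#' @param cosinor Include the solar-hour cosinor in the transition model?
#'   Default `TRUE`.
#' @param seeds Integer vector; one restart per seed (first restart starts
#'   from `init` unjittered).
#' @param init Optional `wt_hmm_params` starting values; default derived
#'   from step-length quantiles.
#' @param maxit Maximum BFGS iterations per restart.
#' @return A `wt_hmm_fit` list: `params` (natural scale), `loglik`,
#'   `convergence` (0 = converged), `restarts` (per-restart log-likelihoods),
#'   `n_obs`, `labels` (state order by increasing step mean).
#' @export
fit_hmm <- function(obs, n_states = 4, cosinor = TRUE,
                    seeds = 1:5, init = NULL, maxit = 400) {
  obs_list <- .obs_list(obs)
  po <- .pool_obs(obs_list)
  n_beta_col <- if (cosinor) 3L else 1L
  fit_zero <- any(!is.na(po$step) & po$step == 0)
  if (is.null(init)) init <- .hmm_default_init(po, n_states, n_beta_col)
  stopifnot(init$n_states == n_states, ncol(init$beta) == n_beta_col)
  if (!fit_zero) init$step_zero_mass <- rep(0, n_states)

  nll_fun <- function(w) {
    p <- try(.unpack_params(w, n_states, n_beta_col, fit_zero), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    hmm_nll_cpp(po$step, po$log_step, po$angle, po$log_angle,
                po$hour_idx, po$stream_start,
                p$step_mean, p$step_sd, p$step_zero_mass,
                p$angle_shape, p$angle_scale, p$beta, p$delta)
  }

  best <- NULL
  restart_ll <- rep(NA_real_, length(seeds))
  for (k in seq_along(seeds)) {
    p0 <- if (k == 1) init else withr::with_seed(seeds[k], .jitter_params(init))
    w0 <- .pack_params(p0, fit_zero)
    opt <- try(stats::optim(w0, nll_fun, method = "BFGS",
                            control = list(maxit = maxit, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value) || opt$value >= 1e10) next
    restart_ll[k] <- -opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("no HMM restart converged", call. = FALSE)
  params <- .unpack_params(best$par, n_states, n_beta_col, fit_zero)
  sep <- abs(outer(params$step_mean, params$step_mean, "-"))
  diag(sep) <- Inf
  if (any(sep < 1e-3 * max(params$step_mean))) {
    warning("possible state collapse: two states have nearly identical step means")
  }
  structure(list(params = params, loglik = -best$value,
                 convergence = best$convergence, restarts = restart_ll,
                 n_obs = length(po$step), labels = label_states(params)),
            class = "wt_hmm_fit")
}

#' @export
print.wt_hmm_fit <- function(x, ...) {
  cat(sprintf("<wt_hmm_fit> %d states, logLik %.2f on %d intervals\n",
              x$params$n_states, x$loglik, x$n_obs))
  m <- rbind(step_mean = x$params$step_mean, step_sd = x$params$step_sd,
             zero_mass = x$params$step_zero_mass,
             angle_shape = x$params$angle_shape, angle_scale = x$params$angle_scale)
  colnames(m) <- paste0("state", seq_len(x$params$n_states))
  print(round(m, 4))
  invisible(x)
}

#' Viterbi decoding of the most likely state path
#'
#' Global maximum-a-posteriori state path by dynamic programming in the log
#' domain. Ties are broken toward the lower state index. Missing
#' observations contribute emission density 1.
#'
#' @param obs A `wt_steps` data.frame.
#' @param p `wt_hmm_params`.
#' @return Integer vector of decoded states (length `nrow(obs)`).
#' @export
viterbi_decode <- function(obs, p) {
  stopifnot(inherits(p, "wt_hmm_params"))
  T_ <- nrow(obs)
  n <- p$n_states
  if (T_ == 0) return(integer(0))
  f <- .hmm_emissions(obs, p)
  logf <- log(f)
  h <- round(ifelse(is.na(obs$solar_hour), 0, obs$solar_hour)) %% 24
  # transition matrices only depend on the (quantised) hour; cache them
  uh <- unique(h)
  gammas <- lapply(uh, function(x) log(hmm_transition_matrix(p, x)))
  gidx <- match(h, uh)

  v <- log(p$delta) + logf[1, ]
  back <- matrix(NA_integer_, T_, n)
  if (T_ > 1) {
    for (t in 2:T_) {
      lg <- gammas[[gidx[t]]]
      cand <- v + lg                 # cand[i, j] = v_i + log gamma_ij
      bi <- max.col(t(cand), ties.method = "first")
      back[t, ] <- bi
      v <- cand[cbind(bi, seq_len(n))] + logf[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(v)
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Order fitted states by movement intensity
#'
#' Returns the permutation mapping label k (1 = rest, 2 = non-flight,
#' 3 = local flight, 4 = migratory flight) to the fitted state index, by
#' increasing gamma mean of sqrt-step. Ties in the step mean are broken by
#' decreasing mean |turning angle|: of two equally fast states the less
#' directed one (larger mean |angle|, lower persistence) gets the lower
#' label, mirroring the local-flight vs migratory-flight distinction.
#'
#' @param p `wt_hmm_params`.
#' @return Integer permutation `perm`, `perm[k]` = fitted state carrying
#'   label `k`.
#' @export
label_states <- function(p) {
  stopifnot(inherits(p, "wt_hmm_params"))
  ang_mean <- p$angle_scale * gamma(1 + 1 / p$angle_shape)
  if (anyDuplicated(p$step_mean)) {
    message("tied step means; breaking ties by mean |turning angle|")
  }
  order(p$step_mean, -ang_mean)
}

#' Relabel HMM parameters by a state permutation
#'
#' Applies `perm` (as returned by [label_states()]) so that state k of the
#' result is fitted state `perm[k]`. The likelihood is invariant under this
#' relabeling.
#' @param p `wt_hmm_params`.
#' @param perm Integer permutation.
#' @return Relabelled `wt_hmm_params`.
#' @export
relabel_hmm_params <- function(p, perm) {
  n <- p$n_states
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  # beta row index for ordered pair (i, j), i != j
  row_of <- function(i, j) (i - 1) * (n - 1) + j - (j > i)
  beta <- p$beta
  r <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    beta[r, ] <- p$beta[row_of(perm[i], perm[j]), ]
    r <- r + 1
  }
  hmm_params(p$step_mean[perm], p$step_sd[perm], p$step_zero_mass[perm],
             p$angle_shape[perm], p$angle_scale[perm], beta, p$delta[perm])
}

#' Serialise fitted HMM parameters to JSON
#'
#' @param p `wt_hmm_params`.
#' @param path Output path.
#' @export
write_hmm_params_json <- function(p, path) {
  doc <- list(format = "wigeontrack-hmm-params", version = 1L,
              n_states = p$n_states, step_mean = p$step_mean,
              step_sd = p$step_sd, step_zero_mass = p$step_zero_mass,
              angle_shape = p$angle_shape, angle_scale = p$angle_scale,
              beta = p$beta, delta = p$delta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read HMM parameters from JSON
#' @param path Path written by [write_hmm_params_json()].
#' @return `wt_hmm_params`.
#' @export
read_hmm_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(doc$format, "wigeontrack-hmm-params"))
  hmm_params(doc$step_mean, doc$step_sd, doc$step_zero_mass,
             doc$angle_shape, doc$angle_scale, as.matrix(doc$beta), doc$delta)
}
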