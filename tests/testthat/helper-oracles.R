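# Independent oracles used by the tests. These deliberately avoid the
# package's computational paths: emissions are recomputed from first
# principles, likelihoods by exhaustive path enumeration, onsets by explicit
# scans, and GLS limits by lm().

# Emission density table computed independently of wigeontrack:::.hmm_emissions
oracle_emissions <- function(obs, p) {
  n <- p$n_states
  out <- matrix(1, nrow(obs), n)
  for (t in seq_len(nrow(obs))) {
    for (s in seq_len(n)) {
      f <- 1
      x <- obs$sqrt_step[t]
      if (!is.na(x)) {
        if (x == 0) {
          f <- f * p$step_zero_mass[s]
        } else {
          sh <- p$step_mean[s]^2 / p$step_sd[s]^2
          ra <- p$step_mean[s] / p$step_sd[s]^2
          f <- f * (1 - p$step_zero_mass[s]) * dgamma(x, shape = sh, rate = ra)
        }
      }
      a <- obs$turn_angle[t]
      if (!is.na(a)) {
        f <- f * 0.5 * dweibull(abs(a), p$angle_shape[s], p$angle_scale[s]) /
          pweibull(pi, p$angle_shape[s], p$angle_scale[s])
      }
      out[t, s] <- f
    }
  }
  out
}

# Exhaustive sum over all state paths (exponential; tiny T only)
oracle_forward_loglik <- function(obs, p) {
  n <- p$n_states
  T_ <- nrow(obs)
  emis <- oracle_emissions(obs, p)
  G <- lapply(obs$solar_hour, function(h) hmm_transition_matrix(p, h))
  paths <- expand.grid(rep(list(seq_len(n)), T_))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    pr <- p$delta[s[1]] * emis[1, s[1]]
    if (T_ > 1) for (t in 2:T_) pr <- pr * G[[t]][s[t - 1], s[t]] * emis[t, s[t]]
    tot <- tot + pr
  }
  log(tot)
}

# Exhaustive most-likely path; ties toward the lexicographically first
# (= lower state index) path because expand.grid varies the first column
# fastest and we require a strict improvement to switch.
oracle_viterbi <- function(obs, p) {
  n <- p$n_states
  T_ <- nrow(obs)
  emis <- oracle_emissions(obs, p)
  G <- lapply(obs$solar_hour, function(h) hmm_transition_matrix(p, h))
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  best <- -Inf; bestpath <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- log(p$delta[s[1]]) + log(emis[1, s[1]])
    if (T_ > 1) for (t in 2:T_) {
      pr <- pr + log(G[[t]][s[t - 1], s[t]]) + log(emis[t, s[t]])
    }
    if (pr > best) { best <- pr; bestpath <- s }
  }
  unname(bestpath)
}

# Degree-day-minimum onset by explicit scan over all candidate boundaries
oracle_onset_ddm <- function(tmean, t_ref = 5) {
  nd <- length(tmean)
  if (max(tmean, na.rm = TRUE) <= t_ref) return(NA_integer_)
  x <- ifelse(is.na(tmean), t_ref, tmean)
  best_s <- Inf; best_d <- NA_integer_
  for (d in 0:nd) {  # balance after day d (0 = before the year starts)
    s <- if (d > 0) sum(x[seq_len(d)] - t_ref) else 0
    if (s < best_s) { best_s <- s; best_d <- d }
  }
  onset <- best_d + 1L
  if (onset > nd) return(NA_integer_)
  onset
}

oracle_onset_persistence <- function(tmean, t_ref = 5, persist = 5) {
  nd <- length(tmean)
  for (d in seq_len(nd - persist + 1)) {
    w <- tmean[d:(d + persist - 1)]
    if (!anyNA(w) && all(w > t_ref)) return(as.integer(d))
  }
  NA_integer_
}

# Direct ML gamma fit (mean/sd parameterisation via optim on log scale)
oracle_gamma_mle <- function(x) {
  nll <- function(w) -sum(dgamma(x, shape = exp(w[1]), rate = exp(w[2]), log = TRUE))
  o <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))
  shape <- exp(o$par[1]); rate <- exp(o$par[2])
  list(mean = shape / rate, sd = sqrt(shape) / rate, loglik = -o$value)
}

# A tiny deterministic Movebank CSV fixture written at test time
write_movebank_fixture <- function(path, rows) {
  header <- "individual-local-identifier,timestamp,location-long,location-lat,ground-speed"
  writeLines(c(header, rows), path)
}
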