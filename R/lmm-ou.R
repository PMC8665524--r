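# Linear mixed model by direct marginal-likelihood maximisation.
#
# Marginal covariance per individual block:
#   V = s2_id * J                      (random intercept, individual)
#     + s2_idyear * blockdiag(J_year)  (random intercept, year in individual)
#     + s2_ou * exp(-|t_i - t_j|/rho)  (OU kernel on arrival day, within
#                                       individual-year)
#     + s2_e * I                       (residual nugget)
# Fixed effects are profiled out by GLS at each variance evaluation; the
# profiled multivariate-normal log-likelihood is maximised numerically over
# the log-scale variance parameters. Wald CIs (estimate +/- 1.96 SE) and
# z-values are reported for fixed effects, matching the symmetric intervals
# of standard mixed-model software.

.ou_kernel <- function(t1, t2 = t1, rho) {
  exp(-abs(outer(t1, t2, "-")) / rho)
}

# Build the covariance matrix for one individual block.
.block_cov <- function(n, year_f, times, th) {
  V <- matrix(th$s2_id, n, n)
  for (lev in levels(year_f)) {
    ix <- which(year_f == lev)
    V[ix, ix] <- V[ix, ix] + th$s2_idyear
    if (th$s2_ou > 0) {
      V[ix, ix] <- V[ix, ix] + th$s2_ou * .ou_kernel(times[ix], rho = th$rho)
    }
  }
  diag(V) <- diag(V) + th$s2_e
  V
}

#' Fit a Gaussian linear mixed model with optional OU residual correlation
#'
#' Low-level engine used by [fit_lmm_ou()] and [fit_ring_model()]. Variance
#' components may be included, excluded, or fixed at given values; fixing
#' all random components at 0 (with `rho` at its tiny floor) reduces the fit
#' to ordinary least squares.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (named columns).
#' @param individual Factor: outer grouping (individual).
#' @param individual_year Factor: inner grouping (individual-year); must be
#'   nested in `individual`.
#' @param times Numeric time variable for the OU kernel (arrival day of
#'   year); ignored when the OU component is off.
#' @param components Character subset of
#'   `c("individual", "individual_year", "ou")` to estimate; the residual
#'   variance is always present.
#' @param fix Named list of fixed (not estimated) parameter values on the
#'   natural scale, among `s2_id`, `s2_idyear`, `s2_ou`, `rho`, `s2_e`.
#' @param reml Use restricted maximum likelihood for the variance
#'   parameters? Default `FALSE` (full ML). REML removes the downward
#'   small-sample bias of ML variance estimates and is the right choice for
#'   interval-coverage work; fixed effects are GLS under either criterion.
#' @param maxit Optimiser iteration cap.
#' @return `wt_lmm` object: `beta`, `se`, `ci_lo`, `ci_hi`, `z`, `varcomp`
#'   (list with `s2_id`, `s2_idyear`, `s2_ou`, `rho`, `s2_e`), `loglik`,
#'   `vcov_beta`, `fitted`, plus the inputs needed for prediction.
#' @export
fit_mvn_lmm <- function(y, X, individual, individual_year, times = NULL,
                        components = c("individual", "individual_year", "ou"),
                        fix = list(), reml = FALSE, maxit = 1000) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(individual) == n, length(individual_year) == n)
  individual <- droplevels(as.factor(individual))
  individual_year <- droplevels(as.factor(individual_year))
  if (is.null(times)) times <- rep(0, n)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient", call. = FALSE)

  use <- list(s2_id = "individual" %in% components,
              s2_idyear = "individual_year" %in% components,
              s2_ou = "ou" %in% components)
  # parameters estimated on log scale
  est_names <- c(if (use$s2_id && is.null(fix$s2_id)) "s2_id",
                 if (use$s2_idyear && is.null(fix$s2_idyear)) "s2_idyear",
                 if (use$s2_ou && is.null(fix$s2_ou)) "s2_ou",
                 if (use$s2_ou && is.null(fix$rho)) "rho",
                 if (is.null(fix$s2_e)) "s2_e")

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  # clamp estimated variances: keeps V well conditioned when an exact fit
  # drives components toward zero (noise-free synthetic data)
  v_floor <- 1e-10 * vy; v_cap <- 1e8 * vy
  theta_full <- function(w) {
    th <- list(s2_id = 0, s2_idyear = 0, s2_ou = 0, rho = 1e-8, s2_e = 1e-12)
    th[names(fix)] <- fix
    if (length(est_names)) {
      v <- pmin(pmax(exp(w), v_floor), v_cap)
      names(v) <- est_names
      if ("rho" %in% est_names) {
        v["rho"] <- min(max(exp(w[est_names == "rho"]), 1e-6), 1e6)
      }
      th[est_names] <- as.list(v)
    }
    th
  }

  blocks <- split(seq_len(n), individual)
  # per-block structure precomputed once (the optimiser calls obj thousands
  # of times)
  block_info <- lapply(blocks, function(ix) {
    list(ix = ix, year = droplevels(individual_year[ix]), t = times[ix],
         X = X[ix, , drop = FALSE], y = y[ix])
  })
  # profiled negative log-likelihood
  obj <- function(w) {
    th <- theta_full(w)
    if (any(unlist(th) > 1e12)) return(1e10)
    XtViX <- matrix(0, ncol(X), ncol(X))
    XtViy <- numeric(ncol(X))
    ytViy <- 0; logdet <- 0
    for (bi in block_info) {
      V <- .block_cov(length(bi$ix), bi$year, bi$t, th)
      ch <- try(chol(V), silent = TRUE)
      if (inherits(ch, "try-error")) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xi <- backsolve(ch, bi$X, transpose = TRUE)
      yi <- backsolve(ch, bi$y, transpose = TRUE)
      XtViX <- XtViX + crossprod(Xi)
      XtViy <- XtViy + crossprod(Xi, yi)
      ytViy <- ytViy + sum(yi^2)
    }
    beta <- try(solve(XtViX, XtViy), silent = TRUE)
    if (inherits(beta, "try-error")) return(1e10)
    quad <- ytViy - 2 * sum(beta * XtViy) + as.numeric(t(beta) %*% XtViX %*% beta)
    nll <- 0.5 * (logdet + quad + n * log(2 * pi))
    if (reml) {
      ld2 <- determinant(XtViX, logarithm = TRUE)
      nll <- nll + 0.5 * (as.numeric(ld2$modulus) - ncol(X) * log(2 * pi))
    }
    if (!is.finite(nll)) return(1e10)
    nll
  }

  if (length(est_names) > 0) {
    w0 <- log(vapply(est_names, function(nm) {
      switch(nm, rho = 5, vy / (length(est_names)))
    }, numeric(1)))
    opt <- stats::optim(w0, obj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (opt$convergence != 0) {
      warning("variance optimisation did not fully converge (code ",
              opt$convergence, ")")
    }
    w_hat <- opt$par
    nll <- opt$value
  } else {
    w_hat <- numeric(0)
    nll <- obj(w_hat)
  }
  th <- theta_full(w_hat)

  # final GLS pass for beta and its covariance
  XtViX <- matrix(0, ncol(X), ncol(X)); XtViy <- numeric(ncol(X))
  for (bi in block_info) {
    V <- .block_cov(length(bi$ix), bi$year, bi$t, th)
    ch <- chol(V)
    Xi <- backsolve(ch, bi$X, transpose = TRUE)
    yi <- backsolve(ch, bi$y, transpose = TRUE)
    XtViX <- XtViX + crossprod(Xi)
    XtViy <- XtViy + crossprod(Xi, yi)
  }
  vcov_beta <- solve(XtViX)
  beta <- drop(vcov_beta %*% XtViy)
  names(beta) <- colnames(X)
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  structure(list(
    beta = beta, se = se,
    ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se, z = z,
    varcomp = th, loglik = -nll, vcov_beta = vcov_beta,
    fitted = drop(X %*% beta), y = y, X = X,
    individual = individual, individual_year = individual_year,
    times = times, components = components, reml = reml
  ), class = "wt_lmm")
}

#' @export
print.wt_lmm <- function(x, ...) {
  cat("<wt_lmm> logLik", round(x$loglik, 2), "\n")
  tab <- data.frame(estimate = x$beta,
                    ci = sprintf("%.2f to %.2f", x$ci_lo, x$ci_hi),
                    z = round(x$z, 2))
  print(tab)
  vc <- x$varcomp
  cat(sprintf("variances: individual %.4g, individual-year %.4g, OU %.4g (range %.3g d), residual %.4g\n",
              vc$s2_id, vc$s2_idyear, vc$s2_ou, vc$rho, vc$s2_e))
  cat(sprintf("marginal R2 = %.3f\n", marginal_r2(x)))
  invisible(x)
}

#' Marginal R-squared of a mixed model
#'
#' Proportion of total variance attributable to the fixed effects:
#' `var(X beta) / (var(X beta) + all random-intercept variances + OU
#' variance + residual variance)`. Also accepts a bare list with components
#' `var_fixed`, `var_random`, `var_residual` for hand calculations.
#'
#' @param fit A `wt_lmm` fit, or a list of variance components.
#' @return A proportion in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  if (inherits(fit, "wt_lmm")) {
    vf <- stats::var(fit$fitted) * (length(fit$fitted) - 1) / length(fit$fitted)
    vc <- fit$varcomp
    vr <- vc$s2_id + vc$s2_idyear + vc$s2_ou
    ve <- vc$s2_e
  } else {
    vf <- fit$var_fixed; vr <- fit$var_random; ve <- fit$var_residual
  }
  tot <- vf + vr + ve
  if (tot <= 0) stop("zero total variance", call. = FALSE)
  vf / tot
}
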