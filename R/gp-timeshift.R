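# Gaussian-process comparison of ortholog expression kinetics.
#
# Model: standardized log2 expression y(t) ~ GP(0, k) + white noise, with the
# neural-network covariance k(x, x') = sf2 * asin( x~' D x~ / sqrt((1 + x~' D
# x~)(1 + x~'' D x~'')) ), x~ = [1, x], D = diag(1/l^2).  Four hyperparameters:
# length scale l, signal variance sf2, noise variance sn2 (bounded to
# [eps, 1] because the data are standardized) and, in the shared cross-species
# model only, a time shift dt in [-24, 24] h added to the second species'
# time points.  Hyperparameters are set by MAP (marginal likelihood times
# Gamma hyperpriors); the shared and independent models are compared by a
# Bayes factor of plug-in marginal likelihoods, BF > 10 calling "shared".
#
# Time is rescaled to the unit interval (hours / 72) before entering the
# covariance, so the length-scale prior Gamma(6, 30) (mode 5/30) refers to a
# fraction of the observed 72 h range.

TIME_SCALE_HOURS <- 72
SN2_EPS <- 1e-4
DT_BOUND_HOURS <- 24

#' Standardize a profile to zero mean and unit variance
#'
#' Affine transform of all observations of one gene's log-expression profile;
#' constant profiles are rejected (their SD is undefined for the model) and
#' callers are expected to skip such genes.
#'
#' @param values numeric vector of (log) expression observations, length >= 2.
#' @return numeric vector with mean 0 and SD 1.
#' @export
standardize_profile <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop("need at least 2 observations to standardize")
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("constant profile: standard deviation is zero; skip this gene")
  (v - mean(v)) / s
}

#' Neural-network covariance function
#'
#' `k(x, x') = sf2 * asin( s (1 + x x') / sqrt((1 + s (1 + x^2))(1 + s (1 +
#' x'^2))) )` with `s = 1 / l^2`, i.e. the arcsine kernel on inputs augmented
#' by a unit value.  Vector inputs produce the full cross-covariance matrix.
#'
#' @param x,x2 rescaled time inputs (numeric vectors).
#' @param l length scale (> 0), in rescaled-time units.
#' @param sf2 signal variance (> 0).
#' @return covariance value (scalar if both inputs are scalars, else a
#'   `length(x) x length(x2)` matrix).
#' @export
nn_covariance <- function(x, x2, l, sf2) {
  if (l <= 0 || sf2 <= 0) stop("`l` and `sf2` must be positive")
  s <- 1 / l^2
  rx <- sqrt(1 + s * (1 + x^2))
  rx2 <- sqrt(1 + s * (1 + x2^2))
  arg <- (s * (1 + tcrossprod(x, x2))) / tcrossprod(rx, rx2)
  arg[arg > 1] <- 1
  arg[arg < -1] <- -1
  k <- sf2 * asin(arg)
  if (length(x) == 1L && length(x2) == 1L) drop(k) else k
}

# Cholesky with escalating diagonal jitter (1e-8 -> 1e-4).
chol_jitter <- function(C, gene_id = NULL) {
  jit <- 1e-8
  di <- seq.int(1L, by = nrow(C) + 1L, length.out = nrow(C))
  repeat {
    Cj <- C
    Cj[di] <- Cj[di] + jit
    L <- tryCatch(chol(Cj), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    if (jit >= 1e-4)
      stop(sprintf("Cholesky factorization failed%s even with jitter %g",
                   if (is.null(gene_id)) "" else paste0(" for gene ", gene_id),
                   jit))
    jit <- jit * 10
  }
}

#' Gaussian-process log marginal likelihood
#'
#' `log N(Y; 0, K + sn2 I)` for the zero-mean GP with neural-network
#' covariance, computed through a jittered Cholesky factorization.
#'
#' @param X rescaled time inputs.
#' @param Y observations (same length as `X`).
#' @param h hyperparameter list with elements `l`, `sf2`, `sn2`.
#' @param gene_id optional id used in error messages.
#' @return the log marginal likelihood (scalar).
#' @export
gp_log_marginal <- function(X, Y, h, gene_id = NULL) {
  n <- length(X)
  stopifnot(n == length(Y), n >= 1L)
  K <- nn_covariance(X, X, h$l, h$sf2)
  if (n == 1L) K <- matrix(K, 1L, 1L)
  di <- seq.int(1L, by = n + 1L, length.out = n)
  K[di] <- K[di] + h$sn2
  cf <- chol_jitter(K, gene_id)
  L <- cf$L
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  -0.5 * sum(Y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

#' Log density of the hyperparameter priors
#'
#' `l ~ Gamma(6, 30)` and `sf2 ~ Gamma(10, 10)` (shape-rate), `sn2 ~
#' Gamma(2, 1/noise_mode)` truncated to `[1e-4, 1]` so that its mode equals
#' `noise_mode`, the average of the replicate variances, and its support
#' respects the standardization of the data; the time shift `dt`, when
#' present, carries a flat prior on \[-24, 24\] h.  Hyperparameters outside
#' the admissible region return `-Inf` rather than an error.
#'
#' @param h list with `l`, `sf2`, `sn2` and optionally `dt` (hours).
#' @param noise_mode mode of the noise-variance prior, in (0, 1].
#' @return the summed log prior density (scalar, possibly `-Inf`).
#' @export
hyperprior_logdensity <- function(h, noise_mode) {
  stopifnot(noise_mode > 0, noise_mode <= 1)
  if (!is.finite(h$l) || !is.finite(h$sf2) || !is.finite(h$sn2) ||
      h$l <= 0 || h$sf2 <= 0 || h$sn2 < SN2_EPS || h$sn2 > 1)
    return(-Inf)
  rate <- 1 / noise_mode
  lp <- dgamma(h$l, shape = 6, rate = 30, log = TRUE) +
    dgamma(h$sf2, shape = 10, rate = 10, log = TRUE) +
    dgamma(h$sn2, shape = 2, rate = rate, log = TRUE) -
    log(pgamma(1, 2, rate = rate) - pgamma(SN2_EPS, 2, rate = rate))
  if (!is.null(h$dt)) {
    if (abs(h$dt) > DT_BOUND_HOURS) return(-Inf)
    lp <- lp + log(1 / (2 * DT_BOUND_HOURS))
  }
  lp
}

#' Noise-prior mode from replicate scatter
#'
#' Mean over time points of the sample variance across the observations that
#' share a time point, clamped to `[1e-3, 1]` so it is a valid prior mode for
#' standardized data.
#'
#' @param X time inputs (any scale; only used for grouping).
#' @param Y standardized observations.
#' @return scalar noise mode in (0, 1].
#' @export
replicate_noise_mode <- function(X, Y) {
  v <- tapply(Y, X, function(y) if (length(y) >= 2L) var(y) else NA_real_)
  m <- mean(v, na.rm = TRUE)
  if (!is.finite(m)) m <- 0.1
  min(max(m, 1e-3), 1)
}

# MAP objective (log marginal + log hyperprior) at rescaled inputs `xs`.
# Non-finite priors and factorization failures (extreme hyperparameters
# proposed during line searches) yield -Inf: infeasible, not an error.
map_objective <- function(l, sf2, sn2, xs, y, noise_mode, dt = NULL) {
  h <- list(l = l, sf2 = sf2, sn2 = sn2, dt = dt)
  lp <- hyperprior_logdensity(h, noise_mode)
  if (!is.finite(lp)) return(-Inf)
  lm <- tryCatch(gp_log_marginal(xs, y, h), error = function(e) -Inf)
  if (!is.finite(lm)) return(-Inf)
  lm + lp
}

new_gpfit <- function(h, xs, y, x_hours, noise_mode, log_map) {
  structure(list(
    hyperparams = h,
    log_marginal = gp_log_marginal(xs, y, h),
    log_map_objective = log_map,
    x = xs, x_hours = x_hours, y = y, noise_mode = noise_mode),
    class = "GPFit")
}

#' @export
print.GPFit <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf("GPFit: l=%.4g sf2=%.4g sn2=%.4g%s  logML=%.3f  MAP obj=%.3f\n",
              h$l, h$sf2, h$sn2,
              if (is.null(h$dt)) "" else sprintf(" dt=%gh", h$dt),
              x$log_marginal, x$log_map_objective))
  invisible(x)
}

#' Fit a GP profile model by MAP hyperparameter estimation
#'
#' Maximizes log marginal likelihood plus log hyperprior density over
#' (l, sf2, sn2).  A coarse grid pre-scan selects promising starting points
#' (always including the prior modes), which are refined by quasi-Newton
#' (BFGS) ascent in transformed coordinates (log l, log sf2, logit-scaled
#' sn2); the best refined optimum is returned.
#'
#' @param X time points in hours (one entry per observation; replicates
#'   appear as repeated times).
#' @param Y standardized log-expression observations.
#' @param noise_mode mode of the noise-variance prior; defaults to
#'   [replicate_noise_mode()] of the data.
#' @param restarts number of optimizer starting points (>= 1).
#' @param seed integer seed (start-point jitter), for reproducibility.
#' @param dt optional time shift (hours) recorded in the fit; the shift must
#'   already be applied to `X` by the caller ([fit_shared()] does this).
#' @return a `GPFit` object.
#' @export
fit_gp_map <- function(X, Y, noise_mode = NULL, restarts = 3, seed = 1,
                       dt = NULL) {
  stopifnot(length(X) == length(Y), length(X) >= 2L, restarts >= 1)
  if (is.null(noise_mode)) noise_mode <- replicate_noise_mode(X, Y)
  xs <- X / TIME_SCALE_HOURS
  eps <- SN2_EPS

  to_h <- function(th) list(l = exp(th[1L]), sf2 = exp(th[2L]),
                            sn2 = eps + (1 - eps) * plogis(th[3L]), dt = dt)
  neg <- function(th) {
    h <- to_h(th)
    v <- map_objective(h$l, h$sf2, h$sn2, xs, Y, noise_mode, dt)
    if (!is.finite(v)) 1e10 else -v   # finite penalty keeps BFGS line searches alive
  }
  to_th <- function(l, sf2, sn2) c(log(l), log(sf2),
                                   qlogis(min(max((sn2 - eps) / (1 - eps), 1e-6), 1 - 1e-6)))

  # coarse pre-scan of the admissible box
  grid <- expand.grid(l = exp(seq(log(0.04), log(1.5), length.out = 6)),
                      sf2 = exp(seq(log(0.1), log(4), length.out = 6)),
                      sn2 = unique(c(0.01, 0.05, 0.1, 0.25, 0.5, 0.9, noise_mode)))
  gobj <- vapply(seq_len(nrow(grid)), function(i)
    map_objective(grid$l[i], grid$sf2[i], grid$sn2[i], xs, Y, noise_mode, dt),
    0)
  ord <- order(gobj, decreasing = TRUE)

  starts <- list(to_th(5 / 30, 0.9, noise_mode))       # prior modes
  for (i in head(ord, max(restarts - 1L, 1L)))
    starts <- c(starts, list(to_th(grid$l[i], grid$sf2[i], grid$sn2[i])))
  if (restarts > length(starts)) {
    jit <- withr::with_seed(as.integer(seed), {
      lapply(seq_len(restarts - length(starts)), function(j)
        to_th(rgamma(1, 6, 30), rgamma(1, 10, 10),
              min(max(rgamma(1, 2, 1 / noise_mode), eps), 1)))
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      optim(th0, neg, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimizer restarts failed; inputs: n=", length(Y),
         " noise_mode=", signif(noise_mode, 3))
  h <- to_h(best$par)
  # never return an optimum below the best scanned grid point
  if (-best$value < max(gobj)) {
    i <- ord[1L]
    h <- list(l = grid$l[i], sf2 = grid$sf2[i], sn2 = grid$sn2[i], dt = dt)
    best$value <- -gobj[i]
  }
  new_gpfit(h, xs, Y, X, noise_mode, -best$value)
}

#' Posterior predictive mean and variance
#'
#' `mu* = k(X, x*)' (K + sn2 I)^-1 Y` and `sigma*^2 = k(x*, x*) - k(X, x*)'
#' (K + sn2 I)^-1 k(X, x*)`, with small negative variances (numerical noise
#' down to -1e-10) clamped to zero.  Prediction times far outside the
#' observed design (beyond \[-24, 96\] h) trigger an extrapolation warning.
#'
#' @param fit a `GPFit`.
#' @param x_star prediction times in hours.
#' @return data.frame with columns `time`, `mean`, `var` (empty for empty
#'   `x_star`).
#' @export
gp_predict <- function(fit, x_star) {
  stopifnot(inherits(fit, "GPFit"))
  if (length(x_star) == 0L)
    return(data.frame(time = numeric(), mean = numeric(), var = numeric()))
  if (any(x_star < -24 | x_star > 96))
    warning("prediction times outside [-24, 96] h: extrapolating")
  h <- fit$hyperparams
  xs <- fit$x
  n <- length(xs)
  K <- nn_covariance(xs, xs, h$l, h$sf2)
  cf <- chol_jitter(K + diag(h$sn2, n))
  L <- cf$L
  xss <- x_star / TIME_SCALE_HOURS
  ks <- nn_covariance(xs, xss, h$l, h$sf2)
  ks <- matrix(ks, nrow = n)
  alpha <- backsolve(L, forwardsolve(t(L), fit$y))
  mu <- drop(crossprod(ks, alpha))
  v <- forwardsolve(t(L), ks)
  kss <- vapply(xss, function(z) nn_covariance(z, z, h$l, h$sf2), 0)
  s2 <- kss - colSums(v^2)
  s2[s2 > -1e-10 & s2 < 0] <- 0
  data.frame(time = x_star, mean = mu, var = s2)
}

#' Fit the shared cross-species GP with a time-shift grid
#'
#' For each candidate shift `dt` in `dt_grid`, pools the first species'
#' observations `(x, y)` with the second species' observations `(x + dt, y)`
#' and fits one GP by [fit_gp_map()]; the fit with the best MAP objective
#' wins and its grid value becomes `dt_hat`.  Sign convention: `dt` is added
#' to the mouse time points, so a positive `dt_hat` means the mouse profile
#' runs ahead of (leads) the human profile on the shared clock.
#'
#' @param Xh,Yh human times (hours) and standardized observations.
#' @param Xm,Ym mouse times (hours) and standardized observations.
#' @param dt_grid candidate shifts in hours, each within \[-24, 24\].
#' @param noise_mode shared noise-prior mode; defaults to the mean of the two
#'   species' replicate noise modes.
#' @param restarts optimizer restarts per grid value.
#' @param seed integer seed.
#' @return a `GPFit` whose `hyperparams$dt` is the winning shift; extra
#'   fields `dt_grid` and `dt_objectives` record the profile over the grid.
#' @export
fit_shared <- function(Xh, Yh, Xm, Ym, dt_grid = seq(-24, 24, by = 2),
                       noise_mode = NULL, restarts = 2, seed = 1) {
  if (length(dt_grid) == 0L) stop("`dt_grid` must be non-empty")
  if (any(abs(dt_grid) > DT_BOUND_HOURS))
    stop("`dt_grid` must lie within [-24, 24] hours")
  if (is.null(noise_mode))
    noise_mode <- min(max(mean(c(replicate_noise_mode(Xh, Yh),
                                 replicate_noise_mode(Xm, Ym))), 1e-3), 1)
  best <- NULL
  objs <- numeric(length(dt_grid))
  for (i in seq_along(dt_grid)) {
    dt <- dt_grid[i]
    fit <- fit_gp_map(c(Xh, Xm + dt), c(Yh, Ym), noise_mode = noise_mode,
                      restarts = restarts, seed = derive_seed(seed, paste0("dt", dt)),
                      dt = dt)
    objs[i] <- fit$log_map_objective
    if (is.null(best) || fit$log_map_objective > best$log_map_objective)
      best <- fit
  }
  best$dt_grid <- dt_grid
  best$dt_objectives <- objs
  best
}

#' Bayes-factor comparison of shared vs. independent kinetics
#'
#' Fits the shared (time-shifted, pooled) model and the two independent
#' per-species models, and forms `BF = exp(logML_shared - logML_human -
#' logML_mouse)` from the GP marginal likelihoods at the MAP hyperparameters
#' (plug-in/empirical-Bayes, not the MAP objectives).  `BF > 10` calls the
#' pair "shared".
#'
#' @inheritParams fit_shared
#' @param pair_id label carried into the result (and error messages).
#' @param bf_threshold Bayes-factor threshold for the "shared" call.
#' @return a one-row data.frame (class `BayesFactorResult`): `pair_id`,
#'   `logml_shared`, `logml_human`, `logml_mouse`, `log_bf`, `bf`, `dt_hat`,
#'   `call`.
#' @export
bayes_factor_pair <- function(Xh, Yh, Xm, Ym, dt_grid = seq(-24, 24, by = 2),
                              noise_mode = NULL, restarts = 2, seed = 1,
                              pair_id = "pair", bf_threshold = 10) {
  res <- tryCatch({
    fit_h <- fit_gp_map(Xh, Yh, restarts = max(restarts, 2),
                        seed = derive_seed(seed, "human"))
    fit_m <- fit_gp_map(Xm, Ym, restarts = max(restarts, 2),
                        seed = derive_seed(seed, "mouse"))
    fit_s <- fit_shared(Xh, Yh, Xm, Ym, dt_grid = dt_grid,
                        noise_mode = noise_mode, restarts = restarts,
                        seed = seed)
    log_bf <- fit_s$log_marginal - fit_h$log_marginal - fit_m$log_marginal
    data.frame(pair_id = pair_id,
               logml_shared = fit_s$log_marginal,
               logml_human = fit_h$log_marginal,
               logml_mouse = fit_m$log_marginal,
               log_bf = log_bf, bf = exp(log_bf),
               dt_hat = fit_s$hyperparams$dt,
               call = if (log_bf > log(bf_threshold)) "shared" else "different",
               stringsAsFactors = FALSE)
  }, error = function(e)
    stop(sprintf("pair %s: %s", pair_id, conditionMessage(e)), call. = FALSE))
  class(res) <- c("BayesFactorResult", class(res))
  res
}

#' Batch Bayes-factor comparison over an ortholog map
#'
#' Extracts each ortholog pair's profiles from the two expression matrices,
#' log2(RPKM + 1)-transforms and standardizes them per species (replicates
#' enter as separate observations), and runs [bayes_factor_pair()].  Genes
#' with constant profiles in either species are skipped (reported via the
#' `skipped` attribute).
#'
#' @param tc_h,tc_m `TimeCourseMatrix` for the two species.
#' @param orthologs data.frame with `human_gene`, `mouse_gene`.
#' @param dt_grid candidate time shifts (hours).
#' @param restarts optimizer restarts per fit.
#' @param seed integer seed; each pair gets a derived seed.
#' @param bf_threshold Bayes-factor threshold for the "shared" call.
#' @return data.frame of per-pair results with columns as in
#'   [bayes_factor_pair()] plus `human_gene`, `mouse_gene`.
#' @export
bayes_factor_table <- function(tc_h, tc_m, orthologs,
                               dt_grid = seq(-24, 24, by = 2),
                               restarts = 2, seed = 1, bf_threshold = 10) {
  stopifnot(inherits(tc_h, "TimeCourseMatrix"), inherits(tc_m, "TimeCourseMatrix"))
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(orthologs))) {
    hg <- orthologs$human_gene[i]
    mg <- orthologs$mouse_gene[i]
    if (!hg %in% rownames(tc_h$values) || !mg %in% rownames(tc_m$values)) {
      skipped <- c(skipped, paste0(hg, "/", mg))
      next
    }
    yh_raw <- log2(tc_h$values[hg, ] + 1)
    ym_raw <- log2(tc_m$values[mg, ] + 1)
    if (sd(yh_raw) == 0 || sd(ym_raw) == 0) {
      skipped <- c(skipped, paste0(hg, "/", mg))
      next
    }
    r <- bayes_factor_pair(tc_h$col_time, standardize_profile(yh_raw),
                           tc_m$col_time, standardize_profile(ym_raw),
                           dt_grid = dt_grid, restarts = restarts,
                           seed = derive_seed(seed, paste0(hg, mg)),
                           pair_id = paste0(hg, "/", mg),
                           bf_threshold = bf_threshold)
    r$human_gene <- hg
    r$mouse_gene <- mg
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pair_id = character(), logml_shared = numeric(),
                      logml_human = numeric(), logml_mouse = numeric(),
                      log_bf = numeric(), bf = numeric(), dt_hat = numeric(),
                      call = character(), human_gene = character(),
                      mouse_gene = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
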