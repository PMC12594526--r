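#' Settings for the membrane-fraction MCMC fit
#'
#' Uniform box priors on (m, dilF, locErr, fCut), an adaptive random-walk
#' Metropolis sampler, and a sampled observation-variance scale giving a
#' mean-squared-error likelihood on histogram bin probabilities. Default
#' bounds contain the plausible microscope/geometry values: m in [0, 1],
#' dilF in [1, 1.6], locErr in [0, 80] nm, fCut in [0, R] (the fCut upper
#' bound is resolved against R at fit time when NA).
#'
#' @param bounds 4 x 2 matrix of lower/upper bounds, rows m, dilF, locErr,
#'   fCut.
#' @param n_iter chain length.
#' @param burn_frac fraction discarded as burn-in (chain length must be at
#'   least 10 times the burn-in count).
#' @param seed RNG seed for the chain.
#' @param bin histogram bin width the settings are intended for.
#' @param h_frac model grid step as a fraction of R.
#' @param adapt_every,adapt_start proposal-covariance adaptation cadence.
#' @return An object of class \code{mb_fit_settings}.
#' @export
mb_fit_settings <- function(bounds = NULL, n_iter = 12000,
                            burn_frac = 0.1, seed = 1, bin = 0.04,
                            h_frac = 1 / 200,
                            adapt_every = 100, adapt_start = 300) {
  if (is.null(bounds)) {
    bounds <- rbind(m = c(0, 1), dilF = c(1, 1.6), locErr = c(0, 80),
                    fCut = c(0, NA))
  }
  bounds <- as.matrix(bounds)
  rownames(bounds) <- c("m", "dilF", "locErr", "fCut")
  if (any(!is.finite(bounds[1:3, ])))
    stop("bounds must be finite")
  if (bounds["m", 1] < 0 || bounds["m", 2] > 1)
    stop("m bounds must be within [0, 1]")
  n_burn <- ceiling(n_iter * burn_frac)
  if (n_iter < 10 * n_burn)
    stop("chain length must be at least 10x the burn-in count")
  structure(list(bounds = bounds, n_iter = as.integer(n_iter),
                 burn_frac = burn_frac, seed = seed, bin = bin,
                 h_frac = h_frac,
                 adapt_every = as.integer(adapt_every),
                 adapt_start = as.integer(adapt_start)),
            class = "mb_fit_settings")
}

#' Estimate the membrane-bound percentage by MCMC
#'
#' Fits the projected membrane/cytoplasm mixture model to an absolute
#' xNorm histogram. The objective is the mean-squared error between
#' observed and model bin probabilities; the observation variance is
#' treated as an unknown scale with a conjugate inverse-gamma update, so
#' the likelihood at parameters theta is Gaussian with the sampled scale.
#' Priors are uniform on the settings box. The proposal is an adaptive
#' random-walk Metropolis whose covariance is tuned from the chain
#' history. MB% is reported as the posterior mean of m (in percent) with a
#' central 95% credible interval.
#'
#' @param histogram an absolute \code{xnorm_histogram} (from
#'   [build_xnorm_histogram()] or [read_xnorm_histogram()]).
#' @param R cell half-width (population mean), um.
#' @param settings an [mb_fit_settings()].
#' @param prior_only if TRUE the likelihood is switched off (sampler
#'   sanity checks only).
#' @return An \code{mb_fit_result}: posterior draws, \code{mb_percent},
#'   \code{ci} (95%), per-bin residuals at the posterior mean, acceptance
#'   rate, split-chain convergence diagnostic \code{rhat} on m, and any
#'   diagnostic warnings.
#' @export
fit_mb <- function(histogram, R, settings = mb_fit_settings(),
                   prior_only = FALSE) {
  stopifnot(inherits(histogram, "xnorm_histogram"),
            inherits(settings, "mb_fit_settings"))
  if (!histogram$absolute)
    stop("fit_mb requires an absolute (folded) xNorm histogram")
  if (abs(sum(histogram$prob) - 1) > 1e-6)
    stop("histogram probabilities are not normalized")
  edges <- c(histogram$bin_lo, histogram$bin_hi[length(histogram$bin_hi)])
  obs <- histogram$prob
  nb <- length(obs)

  bounds <- settings$bounds
  if (is.na(bounds["fCut", 2])) bounds["fCut", 2] <- R
  lo <- bounds[, 1]; hi <- bounds[, 2]
  widths <- hi - lo
  h <- R * settings$h_frac

  # Whitening transform from the bootstrap bin covariance, when the
  # histogram carries one: the objective becomes the squared Mahalanobis
  # misfit, so the likelihood respects both the per-bin variances and the
  # bin-to-bin correlations induced by track clustering and the
  # multinomial constraint. A small ridge stabilizes the inverse.
  Wmat <- NULL
  if (!is.null(histogram$boot_cov)) {
    # inverse-Wishart small-sample factor: the inverse of a covariance
    # estimated from n_boot replicates overstates precision by
    # (n_boot - 1) / (n_boot - nb - 2)
    nB <- histogram$n_boot %||% 100
    cb <- if (nB > nb + 2) (nB - 1) / (nB - nb - 2) else 2
    Sg <- cb * histogram$boot_cov +
      diag(0.05 * mean(diag(histogram$boot_cov)), nb)
    Wmat <- backsolve(chol(Sg), diag(nb), transpose = TRUE)
  }
  sse_of <- function(theta) {
    q <- model_bin_probabilities(
      mb_params(theta[1], theta[2], theta[3], theta[4]), R, edges,
      absolute = TRUE, h = h)
    r <- obs - q
    if (is.null(Wmat)) sum(r^2) else sum((Wmat %*% r)^2)
  }

  set.seed(settings$seed)
  n <- settings$n_iter
  d <- 4L
  chain <- matrix(NA_real_, n, d,
                  dimnames = list(NULL, rownames(bounds)))
  cur <- lo + widths / 2
  if (!prior_only) {
    # multi-start simplex minimization of the SSE to seed the chain in
    # the global basin (the posterior can have local modes in which a
    # random-walk chain started far away gets trapped)
    pen_sse <- function(theta) {
      if (any(theta < lo | theta > hi)) return(1e9)
      sse_of(theta)
    }
    # vary both the mixture weight and the focal cut across starts: the
    # likelihood can be multimodal along the m-fCut trade-off (for data
    # without a defocus signature, fCut = 0 and fCut = R fit identically)
    starts <- list()
    for (fm in c(0.15, 0.5, 0.85))
      for (ff in c(0.05, 0.5, 0.95))
        starts[[length(starts) + 1L]] <-
          c(lo[1] + fm * widths[1], lo[2] + widths[2] / 3,
            lo[3] + widths[3] / 3, lo[4] + ff * widths[4])
    opts <- lapply(starts, function(s)
      stats::optim(s, pen_sse, control = list(maxit = 250,
                                              reltol = 1e-10)))
    cur <- opts[[which.min(vapply(opts, `[[`, numeric(1),
                                  "value"))]]$par
    cur <- pmin(pmax(cur, lo), hi)
  }
  cur_sse <- if (prior_only) 0 else sse_of(cur)
  # Observation-variance prior. When the histogram carries bootstrap SEMs
  # the scale prior is anchored at their mean square with weight n0 = nb,
  # so the likelihood width reflects the actual sampling noise of the bin
  # probabilities (a scale that merely tracks the achieved MSE lets the
  # sampler reward overfitting of bin noise by the extra mixture
  # flexibility). Without SEMs the scale is weakly initialized from the
  # starting misfit.
  if (!is.null(Wmat)) {
    s20 <- 1                    # whitened residuals have unit variance
    n0 <- nb
  } else if (!is.null(histogram$sem) && any(histogram$sem > 0)) {
    s20 <- mean(histogram$sem^2)
    n0 <- nb
  } else {
    s20 <- max(cur_sse / nb, 1e-12)
    n0 <- 0.01
  }
  C <- diag((widths / 50)^2)
  cholC <- chol(C)
  n_acc <- 0L
  for (i in seq_len(n)) {
    # conjugate update of the observation-variance scale
    s2 <- 1 / rgamma(1, shape = (n0 + nb) / 2,
                     rate = (n0 * s20 + cur_sse) / 2)
    s2 <- max(s2, 1e-14)
    prop <- cur + drop(rnorm(d) %*% cholC)
    if (all(prop >= lo & prop <= hi)) {
      prop_sse <- if (prior_only) 0 else sse_of(prop)
      log_alpha <- (cur_sse - prop_sse) / (2 * s2)
      if (log(runif(1)) < log_alpha) {
        cur <- prop
        cur_sse <- prop_sse
        n_acc <- n_acc + 1L
      }
    }
    chain[i, ] <- cur
    if (i >= settings$adapt_start && i %% settings$adapt_every == 0L) {
      win <- seq.int(max(1L, floor(i / 2)), i)   # drop early transient
      Cn <- 2.38^2 / d * (stats::cov(chain[win, , drop = FALSE]) +
                            diag(1e-10, d))
      ch <- try(chol(Cn), silent = TRUE)
      if (!inherits(ch, "try-error")) cholC <- ch
    }
  }

  n_burn <- ceiling(n * settings$burn_frac)
  draws <- chain[(n_burn + 1L):n, , drop = FALSE]
  acc_rate <- n_acc / n
  warnings <- character(0)
  if (!prior_only && (acc_rate < 0.05 || acc_rate > 0.95))
    warnings <- c(warnings, sprintf(
      "acceptance rate %.3f outside [0.05, 0.95] after adaptation",
      acc_rate))
  rhat <- split_rhat(draws[, "m"])
  if (is.finite(rhat) && rhat > 1.05)
    warnings <- c(warnings,
                  sprintf("split-chain diagnostic on m is %.3f > 1.05",
                          rhat))
  theta_hat <- colMeans(draws)
  resid <- if (prior_only) rep(NA_real_, nb) else
    obs - model_bin_probabilities(
      mb_params(theta_hat[1], theta_hat[2], theta_hat[3], theta_hat[4]),
      R, edges, absolute = TRUE, h = h)

  structure(list(draws = draws,
                 mb_percent = 100 * mean(draws[, "m"]),
                 ci = 100 * unname(quantile(draws[, "m"],
                                            c(0.025, 0.975))),
                 theta_hat = theta_hat, residuals = resid,
                 acceptance = acc_rate, rhat = rhat,
                 warnings = warnings, R = R, edges = edges,
                 settings = settings),
            class = "mb_fit_result")
}

# split-chain potential-scale-reduction diagnostic on a single chain
split_rhat <- function(x) {
  n2 <- floor(length(x) / 2)
  a <- x[seq_len(n2)]
  b <- x[seq.int(length(x) - n2 + 1L, length(x))]
  W <- (var(a) + var(b)) / 2
  B <- n2 * (mean(a) - mean(b))^2 / 2
  if (W <= 0) return(1)
  sqrt((n2 - 1) / n2 + B / (W * n2))
}

#' @export
print.mb_fit_result <- function(x, ...) {
  cat(sprintf("MB%% = %.1f [%.1f, %.1f] (95%% CI)\n", x$mb_percent,
              x$ci[1], x$ci[2]))
  cat(sprintf("  acceptance %.2f, split-chain diagnostic %.3f\n",
              x$acceptance, x$rhat))
  if (length(x$warnings)) cat("  warning:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Posterior-predictive envelope of the model density
#'
#' Evaluates the model mixture density over posterior draws and returns
#' the pointwise envelope, visualizing the xNorm range consistent with the
#' parameter uncertainty.
#'
#' @param result an \code{mb_fit_result}.
#' @param x_out evaluation grid in normalized units (|xNorm| in [0, 1]).
#' @param n_draws number of posterior draws to evaluate (thinned evenly).
#' @return data.frame with x, lower, upper, point (densities per
#'   normalized unit).
#' @export
posterior_predictive_band <- function(result,
                                      x_out = seq(0.01, 0.99,
                                                  length.out = 50),
                                      n_draws = 200) {
  stopifnot(inherits(result, "mb_fit_result"))
  draws <- result$draws
  if (nrow(draws) < 100)
    stop("need at least 100 post-burn-in draws")
  R <- result$R
  pick <- unique(round(seq(1, nrow(draws), length.out = n_draws)))
  eval_density <- function(theta) {
    pm <- predicted_marginal(
      mb_params(theta[1], theta[2], theta[3], theta[4]), R,
      x_out = x_out * R, h = R * result$settings$h_frac)
    # fold to |x| and convert to density per normalized unit
    pm2 <- predicted_marginal(
      mb_params(theta[1], theta[2], theta[3], theta[4]), R,
      x_out = -x_out * R, h = R * result$settings$h_frac)
    (pm$mixture + pm2$mixture) * R
  }
  curves <- vapply(pick, function(i) eval_density(draws[i, ]),
                   numeric(length(x_out)))
  data.frame(x = x_out,
             lower = apply(curves, 1, min),
             upper = apply(curves, 1, max),
             point = eval_density(result$theta_hat))
}

#' Check MB% robustness to sampler hyper-parameters
#'
#' Refits under each settings object and tabulates MB%; large spread (over
#' \code{flag_spread} percentage points) flags sensitivity, e.g. a bound
#' pinning the posterior.
#'
#' @param histogram absolute xNorm histogram.
#' @param R cell half-width, um.
#' @param settings_list list of [mb_fit_settings()].
#' @param normspots optional normalized spots; required when a settings
#'   object requests a different bin width than \code{histogram} has.
#' @param flag_spread spread (MB percentage points) above which the result
#'   is flagged.
#' @return data.frame of MB% and CI per setting, with attributes
#'   \code{spread} and \code{flagged}.
#' @export
check_hyperparameter_insensitivity <- function(histogram, R,
                                               settings_list,
                                               normspots = NULL,
                                               flag_spread = 2) {
  stopifnot(length(settings_list) >= 2)
  rows <- lapply(seq_along(settings_list), function(i) {
    s <- settings_list[[i]]
    hst <- histogram
    if (abs(s$bin - histogram$bin) > 1e-12) {
      if (is.null(normspots))
        stop("normspots needed to rebin the histogram to width ", s$bin)
      hst <- build_xnorm_histogram(normspots, bin = s$bin, n_boot = 100,
                                   absolute = TRUE)
    }
    fit <- fit_mb(hst, R, s)
    data.frame(setting = i, mb_percent = fit$mb_percent,
               ci_lo = fit$ci[1], ci_hi = fit$ci[2])
  })
  out <- do.call(rbind, rows)
  spread <- max(out$mb_percent) - min(out$mb_percent)
  attr(out, "spread") <- spread
  attr(out, "flagged") <- spread > flag_spread
  out
}
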