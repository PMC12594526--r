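#' Time-averaged mean-squared displacement of one track
#'
#' Overlapping-window time average: for lag k frames,
#' MSD(k dt) = mean over i of |r(t_i+k) - r(t_i)|^2 (2D), averaged over
#' the N = len - k available windows.
#'
#' @param track data.frame (or matrix) with columns frame, x, y; positions
#'   in um, consecutive frames (no gaps).
#' @param max_k largest lag in frames (default: track length - 1).
#' @param dt frame interval, s.
#' @return data.frame with lag (frames), tau (s), msd (um^2), n (windows
#'   averaged).
#' @export
time_averaged_msd <- function(track, max_k = NULL, dt = 0.0217) {
  track <- as.data.frame(track)
  stopifnot(all(c("frame", "x", "y") %in% names(track)))
  o <- order(track$frame)
  fr <- track$frame[o]
  if (length(fr) < 2L) stop("track too short")
  if (any(diff(fr) != 1L)) stop("track has frame gaps")
  x <- track$x[o]; y <- track$y[o]
  len <- length(x)
  if (is.null(max_k)) max_k <- len - 1L
  if (max_k > len - 1L) stop("max_k exceeds track length - 1")
  ks <- seq_len(max_k)
  msd <- vapply(ks, function(k) {
    dx <- x[(1 + k):len] - x[1:(len - k)]
    dy <- y[(1 + k):len] - y[1:(len - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = ks, tau = ks * dt, msd = msd, n = len - ks)
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD on tau over the first \code{n_points}
#' lags: MSD = 4 D tau + b. The intercept b collects the dynamic
#' (motion-blur) and static (localization-noise) errors,
#' b = -4 D dt / 3 + 4 sigma^2, so sigma is recovered as
#' sqrt((b + 4 D dt / 3) / 4) when the radicand is nonnegative.
#'
#' @param msd data.frame from [time_averaged_msd()].
#' @param dt frame interval, s.
#' @param n_points number of leading lags to fit (>= 2).
#' @return list with D (um^2/s; may be negative for noise-dominated
#'   tracks), b (um^2), sigma_loc (um or NA), sigma_ok flag.
#' @export
fit_track_D <- function(msd, dt = 0.0217, n_points = 3) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (nrow(msd) < n_points) stop("msd has fewer lags than n_points")
  d <- msd[seq_len(n_points), ]
  cf <- coef(lm(msd ~ tau, data = d))
  b <- unname(cf[1]); D <- unname(cf[2]) / 4
  rad <- (b + 4 * D * dt / 3) / 4
  list(D = D, b = b,
       sigma_loc = if (rad >= 0) sqrt(rad) else NA_real_,
       sigma_ok = rad >= 0)
}

#' Ensemble diffusion statistics over tracks
#'
#' Per-track D from the 3-point MSD fit; reports mean and SEM (SD divided
#' by sqrt of the number of tracks). Only tracks of at least
#' \code{min_len} frames qualify; negative per-track D values are retained
#' (truncation would bias the mean).
#'
#' @param tracks list of track data.frames (frame, x, y in um).
#' @param dt frame interval, s.
#' @param min_len minimum track length (frames) for diffusion analysis.
#' @param n_points MSD lags used in the per-track fit.
#' @return list with mean, sem, n, D (per-track vector), b (per-track
#'   intercepts).
#' @export
ensemble_D <- function(tracks, dt = 0.0217, min_len = 12, n_points = 3) {
  lens <- vapply(tracks, nrow, integer(1))
  use <- tracks[lens >= min_len]
  if (length(use) < 2L) stop("need >= 2 tracks of length >= ", min_len)
  fits <- lapply(use, function(tr)
    fit_track_D(time_averaged_msd(tr, max_k = n_points, dt = dt),
                dt = dt, n_points = n_points))
  D <- vapply(fits, `[[`, numeric(1), "D")
  b <- vapply(fits, `[[`, numeric(1), "b")
  list(mean = mean(D), sem = sd(D) / sqrt(length(D)), n = length(D),
       D = D, b = b)
}

#' Ensemble-averaged time-averaged MSD
#'
#' Unweighted mean of per-track time-averaged MSDs at each lag, over all
#' tracks long enough to contribute every requested lag.
#'
#' @param tracks list of track data.frames (frame, x, y in um).
#' @param max_k largest lag in frames.
#' @param dt frame interval, s.
#' @return data.frame with lag, tau, msd, n_tracks.
#' @export
eata_msd <- function(tracks, max_k, dt = 0.0217) {
  lens <- vapply(tracks, nrow, integer(1))
  use <- tracks[lens >= max_k + 1L]
  if (length(use) == 0L) stop("no track long enough for max_k = ", max_k)
  curves <- vapply(use, function(tr)
    time_averaged_msd(tr, max_k = max_k, dt = dt)$msd, numeric(max_k))
  if (max_k == 1L) curves <- matrix(curves, nrow = 1L)
  data.frame(lag = seq_len(max_k), tau = seq_len(max_k) * dt,
             msd = rowMeans(curves), n_tracks = length(use))
}

#' Gaussian fits to a diffusion-coefficient histogram
#'
#' Least-squares fit of one- or two-population Gaussian shapes to the
#' probability-density histogram of per-track D values
#' (Freedman-Diaconis binning). In two-population mode the fraction
#' \code{a} of the first (slow) population may be fixed, e.g. to an
#' independently estimated membrane-bound fraction.
#'
#' @param D vector of per-track diffusion coefficients (>= 100 values).
#' @param mode "one" or "two" populations.
#' @param fixed_a optional fixed first-population fraction in [0, 1];
#'   \code{fixed_a = 1} reduces the two-population form to one population.
#' @return list with coefficients (c, mu, sigma) or (c, a, mu1, sigma1,
#'   mu2, sigma2), fitted bin densities, residual norm, and the histogram.
#' @export
fit_D_histogram <- function(D, mode = c("one", "two"), fixed_a = NULL) {
  mode <- match.arg(mode)
  if (length(D) < 100) stop("need at least 100 D values")
  hh <- graphics::hist(D, breaks = "FD", plot = FALSE)
  df <- data.frame(x = hh$mids, dens = hh$density)
  mu0 <- mean(D); sd0 <- sd(D)
  if (mode == "one") {
    fit <- minpack.lm::nlsLM(
      dens ~ cc / (sig * sqrt(2 * pi)) * exp(-0.5 * (x - mu)^2 / sig^2),
      data = df, start = list(cc = 1, mu = mu0, sig = sd0),
      lower = c(1e-8, -Inf, 1e-8), upper = c(Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    co <- list(c = unname(cf["cc"]), mu = unname(cf["mu"]),
               sigma = unname(cf["sig"]))
  } else if (!is.null(fixed_a) && (fixed_a >= 1 - 1e-12 ||
                                   fixed_a <= 1e-12)) {
    # a single population carries all the weight: reduce exactly to the
    # one-population fit (the other component is unidentifiable)
    one <- fit_D_histogram(D, mode = "one")
    co1 <- one$coefficients
    if (fixed_a >= 1 - 1e-12) {
      co <- list(c = co1$c, a = 1, mu1 = co1$mu, sigma1 = co1$sigma,
                 mu2 = NA_real_, sigma2 = NA_real_)
    } else {
      co <- list(c = co1$c, a = 0, mu1 = NA_real_, sigma1 = NA_real_,
                 mu2 = co1$mu, sigma2 = co1$sigma)
    }
    return(list(mode = "two", coefficients = co, fitted = one$fitted,
                residual_norm = one$residual_norm,
                histogram = one$histogram))
  } else {
    # start with a dominant core and a minority fast tail; fall back to
    # alternative starts when the gradient is singular (near-degenerate
    # mixtures)
    q97 <- unname(quantile(D, 0.97))
    s2_0 <- max(sd(D[D > q97]), sd0 / 4)
    start_sets <- list(
      list(m1 = stats::median(D), s1 = sd0 / 2, m2 = q97, s2 = s2_0),
      list(m1 = unname(quantile(D, 0.25)), s1 = sd0 / 2,
           m2 = unname(quantile(D, 0.75)), s2 = sd0),
      list(m1 = mu0, s1 = sd0, m2 = mu0 + 2 * sd0, s2 = sd0 / 2))
    shape2 <- function(p, a) {
      # p = (cc, m1, s1, m2, s2)
      p[1] / sqrt(2 * pi) * (
        a / p[3] * exp(-0.5 * (df$x - p[2])^2 / p[3]^2) +
          (1 - a) / p[5] * exp(-0.5 * (df$x - p[4])^2 / p[5]^2))
    }
    # Levenberg-Marquardt on the raw residuals (robust to the parameter
    # degeneracy of near-single-population data)
    lm_fit <- function(a_free, a_fix = NULL) {
      best <- NULL
      for (start2 in start_sets) {
        p0 <- if (a_free) c(1, 0.9, unlist(start2)) else
          c(1, unlist(start2))
        res_fn <- if (a_free) {
          function(p) df$dens - shape2(p[-2], p[2])
        } else {
          function(p) df$dens - shape2(p, a_fix)
        }
        lo <- if (a_free) c(1e-8, 0, -Inf, 1e-8, -Inf, 1e-8) else
          c(1e-8, -Inf, 1e-8, -Inf, 1e-8)
        hi <- if (a_free) c(Inf, 1, Inf, Inf, Inf, Inf) else
          rep(Inf, 5)
        out <- tryCatch(minpack.lm::nls.lm(
          par = p0, fn = res_fn, lower = lo, upper = hi,
          control = minpack.lm::nls.lm.control(maxiter = 500)),
          error = function(e) NULL)
        if (!is.null(out) &&
            (is.null(best) || out$deviance < best$deviance))
          best <- out
      }
      if (is.null(best))
        stop("two-population fit did not converge from any start")
      best
    }
    if (is.null(fixed_a)) {
      out <- lm_fit(a_free = TRUE)
      a_hat <- out$par[2]
      pcoef <- out$par[-2]
    } else {
      stopifnot(fixed_a >= 0, fixed_a <= 1)
      out <- lm_fit(a_free = FALSE, a_fix = fixed_a)
      a_hat <- fixed_a
      pcoef <- out$par
    }
    co <- list(c = pcoef[1], a = a_hat, mu1 = pcoef[2],
               sigma1 = pcoef[3], mu2 = pcoef[4], sigma2 = pcoef[5])
    fitted_dens <- shape2(pcoef, a_hat)
    return(list(mode = mode, coefficients = co, fitted = fitted_dens,
                residual_norm = sqrt(sum((df$dens - fitted_dens)^2)),
                histogram = df))
  }
  fitted_dens <- stats::fitted(fit)
  list(mode = mode, coefficients = co, fitted = fitted_dens,
       residual_norm = sqrt(sum((df$dens - fitted_dens)^2)),
       histogram = df)
}

#' Adaptive maximum linking radius for particle tracking
#'
#' Converts a preliminary diffusion coefficient (estimated with a loose
#' 5-pixel linking radius) into the maximum linking distance in pixels:
#' ceiling(2 * sqrt(4 * D * dt) / pixel_size), at least 1 pixel. Twice the
#' per-frame RMS displacement, so genuine steps are linked while spurious
#' long jumps are excluded.
#'
#' @param D_5pix preliminary diffusion coefficient, um^2/s (>= 0).
#' @param dt frame interval, s.
#' @param pixel_size um per pixel.
#' @return Integer radius in pixels.
#' @export
adaptive_link_radius <- function(D_5pix, dt = 0.0217, pixel_size = 0.160) {
  if (any(D_5pix < 0)) stop("D_5pix must be >= 0")
  pmax(1L, as.integer(ceiling(2 * sqrt(4 * D_5pix * dt) / pixel_size)))
}
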