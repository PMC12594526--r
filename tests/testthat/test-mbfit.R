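test_that("settings validation enforces the prior box and burn-in rule", {
  expect_error(mb_fit_settings(bounds = rbind(m = c(-0.1, 1),
                                              dilF = c(1, 1.6),
                                              locErr = c(0, 80),
                                              fCut = c(0, 0.4))), "m bounds")
  expect_error(mb_fit_settings(burn_frac = 0.3), "10x")
  s <- mb_fit_settings()
  expect_true(all(s$bounds["m", ] == c(0, 1)))
})

test_that("noiseless model histograms are recovered to within 0.01", {
  R <- 0.45
  truth <- c(m = 0.7, dilF = 1.2, locErr = 30, fCut = 0.1)
  prob <- model_bin_probabilities(mb_params(0.7, 1.2, 30, 0.1), R,
                                  seq(0, 1, 0.04))
  h <- as_xnorm_hist(prob)
  tight <- rbind(m = c(0.5, 0.9), dilF = c(1.05, 1.35),
                 locErr = c(15, 45), fCut = c(0, 0.2))
  fit <- fit_mb(h, R, mb_fit_settings(bounds = tight, n_iter = 4000,
                                      seed = 2))
  expect_lt(abs(mean(fit$draws[, "m"]) - 0.7), 0.01)
  expect_true(all(fit$draws[, "m"] >= 0.5 & fit$draws[, "m"] <= 0.9))
  expect_lte(fit$ci[1], fit$mb_percent)
  expect_gte(fit$ci[2], fit$mb_percent)
})

test_that("under the prior alone the m-marginal is uniform on its box", {
  h <- as_xnorm_hist(rep(0.04, 25))
  fit <- fit_mb(h, 0.45, mb_fit_settings(n_iter = 8000, seed = 5),
                prior_only = TRUE)
  m <- fit$draws[, "m"]
  expect_lt(abs(mean(m) - 0.5), 0.08)
  expect_lt(abs(sd(m) - sqrt(1 / 12)), 0.05)
  expect_lt(abs(mean(m < 0.25) - 0.25), 0.1)
})

test_that("fixed seeds give identical chains", {
  R <- 0.45
  prob <- model_bin_probabilities(mb_params(0.8, 1.1, 20, 0), R,
                                  seq(0, 1, 0.04))
  h <- as_xnorm_hist(prob)
  s <- mb_fit_settings(n_iter = 800, seed = 9)
  f1 <- fit_mb(h, R, s)
  f2 <- fit_mb(h, R, s)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$mb_percent, f2$mb_percent)
})

test_that("input validation rejects unusable histograms", {
  h <- as_xnorm_hist(rep(0.04, 25))
  h$prob <- h$prob * 2
  expect_error(fit_mb(h, 0.45), "not normalized")
  hs <- as_xnorm_hist(rep(0.02, 50), absolute = FALSE)
  expect_error(fit_mb(hs, 0.45), "absolute")
})

test_that("posterior predictive band behaves like an envelope", {
  cfg <- sim_config(n_cells = 30, m_true = 0.93, seed = 51,
                    spots_per_cell = 800)
  pip <- run_xnorm_pipeline(cfg, n_boot = 100)
  fit <- fit_mb(pip$hist, pip$R_um, mb_fit_settings(n_iter = 3000,
                                                    seed = 3))
  band <- posterior_predictive_band(fit, n_draws = 150)
  expect_true(all(band$lower <= band$point + 1e-9))
  expect_true(all(band$upper >= band$point - 1e-9))

  # zero posterior variance collapses the band onto the point curve
  degen <- fit
  degen$draws <- matrix(rep(fit$theta_hat, each = 200), nrow = 200,
                        dimnames = list(NULL, colnames(fit$draws)))
  b0 <- posterior_predictive_band(degen, n_draws = 50)
  expect_equal(b0$lower, b0$point, tolerance = 1e-12)
  expect_equal(b0$upper, b0$point, tolerance = 1e-12)

  short <- fit
  short$draws <- fit$draws[1:50, , drop = FALSE]
  expect_error(posterior_predictive_band(short), "100")
})

test_that("the band tightens as the spot count grows", {
  widths <- vapply(c(150, 1500), function(spc) {
    cfg <- sim_config(n_cells = 30, m_true = 0.93, seed = 61,
                      spots_per_cell = spc)
    pip <- run_xnorm_pipeline(cfg, n_boot = 100)
    fit <- fit_mb(pip$hist, pip$R_um,
                  mb_fit_settings(n_iter = 3000, seed = 7))
    band <- posterior_predictive_band(fit, n_draws = 150)
    mean(band$upper - band$lower)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("MB% is insensitive to bin width but flags absurd bounds", {
  cfg <- sim_config(n_cells = 80, m_true = 0.93, seed = 71,
                    spots_per_cell = 3000)
  pip <- run_xnorm_pipeline(cfg, n_boot = 100)
  s04 <- mb_fit_settings(n_iter = 4000, seed = 11, bin = 0.04)
  s02 <- mb_fit_settings(n_iter = 4000, seed = 11, bin = 0.02)
  rep1 <- check_hyperparameter_insensitivity(
    pip$hist, pip$R_um, list(s04, s02), normspots = pip$normspots)
  expect_lt(attr(rep1, "spread"), 2)
  expect_false(attr(rep1, "flagged"))

  # identical settings twice: spread exactly zero
  rep0 <- check_hyperparameter_insensitivity(pip$hist, pip$R_um,
                                             list(s04, s04))
  expect_equal(attr(rep0, "spread"), 0)

  pin <- mb_fit_settings(bounds = rbind(m = c(0, 0.1), dilF = c(1, 1.6),
                                        locErr = c(0, 80),
                                        fCut = c(0, NA)),
                         n_iter = 3000, seed = 11)
  rep2 <- check_hyperparameter_insensitivity(pip$hist, pip$R_um,
                                             list(s04, pin))
  expect_true(attr(rep2, "flagged"))
})


test_that("without motion blur the cytoplasm-only fit stays near zero", {
  # control for the blur-compression deviation: with instantaneous
  # positions (n_sub = 1) the generator matches the projection model and
  # the all-cytoplasm boundary is recovered near zero
  cfg <- sim_config(n_cells = 60, m_true = 0, seed = 81, n_sub = 1,
                    spots_per_cell = 2500)
  pip <- run_xnorm_pipeline(cfg, n_boot = 100)
  fit <- fit_mb(pip$hist, pip$R_um,
                mb_fit_settings(n_iter = 4000, seed = 82))
  expect_lt(fit$mb_percent, 10)
})
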