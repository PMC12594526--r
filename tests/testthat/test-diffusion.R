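test_that("TA-MSD matches a brute-force double loop and closed forms", {
  # hand-sized track against the independent double-loop oracle
  set.seed(8)
  tr <- data.frame(frame = 0:4, x = c(0, 0.1, 0.05, 0.2, 0.15),
                   y = c(0, -0.05, 0.1, 0.05, 0))
  msd <- time_averaged_msd(tr, max_k = 4)
  expect_equal(msd$msd, brute_msd(tr, 4), tolerance = 1e-15)
  expect_equal(msd$n, 4:1)

  big <- data.frame(frame = 0:29, x = rnorm(30), y = rnorm(30))
  expect_equal(time_averaged_msd(big, max_k = 20)$msd,
               brute_msd(big, 20), tolerance = 1e-12)

  # stationary and ballistic closed forms
  st <- data.frame(frame = 0:9, x = 1, y = 2)
  expect_true(all(time_averaged_msd(st)$msd == 0))
  v <- 0.3; dt <- 0.0217
  bal <- data.frame(frame = 0:9, x = v * dt * (0:9), y = 0)
  mb <- time_averaged_msd(bal, dt = dt)
  expect_equal(mb$msd, (v * mb$lag * dt)^2, tolerance = 1e-12)

  gap <- data.frame(frame = c(0, 1, 3), x = 1:3, y = 1:3)
  expect_error(time_averaged_msd(gap), "gaps")
})

test_that("an exact linear MSD is fit to machine precision", {
  dt <- 0.0217
  msd <- data.frame(lag = 1:5, tau = (1:5) * dt,
                    msd = 4 * 0.05 * (1:5) * dt + 0.001, n = 10)
  fit <- fit_track_D(msd, dt = dt)
  expect_equal(fit$D, 0.05, tolerance = 1e-12)
  expect_equal(fit$b, 0.001, tolerance = 1e-12)
  expect_equal(fit$sigma_loc,
               sqrt((0.001 + 4 * 0.05 * dt / 3) / 4), tolerance = 1e-12)
  expect_error(fit_track_D(msd, n_points = 1), "n_points")
})

test_that("blurred noisy ensembles reproduce the error intercept", {
  set.seed(12)
  dt <- 0.0217
  trs <- simulate_point_tracks(3000, 14, D = 0.1, dt = dt, n_sub = 10,
                               sigma_loc = 0.02)
  ed <- ensemble_D(trs, dt = dt)
  b_th <- -4 * 0.1 * dt / 3 + 4 * 0.02^2
  expect_lt(abs(mean(ed$b) - b_th) / abs(b_th), 0.2)
  expect_lt(abs(ed$mean - 0.1), 3 * ed$sem)

  # stationary emitters: b tends to the static term, D to zero
  st <- ensemble_D(simulate_point_tracks(1500, 14, D = 0,
                                         sigma_loc = 0.02), dt = dt)
  expect_lt(abs(mean(st$b) - 4 * 0.02^2) / (4 * 0.02^2), 0.2)
  expect_lt(abs(st$mean), 3 * st$sem)
})

test_that("ensemble statistics are consistent across data splits", {
  set.seed(18)
  trs <- simulate_point_tracks(2000, 13, D = 0.0184, sigma_loc = 0.02)
  e1 <- ensemble_D(trs[1:1000])
  e2 <- ensemble_D(trs[1001:2000])
  expect_lt(abs(e1$mean - e2$mean), 3 * sqrt(e1$sem^2 + e2$sem^2))
  # identical tracks have zero SEM
  same <- ensemble_D(trs[c(1, 1, 1)][1:2])
  expect_equal(same$sem, 0)
})

test_that("EATA-MSD averages per-track curves", {
  st <- data.frame(frame = 0:12, x = 0, y = 0)
  expect_true(all(eata_msd(list(st, st), max_k = 5)$msd == 0))
  set.seed(3)
  t1 <- data.frame(frame = 0:9, x = cumsum(rnorm(10)),
                   y = cumsum(rnorm(10)))
  expect_equal(eata_msd(list(t1), max_k = 4)$msd,
               time_averaged_msd(t1, max_k = 4)$msd)
  t2 <- data.frame(frame = 0:9, x = rnorm(10), y = rnorm(10))
  t3 <- data.frame(frame = 0:9, x = rnorm(10), y = rnorm(10))
  expect_equal(eata_msd(list(t1, t2, t3), max_k = 3)$msd,
               (brute_msd(t1, 3) + brute_msd(t2, 3) + brute_msd(t3, 3))
               / 3, tolerance = 1e-12)
})

test_that("projection onto the image plane lowers apparent membrane D", {
  # surface diffusion seen in 2D projection: the transverse component is
  # compressed by cos(theta), so the apparent D is below the chart D
  cfg <- sim_config(n_cells = 15, m_true = 1, seed = 77, L_mean = 5,
                    D_mem = 0.0184, spots_per_cell = 2500,
                    p_bleach = 0.05, f_depth = 10)
  cells <- simulate_cells(cfg)
  sim <- simulate_tracks(cells, cfg)
  trs <- split_tracks(sim$tracks, cfg$pixel_size)
  ed <- ensemble_D(trs)
  expect_lt(ed$mean, 0.0184 - 3 * ed$sem)
  expect_gt(ed$mean, 0.5 * 0.0184)
})

test_that("D histogram mixtures are recovered and degenerate correctly", {
  set.seed(22)
  Ds <- c(rnorm(4650, 0.018, 0.006), rnorm(350, 0.09, 0.02))
  two <- fit_D_histogram(Ds, mode = "two")
  co <- two$coefficients
  mus <- sort(c(co$mu1, co$mu2))
  expect_lt(abs(mus[2] / mus[1] - 5) / 5, 0.25)

  one_data <- rnorm(3000, 0.02, 0.005)
  one <- fit_D_histogram(one_data, mode = "one")
  expect_equal(one$coefficients$mu, 0.02, tolerance = 0.05)
  two_deg <- fit_D_histogram(one_data, mode = "two")
  expect_lt(two_deg$residual_norm, 2 * one$residual_norm + 1e-9)
  cd <- two_deg$coefficients
  expect_true(abs(cd$mu1 - cd$mu2) < 2 * 0.005 ||
                min(cd$a, 1 - cd$a) < 0.1)

  # fixed a = 1 reduces to the one-population shape
  fx <- fit_D_histogram(one_data, mode = "two", fixed_a = 1)
  expect_equal(fx$coefficients$mu1, one$coefficients$mu,
               tolerance = 1e-3)
  expect_error(fit_D_histogram(rnorm(50)), "100")
})

test_that("the adaptive linking radius is a nondecreasing step function", {
  D <- seq(0, 0.6, by = 0.001)
  r <- adaptive_link_radius(D)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 1))
  expect_error(adaptive_link_radius(-0.1), "D_5pix")
  # printed switch points between 1->2 and 2->3 pixels
  expect_equal(adaptive_link_radius(c(0.073, 0.0745, 0.294, 0.296)),
               c(1L, 2L, 2L, 3L))
})
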