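rect_cell <- function(cx = 0, cy = 0, L = 20, R = 2, id = "cellA") {
  # straight rod as an explicit polygon, centerline pole to pole
  outline <- spherocylinder_outline(L, R, origin = c(cx, cy))
  cell_geometry(id, outline, rbind(c(cx, cy), c(cx + L, cy)), L, R)
}

test_that("spots are assigned by polygon containment", {
  cell <- rect_cell()
  spots <- data.frame(movie_id = "m", track_id = c("t1", "t1", "t2"),
                      frame = c(0, 1, 0),
                      x_px = c(10, 11, 100), y_px = c(0, 0.5, 50))
  out <- assign_spots(spots, list(cell))
  expect_equal(out$cell_id, c("cellA", "cellA"))  # t2 outside, dropped
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("overlapping polygons raise an ambiguity error with cell ids", {
  cells <- list(rect_cell(id = "c1"), rect_cell(cx = 1, id = "c2"))
  spots <- data.frame(movie_id = "m", track_id = "t1", frame = 0,
                      x_px = 10, y_px = 0)
  expect_error(assign_spots(spots, cells), "c1.*c2")
})

test_that("assignment round-trips the generator's cell labels", {
  cfg <- sim_config(n_cells = 12, seed = 31, spots_per_cell = 200,
                    sigma_loc = 0, f_depth = 10)
  cells <- simulate_cells(cfg)
  sim <- simulate_tracks(cells, cfg)
  sp <- assign_spots(sim$tracks, cells)
  truth_cell <- setNames(sim$truth$molecules$cell_id,
                         sim$truth$molecules$molecule_id)
  map <- setNames(truth_cell[as.character(
    sim$truth$track_map$molecule_id)], sim$truth$track_map$track_id)
  expect_true(all(sp$cell_id == map[sp$track_id]))
  # without localization noise nearly everything lies inside its polygon
  expect_lt(attr(sp, "n_dropped") / nrow(sim$tracks), 0.02)
})

test_that("an injected drift is recovered and small drifts are ignored", {
  cfg <- sim_config(n_cells = 10, seed = 17, spots_per_cell = 300)
  cells <- simulate_cells(cfg)
  sim <- simulate_tracks(cells, cfg)
  base <- attr(estimate_drift(sim$tracks, cells), "raw")

  shifted <- sim$tracks
  shifted$x_px <- shifted$x_px + 2
  shifted$y_px <- shifted$y_px - 1
  dr <- estimate_drift(shifted, cells)
  expect_equal(unname(dr[1] - base[1]), 2, tolerance = 0.1)
  expect_equal(unname(dr[2] - base[2]), -1, tolerance = 0.1)
  corrected <- apply_drift(shifted, dr)
  expect_lt(abs(mean(corrected$x_px) - mean(sim$tracks$x_px)), 0.5)

  # below-threshold drift is not applied
  small <- sim$tracks
  small$x_px <- small$x_px + 0.1
  dr2 <- estimate_drift(small, cells, threshold = 0.5)
  expect_identical(unclass(dr2)[1:2], c(0, 0))
})

test_that("normalization follows the centerline sign convention", {
  cell <- rect_cell(L = 20, R = 2)
  spots <- data.frame(movie_id = "m", track_id = "t1", frame = 0:3,
                      cell_id = "cellA",
                      x_px = c(10, 10, 10, 5),
                      y_px = c(0, 2, -2, 1))
  ns <- normalize_spots(spots, list(cell))
  expect_equal(ns$xNorm[1], 0, tolerance = 1e-12)      # on the axis
  expect_equal(ns$xNorm[2], 1, tolerance = 1e-12)      # left edge
  expect_equal(ns$xNorm[3], -1, tolerance = 1e-12)     # right edge
  expect_equal(ns$yNorm[1], 0.5, tolerance = 1e-12)    # mid-cell
  expect_equal(ns$yNorm[4], 0.25, tolerance = 1e-12)
})

test_that("out-of-range normalized spots are rejected, not clipped", {
  cell <- rect_cell(L = 20, R = 2)
  spots <- data.frame(movie_id = "m", track_id = "t1", frame = 0:1,
                      cell_id = "cellA",
                      x_px = c(10, 10), y_px = c(2.5, 1))
  ns <- normalize_spots(spots, list(cell))
  expect_equal(nrow(ns), 1)
  expect_equal(attr(ns, "n_rejected"), 1)
  expect_true(all(abs(ns$xNorm) <= 1))
})

test_that("normalization inverts exactly on straight cells", {
  cell <- rect_cell(cx = 5, cy = 7, L = 25, R = 3)
  set.seed(4)
  spots <- data.frame(movie_id = "m", track_id = "t1", frame = 0:49,
                      cell_id = "cellA",
                      x_px = runif(50, 8, 27), y_px = runif(50, 4.5, 9.5))
  ns <- normalize_spots(spots, list(cell))
  # inverse transform for an axis-aligned rod
  x_rec <- 5 + ns$yNorm * 25
  y_rec <- 7 + ns$xNorm * 3
  expect_equal(x_rec, spots$x_px, tolerance = 1e-9)
  expect_equal(y_rec, spots$y_px, tolerance = 1e-9)
})

test_that("membrane-only |xNorm| follows the arcsine law", {
  cfg <- sim_config(n_cells = 10, m_true = 1, seed = 23, R_sd = 0,
                    dilF_true = 1, sigma_loc = 0, n_sub = 1, D_mem = 0,
                    spots_per_cell = 10000, p_bleach = 1, f_depth = 10)
  cells <- simulate_cells(cfg)
  sim <- simulate_tracks(cells, cfg)
  ns <- normalize_spots(assign_spots(sim$tracks, cells), cells)
  x <- abs(ns$xNorm)
  ks <- max(abs(stats::ecdf(x)(sort(x)) - 2 / pi * asin(sort(x))))
  expect_gt(length(x), 5e4)
  expect_lt(ks, 0.01)
})

test_that("endcap filtering keeps the exact open interval", {
  cell <- rect_cell(L = 20, R = 5)   # L = 4R
  ns <- data.frame(cell_id = "cellA", track_id = "t", frame = 0:3,
                   xNorm = 0, yNorm = c(0.5, 0.1, 0.25, 0.75),
                   y_px = c(10, 2, 5, 15))
  out <- cylinder_filter(ns, list(cell))
  expect_equal(out$in_cylinder, c(TRUE, FALSE, FALSE, FALSE))
  # uniform axial spots: kept fraction tends to (L - 2R) / L
  cfg <- sim_config(n_cells = 6, m_true = 0, seed = 29, L_mean = 2,
                    L_sd = 0, R_mean = 0.5, R_sd = 0, dilF_true = 1,
                    spots_per_cell = 2000, p_bleach = 1, n_sub = 1,
                    sigma_loc = 0, D_cyto = 0, f_depth = 10)
  cells <- simulate_cells(cfg)
  sim <- simulate_tracks(cells, cfg)
  nf <- cylinder_filter(normalize_spots(
    assign_spots(sim$tracks, cells), cells), cells)
  kept <- mean(nf$in_cylinder)
  # axial marginal of a spherocylinder body is not uniform in the caps;
  # the cylindrical fraction of the volume is (L-2R)/(L-2R + 4R/3)
  frac <- 1 / (1 + (4 * 0.5 / 3) / (2 - 1))
  expect_lt(abs(kept - frac), 3 * sqrt(frac * (1 - frac) / nrow(nf)))
})

test_that("xNorm histograms are normalized with track-level bootstrap", {
  ns <- data.frame(cell_id = "c", track_id = "t1", frame = 0:3,
                   xNorm = 0.5, yNorm = 0.5, y_px = 5)
  h <- build_xnorm_histogram(ns, n_boot = 0)
  expect_equal(sum(h$prob), 1, tolerance = 1e-9)
  expect_equal(max(h$prob), 1)
  expect_true(all(h$sem == 0))
  expect_error(build_xnorm_histogram(ns[0, ]), "no spots")

  cfg <- sim_config(n_cells = 10, seed = 37, spots_per_cell = 400)
  pip <- run_xnorm_pipeline(cfg, n_boot = 50)
  h2 <- pip$hist
  expect_equal(sum(h2$prob), 1, tolerance = 1e-9)
  expect_true(all(h2$sem >= 0))
  expect_gt(max(h2$sem), 0)
})

test_that("folding preserves mass and equals the signed-bin sums", {
  cfg <- sim_config(n_cells = 10, seed = 41, spots_per_cell = 500)
  pip <- run_xnorm_pipeline(cfg)
  ns <- pip$normspots
  ha <- build_xnorm_histogram(ns, n_boot = 0, absolute = TRUE)
  hs <- build_xnorm_histogram(ns, n_boot = 0, absolute = FALSE)
  folded <- rev(hs$prob[1:25]) + hs$prob[26:50]
  expect_equal(folded, ha$prob, tolerance = 1e-12)
  expect_equal(sum(hs$prob), 1, tolerance = 1e-9)
})

test_that("cytoplasm-only histograms match the semicircle law", {
  cfg <- sim_config(n_cells = 20, m_true = 0, seed = 43, R_sd = 0,
                    dilF_true = 1, sigma_loc = 0, n_sub = 1,
                    D_cyto = 0.05, spots_per_cell = 4000,
                    p_bleach = 0.25, f_depth = 10)
  pip <- run_xnorm_pipeline(cfg, n_boot = 60)
  h <- pip$hist
  edges <- c(h$bin_lo, 1)
  # folded semicircle bin masses: F(b) - F(a) with
  # F(x) = (x sqrt(1-x^2) + asin(x)) * 2/pi
  Fsc <- function(x) (x * sqrt(1 - x^2) + asin(x)) * 2 / pi
  pth <- diff(Fsc(edges))
  expect_true(all(abs(h$prob - pth) < 4 * pmax(h$sem, 5e-4)))
})
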