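# shared fixtures and independent brute-force oracles

# full pipeline from config to an absolute xNorm histogram
run_xnorm_pipeline <- function(cfg, n_boot = 0) {
  cells <- simulate_cells(cfg)
  sim <- simulate_tracks(cells, cfg)
  sp <- assign_spots(sim$tracks, cells)
  ns <- cylinder_filter(normalize_spots(sp, cells), cells)
  list(hist = build_xnorm_histogram(ns, n_boot = n_boot),
       R_um = mean(vapply(cells, `[[`, numeric(1), "R_px")) *
         cfg$pixel_size,
       cells = cells, sim = sim, normspots = ns)
}

# brute-force time-averaged MSD: explicit double loop over window starts
brute_msd <- function(track, max_k) {
  track <- track[order(track$frame), ]
  len <- nrow(track)
  vapply(seq_len(max_k), function(k) {
    acc <- 0
    for (i in seq_len(len - k))
      acc <- acc + (track$x[i + k] - track$x[i])^2 +
        (track$y[i + k] - track$y[i])^2
    acc / (len - k)
  }, numeric(1))
}

# brute-force Ripley K: explicit double loop over ordered pairs
brute_K <- function(pts, r_grid, area) {
  n <- nrow(pts)
  K <- numeric(length(r_grid))
  for (g in seq_along(r_grid)) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2)
      if (d <= r_grid[g]) cnt <- cnt + 1
    }
    K[g] <- area * cnt / (n * (n - 1))
  }
  K
}

# wrap a probability vector as an xnorm_histogram for model-based fits
as_xnorm_hist <- function(prob, bin = 0.04, n_spots = 1e5,
                          absolute = TRUE) {
  lim <- if (absolute) c(0, 1) else c(-1, 1)
  edges <- seq(lim[1], lim[2], by = bin)
  structure(list(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 prob = prob, sem = rep(0, length(prob)),
                 n_spots = n_spots, n_tracks = n_spots / 4,
                 absolute = absolute, bin = bin),
            class = "xnorm_histogram")
}

# component-wise Monte-Carlo oracle for the projection model: bin masses
# of the membrane and cytoplasm components are estimated separately (the
# model mixes individually normalized components with weight m), then
# mixed and jointly renormalized over |xNorm| <= 1
mc_model_bins <- function(params, R, edges, n_per_comp = 1e6) {
  r <- R / params$dilF
  f <- R - params$fCut
  sig <- params$locErr / 1000
  one_comp <- function(membrane) {
    if (membrane) {
      th <- runif(n_per_comp, 0, 2 * pi)
      x <- r * cos(th); z <- r * sin(th)
    } else {
      rho <- r * sqrt(runif(n_per_comp))
      an <- runif(n_per_comp, 0, 2 * pi)
      x <- rho * cos(an); z <- rho * sin(an)
    }
    keep <- runif(n_per_comp) < defocus_weight(z, f, sig)
    xo <- x[keep] + rnorm(sum(keep), 0, sig)
    xo <- abs(xo / R)
    n_acc <- sum(keep)
    inr <- xo <= 1
    counts <- tabulate(pmin(findInterval(xo[inr], edges,
                                         rightmost.closed = TRUE),
                            length(edges) - 1L), length(edges) - 1L)
    list(q = counts / n_acc, n = n_acc)   # out-of-range mass excluded
  }
  mem <- one_comp(TRUE); cyt <- one_comp(FALSE)
  q <- params$m * mem$q + (1 - params$m) * cyt$q
  p <- q / sum(q)
  # binomial SE of the mixed, renormalized bin probabilities
  se <- sqrt(params$m^2 * mem$q * (1 - mem$q) / mem$n +
               (1 - params$m)^2 * cyt$q * (1 - cyt$q) / cyt$n) / sum(q)
  list(p = p, se = se)
}
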