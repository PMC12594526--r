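#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator: cell geometry,
#' the true membrane-bound fraction, membrane and cytoplasmic diffusion
#' coefficients, camera/imaging parameters, photobleaching, and the
#' two-phase mRNA decay rates. Defaults describe the imaging conditions the
#' pipeline targets: a 21.7 ms frame interval, 160 nm pixels, E. coli-like
#' cell dimensions, a membrane coefficient at the scale measured for
#' membrane-bound RNase E and a typical cytoplasmic-protein coefficient.
#'
#' @param n_cells number of cells to simulate.
#' @param L_mean,L_sd cell length mean and SD, um.
#' @param R_mean,R_sd cell half-width mean and SD, um.
#' @param m_true true membrane-bound fraction in [0, 1].
#' @param dilF_true true dilation factor: the bright-field outline
#'   half-width R is \code{dilF_true} times the inner-membrane radius
#'   (segmentation outlines sit outside the membrane).
#' @param D_mem,D_cyto membrane and cytoplasmic diffusion coefficients,
#'   um^2/s.
#' @param dt frame interval, s.
#' @param n_sub motion-blur substeps per frame; the recorded position is the
#'   average of the substep positions.
#' @param sigma_loc lateral localization error SD, um.
#' @param f_depth focal depth parameter, um: a localization at depth z
#'   (relative to the cell midplane, negative = away from the objective) is
#'   detected with probability Phi((f_depth + z) / sigma_z). f_depth = R
#'   with small sigma_z approximates an unobstructed view.
#' @param sigma_z axial softness of the detection cutoff, um.
#' @param p_bleach per-frame photobleaching probability (track lengths are
#'   geometric).
#' @param spots_per_cell target mean number of localizations per cell.
#' @param pixel_size camera pixel size, um.
#' @param seed integer RNG seed.
#' @param k_d1_true,k_d2_true co- and post-transcriptional mRNA decay
#'   rates, 1/s.
#' @param cv_noise coefficient of variation of the multiplicative
#'   (lognormal) noise on decay curves.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_cells = 50,
                       L_mean = 3.0, L_sd = 0.4,
                       R_mean = 0.45, R_sd = 0.03,
                       m_true = 0.93, dilF_true = 1.2,
                       D_mem = 0.0184, D_cyto = 0.1,
                       dt = 0.0217, n_sub = 10,
                       sigma_loc = 0.02,
                       f_depth = 0.45, sigma_z = 0.02,
                       p_bleach = 0.1,
                       spots_per_cell = 300,
                       pixel_size = 0.160,
                       seed = NULL,
                       k_d1_true = 0.02, k_d2_true = 0.01,
                       cv_noise = 0.1) {
  cfg <- list(n_cells = n_cells, L_mean = L_mean, L_sd = L_sd,
              R_mean = R_mean, R_sd = R_sd, m_true = m_true,
              dilF_true = dilF_true,
              D_mem = D_mem, D_cyto = D_cyto, dt = dt, n_sub = n_sub,
              sigma_loc = sigma_loc, f_depth = f_depth, sigma_z = sigma_z,
              p_bleach = p_bleach, spots_per_cell = spots_per_cell,
              pixel_size = pixel_size, seed = seed,
              k_d1_true = k_d1_true, k_d2_true = k_d2_true,
              cv_noise = cv_noise)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, field, what) {
    if (!isTRUE(cond))
      stop("invalid sim_config field '", field, "': ", what, call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    chk(is.numeric(v) && length(v) == 1L && is.finite(v), field,
        "must be a single finite number")
    v
  }
  chk(num1("n_cells") >= 1, "n_cells", "must be >= 1")
  for (f in c("L_mean", "R_mean"))
    chk(num1(f) > 0, f, "must be > 0")
  for (f in c("L_sd", "R_sd", "D_mem", "D_cyto", "sigma_loc", "sigma_z",
              "f_depth", "k_d1_true", "k_d2_true", "cv_noise"))
    chk(num1(f) >= 0, f, "must be >= 0")
  chk(num1("dt") > 0, "dt", "must be > 0")
  chk(num1("pixel_size") > 0, "pixel_size", "must be > 0")
  m <- num1("m_true")
  chk(m >= 0 && m <= 1, "m_true", "must be in [0, 1]")
  p <- num1("p_bleach")
  chk(p > 0 && p <= 1, "p_bleach", "must be in (0, 1]")
  chk(num1("n_sub") >= 1, "n_sub", "must be >= 1")
  chk(num1("dilF_true") >= 1, "dilF_true", "must be >= 1")
  chk(num1("spots_per_cell") > 0, "spots_per_cell", "must be > 0")
  chk(cfg$L_mean > 2 * cfg$R_mean, "L_mean",
      "must exceed 2 * R_mean (spherocylinder geometry)")
  if (!is.null(cfg$seed))
    chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed",
        "must be a single number or NULL")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells, m_true =", x$m_true,
      "| D_mem =", x$D_mem, "D_cyto =", x$D_cyto, "um^2/s",
      "| dt =", x$dt, "s\n")
  invisible(x)
}

#' Write / read a simulation configuration
#'
#' Flat key/value YAML; field names are those of [sim_config()].
#'
#' @param config a \code{sim_config}.
#' @param path file path.
#' @return \code{read_sim_config} returns a \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
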