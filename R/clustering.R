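#' Ripley K, L and H statistics of a 2D point pattern
#'
#' Khat(r) = A / (n (n - 1)) * sum over ordered pairs i != j of
#' 1(d_ij <= r), with A the observation-window area; L(r) = sqrt(K / pi)
#' and H(r) = L(r) - r. No analytic edge correction is applied: the
#' statistic is designed to be compared against complete spatial
#' randomness simulated in the *same* geometry ([csr_on_cell()]), which
#' absorbs edge and projection effects. Under planar CSR far from edges,
#' K(r) = pi r^2 and H(r) = 0.
#'
#' @param points two-column matrix or data.frame of coordinates (um).
#' @param r_grid increasing vector of radii (um).
#' @param area observation-window area (um^2); for on-cell patterns use
#'   the projected spherocylinder footprint 2 R (L - 2R) + pi R^2.
#' @return data.frame with r, K, L, H (class \code{ripley_curves}).
#' @export
ripley_K <- function(points, r_grid, area) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 2, area > 0)
  if (any(diff(r_grid) <= 0)) stop("r_grid must be increasing")
  cnt <- .count_pairs_within(pts[, 1], pts[, 2], r_grid)
  n <- nrow(pts)
  K <- area * cnt / (n * (n - 1))
  L <- sqrt(K / pi)
  structure(data.frame(r = r_grid, K = K, L = L, H = L - r_grid),
            class = c("ripley_curves", "data.frame"))
}

# half-width/length of a cell in um, from a cell_geometry (px) or a
# list(L=, R=) already in um
cell_dims_um <- function(cell, pixel_size = NULL) {
  if (inherits(cell, "cell_geometry")) {
    if (is.null(pixel_size))
      stop("pixel_size needed to convert cell_geometry (px) to um")
    list(L = cell$L_px * pixel_size, R = cell$R_px * pixel_size)
  } else {
    stopifnot(is.list(cell), !is.null(cell$L), !is.null(cell$R))
    cell[c("L", "R")]
  }
}

#' Simulate complete spatial randomness on a cell surface
#'
#' Points uniform by area on a spherocylinder surface (cylindrical body
#' plus hemispherical caps) with the same length and width as the data
#' cell, projected onto the imaging plane. This is the CSR reference for
#' [ripley_K()] comparisons: it carries the same footprint, edge and
#' projection effects as membrane-localized data.
#'
#' @param cell a [cell_geometry()] (with \code{pixel_size}) or a
#'   \code{list(L =, R =)} in um.
#' @param n number of points (>= 2).
#' @param pixel_size um per pixel, when \code{cell} is a
#'   \code{cell_geometry}.
#' @return Matrix with columns \code{y} (axial position, um, in [0, L]
#'   with 0 at the left pole tip) and \code{x} (transverse, um, in
#'   [-R, R]).
#' @export
csr_on_cell <- function(cell, n, pixel_size = NULL) {
  dims <- cell_dims_um(cell, pixel_size)
  L <- dims$L; R <- dims$R
  stopifnot(n >= 2)
  a_cyl <- 2 * pi * R * (L - 2 * R)
  a_caps <- 4 * pi * R^2
  on_cyl <- runif(n) < a_cyl / (a_cyl + a_caps)
  ax <- numeric(n); tx <- numeric(n)
  nc <- sum(on_cyl)
  if (nc > 0) {
    ax[on_cyl] <- runif(nc, R, L - R)
    tx[on_cyl] <- R * cos(runif(nc, 0, 2 * pi))
  }
  nk <- n - nc
  if (nk > 0) {
    # uniform on the sphere via normalized Gaussians; outward hemisphere
    u <- matrix(rnorm(3 * nk), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    left <- runif(nk) < 0.5
    u[, 1] <- abs(u[, 1]) * ifelse(left, -1, 1)
    centers <- ifelse(left, R, L - R)
    ax[!on_cyl] <- centers + R * u[, 1]
    tx[!on_cyl] <- R * u[, 2]
  }
  cbind(y = ax, x = tx)
}

#' Clustering excess of a point pattern relative to matched CSR
#'
#' Computes H(r) for the data pattern and for \code{n_csr} CSR replicates
#' simulated on the same cell surface, and summarizes the departure from
#' randomness as the integral over r of H_data(r) - mean H_CSR(r)
#' (trapezoidal); positive values indicate clustering. The spread of the
#' same integral across the CSR replicates (each referenced against the
#' remaining replicates' mean) provides a null scale.
#'
#' @param points two-column matrix of data coordinates (um, cell frame).
#' @param cell cell geometry (see [csr_on_cell()]).
#' @param n_csr number of CSR replicates.
#' @param r_grid radii (um); default 0 to R in 50 steps.
#' @param pixel_size um per pixel for \code{cell_geometry} input.
#' @param min_points minimum number of data points required.
#' @return list with \code{integral}, \code{mean_excess} (mean over r of
#'   H_data - H_CSR), \code{r}, \code{H_data}, \code{H_csr} (mean curve),
#'   \code{null_integrals} (per-replicate null integrals), \code{n}.
#' @export
h_excess_integral <- function(points, cell, n_csr = 20, r_grid = NULL,
                              pixel_size = NULL, min_points = 300) {
  pts <- as.matrix(points)
  if (nrow(pts) < min_points)
    stop("need at least ", min_points, " points (got ", nrow(pts), ")")
  dims <- cell_dims_um(cell, pixel_size)
  if (is.null(r_grid))
    r_grid <- seq(0, dims$R, length.out = 51)[-1]
  area <- 2 * dims$R * (dims$L - 2 * dims$R) + pi * dims$R^2
  H_data <- ripley_K(pts, r_grid, area)$H
  H_csr <- vapply(seq_len(n_csr), function(i)
    ripley_K(csr_on_cell(dims, nrow(pts)), r_grid, area)$H,
    numeric(length(r_grid)))
  H_csr_mean <- rowMeans(H_csr)
  null_int <- vapply(seq_len(n_csr), function(i) {
    ref <- rowMeans(H_csr[, -i, drop = FALSE])
    trapz(r_grid, H_csr[, i] - ref)
  }, numeric(1))
  list(integral = trapz(r_grid, H_data - H_csr_mean),
       mean_excess = mean(H_data - H_csr_mean),
       r = r_grid, H_data = H_data, H_csr = H_csr_mean,
       null_integrals = null_int, n = nrow(pts))
}
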