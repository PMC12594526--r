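#' Projection-model parameters
#'
#' Parameters of the cylindrical-projection model for the transverse
#' (xNorm) distribution of a membrane/cytoplasm mixture: the membrane-bound
#' fraction \code{m}, the dilation factor \code{dilF} relating the
#' bright-field cell boundary R to the inner-membrane radius r = R / dilF,
#' the localization error \code{locErr} in nm (sigma = locErr / 1000 um),
#' and the focal cut \code{fCut} measured from the cell top (the in-focus
#' half-space is z > -(R - fCut); fCut = 0 means an unobstructed view).
#'
#' @param m membrane fraction in [0, 1].
#' @param dilF dilation factor, >= 1.
#' @param locErr localization error, nm (>= 0).
#' @param fCut focal cut, um (>= 0).
#' @return An object of class \code{mb_params}.
#' @export
mb_params <- function(m, dilF = 1, locErr = 0, fCut = 0) {
  if (!(is.numeric(m) && m >= 0 && m <= 1))
    stop("m must be in [0, 1]")
  if (!(dilF >= 1)) stop("dilF must be >= 1")
  if (!(locErr >= 0)) stop("locErr must be >= 0")
  if (!(fCut >= 0)) stop("fCut must be >= 0")
  structure(list(m = m, dilF = dilF, locErr = locErr, fCut = fCut),
            class = "mb_params")
}

#' Transverse marginals of the raw (imaging-free) geometry
#'
#' For molecules uniform on a circle of radius r (the projected membrane),
#' the x-marginal is the arcsine density 1 / (pi * sqrt(r^2 - x^2)); for
#' molecules uniform in the disk (the projected cytoplasm cross-section) it
#' is the semicircle density 2 * sqrt(r^2 - x^2) / (pi * r^2). Outside the
#' support the density is 0.
#'
#' @param x evaluation points.
#' @param r circle/disk radius.
#' @return Density values.
#' @export
raw_membrane_marginal <- function(x, r) {
  stopifnot(r > 0)
  out <- numeric(length(x))
  in_sup <- abs(x) < r
  out[in_sup] <- 1 / (pi * sqrt(r^2 - x[in_sup]^2))
  out
}

#' @rdname raw_membrane_marginal
#' @export
raw_cytoplasm_marginal <- function(x, r) {
  stopifnot(r > 0)
  out <- numeric(length(x))
  in_sup <- abs(x) <= r
  out[in_sup] <- 2 * sqrt(r^2 - x[in_sup]^2) / (pi * r^2)
  out
}

#' Defocus detection weight
#'
#' Probability weight for detecting a molecule at depth z when the
#' defocused region is z < -f and the cutoff is softened by the
#' localization uncertainty: Phi((f + z) / sigma). With sigma = 0 this is
#' the hard indicator of z >= -f (the closed half-space, so that fCut = 0
#' leaves the whole cell in view).
#'
#' @param z depth relative to the cylinder axis (same unit as f).
#' @param f in-focus half-depth (f = R - fCut).
#' @param sigma softness (um); 0 gives a hard cutoff.
#' @return Weights in [0, 1].
#' @export
defocus_weight <- function(z, f, sigma) {
  if (sigma > 0) return(pnorm((f + z) / sigma))
  0 + (z >= -f)   # keeps the shape of z (matrix inputs stay matrices)
}

# antiderivative of Phi((f + u) / sigma) du (used for the cytoplasm depth
# integral); W(z) = G(z) - G(-z) is the integral over u in (-z, z)
defocus_depth_integral <- function(z, f, sigma) {
  if (sigma > 0) {
    G <- function(u) {
      v <- (f + u) / sigma
      sigma * (v * pnorm(v) + dnorm(v))
    }
    return(G(z) - G(-z))
  }
  pmax(0, pmin(2 * z, z + f))
}

# Core grid computation shared by predicted_marginal() and
# model_bin_probabilities(). Works in physical um on a uniform grid of
# cell width h symmetric about 0 (0 is a cell edge, so folding is exact).
# Membrane mass is accumulated by quadrature over the circle angle (which
# handles the arcsine edge singularity exactly in measure); the cytoplasm
# depth integral has a closed form. Each component is blurred by a 1D
# Gaussian of SD sigma in x and renormalized.
mb_component_masses <- function(params, R, h = R / 400,
                                literal_defocus = FALSE) {
  stopifnot(inherits(params, "mb_params"), R > 0)
  r <- R / params$dilF
  f <- R - params$fCut
  sigma <- params$locErr / 1000
  if (r <= 0) stop("invalid parameters: inner membrane radius r <= 0")
  if (f < -R) stop("invalid parameters: fCut > 2R (f < -R)")
  K <- ceiling((R + 6 * sigma) / h) + 2L
  edges <- (-K:K) * h
  nc <- 2L * K
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  # membrane: exact per-cell integration over the circle angle.  With
  # x = r cos(theta), the mass of grid cell [a, b] is
  # (1/2pi) * int [w(r sin th) + w(-r sin th)] dth over th in
  # [acos(b/r), acos(a/r)]; the angular substitution absorbs the arcsine
  # edge singularity, and the smooth integrand is handled by composite
  # Simpson (5 nodes per cell).
  mem <- numeric(nc)
  lo_x <- pmax(edges[-length(edges)], -r)
  hi_x <- pmin(edges[-1], r)
  act <- which(lo_x < hi_x)
  th_hi <- acos(pmin(pmax(lo_x[act] / r, -1), 1))
  th_lo <- acos(pmin(pmax(hi_x[act] / r, -1), 1))
  dth <- th_hi - th_lo
  nodes <- c(0, 0.25, 0.5, 0.75, 1)
  sw <- c(1, 4, 2, 4, 1) / 12
  TH <- matrix(th_lo, 5L, length(act), byrow = TRUE) + outer(nodes, dth)
  Z <- r * sin(TH)
  FW <- defocus_weight(Z, f, sigma) + defocus_weight(-Z, f, sigma)
  mem[act] <- colSums(FW * sw) * dth / (2 * pi)

  # cytoplasm: disk density integrated over depth with the defocus weight
  zx <- sqrt(pmax(r^2 - mids^2, 0))
  if (literal_defocus) {
    wcy <- 2 * zx * defocus_weight(zx, f, sigma)
  } else {
    wcy <- defocus_depth_integral(zx, f, sigma)
  }
  cyto <- ifelse(abs(mids) <= r, wcy * 2 / (pi * r^2) * h, 0)

  if (sigma > 0) {
    kk <- ceiling(5 * sigma / h)
    kern <- dnorm((-kk:kk) * h, 0, sigma)
    kern <- kern / sum(kern)
    mem <- blur_vec(mem, kern)
    cyto <- blur_vec(cyto, kern)
  }
  mem <- mem / sum(mem)
  cyto <- cyto / sum(cyto)
  list(edges = edges, mids = mids, h = h, mem = mem, cyto = cyto,
       mix = params$m * mem + (1 - params$m) * cyto,
       r = r, f = f, sigma = sigma)
}

# full discrete convolution, trimmed back to the input support
blur_vec <- function(x, kern) {
  k <- (length(kern) - 1L) / 2L
  out <- convolve(x, rev(kern), type = "open")
  out[(k + 1L):(length(out) - k)]
}

#' Model-implied transverse density
#'
#' Evaluates the mixture density of Eq.-style membrane (projected circle
#' with defocus weighting) and cytoplasm (depth-integrated disk) components
#' after Gaussian blur, in physical units. With \code{locErr = 0} and
#' \code{fCut = 0} this reduces exactly to the arcsine / semicircle
#' marginals at radius r = R / dilF.
#'
#' @param params an [mb_params()].
#' @param R cell half-width, um.
#' @param x_out optional evaluation points (um, signed); default is the
#'   internal grid.
#' @param h grid step, um.
#' @param literal_defocus if TRUE use the printed form of the cytoplasm
#'   defocus integrand (constant in the depth variable) instead of the
#'   depth-dependent integrand; see the methods vignette.
#' @return data.frame with x, membrane, cytoplasm, mixture (densities per
#'   um).
#' @export
predicted_marginal <- function(params, R, x_out = NULL, h = R / 400,
                               literal_defocus = FALSE) {
  cm <- mb_component_masses(params, R, h = h,
                            literal_defocus = literal_defocus)
  dens <- data.frame(x = cm$mids, membrane = cm$mem / cm$h,
                     cytoplasm = cm$cyto / cm$h, mixture = cm$mix / cm$h)
  if (is.null(x_out)) return(dens)
  data.frame(
    x = x_out,
    membrane = approx(cm$mids, dens$membrane, x_out, yleft = 0,
                      yright = 0)$y,
    cytoplasm = approx(cm$mids, dens$cytoplasm, x_out, yleft = 0,
                       yright = 0)$y,
    mixture = approx(cm$mids, dens$mixture, x_out, yleft = 0,
                     yright = 0)$y)
}

#' Model-implied histogram bin probabilities
#'
#' Integrates the mixture density over xNorm bins (x normalized by R),
#' folding to |xNorm| when \code{absolute}. Probabilities are conditioned
#' on |xNorm| <= 1 (matching the rejection of out-of-range spots in the
#' data pipeline) and sum to 1.
#'
#' @param params an [mb_params()].
#' @param R cell half-width, um.
#' @param bin_edges increasing bin edges on the normalized axis covering
#'   [0, 1] (absolute) or [-1, 1] (signed).
#' @param absolute fold to |xNorm|?
#' @inheritParams predicted_marginal
#' @return Vector of bin probabilities (sums to 1).
#' @export
model_bin_probabilities <- function(params, R, bin_edges, absolute = TRUE,
                                    h = R / 400,
                                    literal_defocus = FALSE) {
  lim <- if (absolute) c(0, 1) else c(-1, 1)
  if (any(diff(bin_edges) <= 0) ||
      abs(bin_edges[1] - lim[1]) > 1e-9 ||
      abs(bin_edges[length(bin_edges)] - lim[2]) > 1e-9)
    stop("bin_edges must increase and cover [", lim[1], ", ", lim[2], "]")
  cm <- mb_component_masses(params, R, h = h,
                            literal_defocus = literal_defocus)
  xn <- cm$mids / R
  mass <- cm$mix
  if (absolute) xn <- abs(xn)
  keep <- xn >= lim[1] & xn <= lim[2]
  idx <- pmin(pmax(findInterval(xn[keep], bin_edges,
                                rightmost.closed = TRUE), 1L),
              length(bin_edges) - 1L)
  p <- numeric(length(bin_edges) - 1L)
  rs <- rowsum(mass[keep], idx)
  p[as.integer(rownames(rs))] <- rs
  p / sum(p)
}
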