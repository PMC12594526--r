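#' Cell geometry
#'
#' A rod-shaped cell as segmented from a bright-field image: a closed
#' outline polygon, an ordered centerline running pole to pole, the cell
#' length L and half-width R. All coordinates are in pixels.
#'
#' @param cell_id character id.
#' @param outline two-column matrix of polygon vertices, px (closed
#'   implicitly; the last vertex need not repeat the first).
#' @param centerline two-column matrix of ordered centerline points, px.
#' @param L_px cell length (pole to pole along the centerline), px.
#' @param R_px half of the mean cell width, px.
#' @param movie_id id of the movie the cell belongs to.
#' @return An object of class \code{cell_geometry}.
#' @export
cell_geometry <- function(cell_id, outline, centerline, L_px, R_px,
                          movie_id = "movie1") {
  outline <- as.matrix(outline)
  centerline <- as.matrix(centerline)
  dimnames(outline) <- NULL
  dimnames(centerline) <- NULL
  stopifnot(ncol(outline) == 2L, nrow(outline) >= 3L,
            ncol(centerline) == 2L, nrow(centerline) >= 2L)
  if (!(L_px > 2 * R_px) || !(R_px > 0))
    stop("cell geometry requires L > 2R > 0")
  seglen <- sqrt(rowSums(diff(centerline)^2))
  if (any(seglen <= 0))
    stop("degenerate centerline: zero-length segment")
  structure(list(cell_id = as.character(cell_id),
                 movie_id = as.character(movie_id),
                 outline = outline, centerline = centerline,
                 L_px = L_px, R_px = R_px),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("cell_geometry", x$cell_id, ": L =", round(x$L_px, 2),
      "px, R =", round(x$R_px, 2), "px,", nrow(x$outline),
      "outline vertices\n")
  invisible(x)
}

# Spherocylinder outline in px: total length L, half-width R, long axis
# along +x, left pole tip at `origin`. Vertices ordered counter-clockwise.
spherocylinder_outline <- function(L, R, origin = c(0, 0), n_arc = 24) {
  th <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)       # left cap
  left <- cbind(R + R * cos(th), R * sin(th))
  th2 <- seq(-pi / 2, pi / 2, length.out = n_arc)         # right cap
  right <- cbind(L - R + R * cos(th2), R * sin(th2))
  ns <- 8
  xs <- seq(R, L - R, length.out = ns + 2)[2:(ns + 1)]
  bottom <- cbind(xs, rep(-R, ns))
  top <- cbind(rev(xs), rep(R, ns))
  out <- rbind(left, bottom, right, top)
  sweep(out, 2, origin, `+`)
}

#' Simulate cell geometries
#'
#' Draws straight, axis-aligned spherocylinders with lengths and half-widths
#' from truncated normal distributions (truncated to L > 2R and R > 0) and
#' lays them out on a non-overlapping grid in the movie frame. The
#' centerline is the axis segment between the two pole tips.
#'
#' @param config a [sim_config()].
#' @param movie_id movie id attached to every cell.
#' @param n_arc vertices per polar cap arc of the outline polygon.
#' @return A list of [cell_geometry()] objects (class
#'   \code{cell_collection}).
#' @export
simulate_cells <- function(config, movie_id = "movie1", n_arc = 24) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  px <- config$pixel_size
  n <- config$n_cells
  R <- rtruncnorm(n, config$R_mean, config$R_sd, lo = 0)
  # truncate L above 2R so every draw is a valid spherocylinder
  L <- vapply(R, function(r)
    rtruncnorm(1L, config$L_mean, config$L_sd, lo = 2 * r), numeric(1))
  # grid layout with a 2 um margin between footprints
  ncol_grid <- max(1L, ceiling(sqrt(n)))
  pitch_x <- (max(L) + 2) / px
  pitch_y <- (2 * max(R) + 2) / px
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    ox <- ((i - 1L) %% ncol_grid) * pitch_x
    oy <- ((i - 1L) %/% ncol_grid) * pitch_y
    Lp <- L[i] / px
    Rp <- R[i] / px
    outline <- spherocylinder_outline(Lp, Rp, origin = c(ox, oy),
                                      n_arc = n_arc)
    centerline <- rbind(c(ox, oy), c(ox + Lp, oy))
    cells[[i]] <- cell_geometry(sprintf("cell%04d", i), outline,
                                centerline, Lp, Rp, movie_id = movie_id)
  }
  structure(cells, class = "cell_collection")
}

#' @export
print.cell_collection <- function(x, ...) {
  cat("cell_collection with", length(x), "cells\n")
  invisible(x)
}

#' Write / read cell geometries as delimited text
#'
#' One record per cell: cell_id, movie_id, semicolon-separated vertex and
#' centerline lists ("x y;x y;..."), length and width in px.
#'
#' @param cells a list of [cell_geometry()] objects.
#' @param path file path (tab-separated).
#' @return \code{read_cells} returns a \code{cell_collection}.
#' @export
write_cells <- function(cells, path) {
  pack <- function(m) paste(apply(m, 1, function(p)
    paste(format(p, digits = 17, trim = TRUE), collapse = " ")),
    collapse = ";")
  df <- data.frame(
    cell_id = vapply(cells, `[[`, character(1), "cell_id"),
    movie_id = vapply(cells, `[[`, character(1), "movie_id"),
    outline = vapply(cells, function(c) pack(c$outline), character(1)),
    centerline = vapply(cells, function(c) pack(c$centerline),
                        character(1)),
    length_px = vapply(cells, `[[`, numeric(1), "L_px"),
    width_px = vapply(cells, function(c) 2 * c$R_px, numeric(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  unpack <- function(s) {
    do.call(rbind, lapply(strsplit(s, ";", fixed = TRUE)[[1]],
                          function(p) as.numeric(strsplit(p, " ")[[1]])))
  }
  cells <- lapply(seq_len(nrow(df)), function(i)
    cell_geometry(df$cell_id[i], unpack(df$outline[i]),
                  unpack(df$centerline[i]), df$length_px[i],
                  df$width_px[i] / 2, movie_id = df$movie_id[i]))
  structure(cells, class = "cell_collection")
}
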