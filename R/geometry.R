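#' Assign localizations to cells
#'
#' Each spot is mapped to the cell whose outline polygon contains it; spots
#' in no cell are dropped. A track is then assigned as a whole to the cell
#' containing the majority of its spots; tracks whose spots straddle two
#' cells after the majority vote (i.e. with spots inside a different cell)
#' are dropped, as are the spots of tracks that fall entirely outside.
#'
#' @param spots data.frame with movie_id, track_id, frame, x_px, y_px.
#' @param cells a list of [cell_geometry()] objects from the same movie.
#' @return The spot data.frame restricted to assigned spots, with a
#'   \code{cell_id} column appended. The number of spots dropped is
#'   attached as attribute \code{n_dropped}.
#' @export
assign_spots <- function(spots, cells) {
  stopifnot(nrow(spots) > 0, length(cells) > 0)
  pts <- cbind(spots$x_px, spots$y_px)
  inside <- matrix(FALSE, nrow(spots), length(cells))
  for (j in seq_along(cells))
    inside[, j] <- mgcv::in.out(close_poly(cells[[j]]$outline), pts)
  hits <- rowSums(inside)
  if (any(hits > 1L)) {
    amb <- which(hits > 1L)[1L]
    ids <- vapply(cells[which(inside[amb, ])], `[[`, character(1),
                  "cell_id")
    stop("overlapping cell polygons: spot contained in cells ",
         paste(ids, collapse = ", "))
  }
  cell_of_spot <- ifelse(hits == 1L, max.col(inside, ties.method = "first"),
                         NA_integer_)
  cell_of_spot[hits == 0L] <- NA_integer_

  # majority vote per track; drop tracks split across cells
  keep <- logical(nrow(spots))
  assigned <- integer(nrow(spots))
  for (idx in split(seq_len(nrow(spots)), spots$track_id)) {
    cs <- cell_of_spot[idx]
    cs_in <- cs[!is.na(cs)]
    if (length(cs_in) == 0L) next
    tab <- table(cs_in)
    win <- as.integer(names(tab)[which.max(tab)])
    if (length(tab) > 1L) next           # straddling tracks are dropped
    inwin <- !is.na(cs) & cs == win
    keep[idx[inwin]] <- TRUE
    assigned[idx[inwin]] <- win
  }
  out <- spots[keep, , drop = FALSE]
  out$cell_id <- vapply(cells, `[[`, character(1), "cell_id")[
    assigned[keep]]
  attr(out, "n_dropped") <- nrow(spots) - nrow(out)
  out
}

close_poly <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

#' Estimate and correct stage drift between outline and fluorescence data
#'
#' Runs on raw (pre-assignment) spots: each spot is attributed to the cell
#' with the nearest outline centroid, so a drifted spot cloud is not
#' truncated at the polygon boundary (containment-based assignment would
#' systematically shrink the estimate). For every cell attracting at least
#' \code{min_spots} spots, the offset between its spot centroid and its
#' outline centroid is computed; the movie-wide drift is the mean offset.
#' The correction is applied only when the drift magnitude exceeds
#' \code{threshold} pixels.
#'
#' @param spots spot data.frame with x_px, y_px (raw, before
#'   [assign_spots()]).
#' @param cells the cell list.
#' @param min_spots minimum attributed spots for a cell to contribute.
#' @param threshold magnitude (px) below which no correction is applied.
#' @return Numeric length-2 drift vector (px): the displacement of the
#'   spot data relative to the outlines (zero when below threshold, with
#'   the raw estimate in attribute \code{raw}). Subtract it from spot
#'   coordinates to correct; [apply_drift()] does this.
#' @export
estimate_drift <- function(spots, cells, min_spots = 10, threshold = 0.5) {
  centers <- t(vapply(cells, function(c) polygon_centroid(c$outline),
                      numeric(2)))
  d2 <- outer(spots$x_px, centers[, 1], `-`)^2 +
    outer(spots$y_px, centers[, 2], `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  offs <- t(vapply(seq_along(cells), function(j) {
    sel <- nearest == j
    if (sum(sel) < min_spots) return(c(NA_real_, NA_real_))
    c(mean(spots$x_px[sel]), mean(spots$y_px[sel])) - centers[j, ]
  }, numeric(2)))
  offs <- offs[complete.cases(offs), , drop = FALSE]
  if (nrow(offs) == 0L) {
    warning("no cell has >= ", min_spots,
            " assigned spots; drift not estimated")
    return(structure(c(0, 0), raw = c(NA_real_, NA_real_)))
  }
  raw <- colMeans(offs)
  drift <- if (sqrt(sum(raw^2)) > threshold) raw else c(0, 0)
  structure(drift, raw = raw)
}

#' @rdname estimate_drift
#' @param drift drift vector from [estimate_drift()].
#' @export
apply_drift <- function(spots, drift) {
  spots$x_px <- spots$x_px - drift[1]
  spots$y_px <- spots$y_px - drift[2]
  spots
}

#' Convert localizations to normalized cell coordinates
#'
#' Each spot is projected onto its cell's centerline (piecewise linear,
#' arc-length parameterized). yNorm is the arc-length position divided by
#' the cell length L; xNorm is the signed perpendicular distance divided by
#' the half-width R, with the sign taken from the cross product of the
#' local centerline tangent with the spot offset (positive to the left of
#' the direction of increasing yNorm). Spots with |xNorm| > 1 or yNorm
#' outside [0, 1] are rejected, not clipped (clipping would pile mass into
#' the membrane bin); the rejected count is reported in attribute
#' \code{n_rejected}.
#'
#' @param spots assigned spots (with cell_id), drift-corrected.
#' @param cells the cell list.
#' @return data.frame with cell_id, track_id, frame, xNorm, yNorm, y_px
#'   (absolute axial arc-length position, px).
#' @export
normalize_spots <- function(spots, cells) {
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  out <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    d <- spots[spots$cell_id == ids[j], , drop = FALSE]
    if (nrow(d) == 0L) next
    cl <- cells[[j]]$centerline
    pr <- project_polyline(cbind(d$x_px, d$y_px), cl)
    out[[j]] <- data.frame(cell_id = ids[j], track_id = d$track_id,
                           frame = d$frame,
                           xNorm = pr$signed_dist / cells[[j]]$R_px,
                           yNorm = pr$arc / cells[[j]]$L_px,
                           y_px = pr$arc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  ok <- abs(res$xNorm) <= 1 & res$yNorm >= 0 & res$yNorm <= 1
  structure(res[ok, , drop = FALSE], n_rejected = sum(!ok))
}

# Project points onto a piecewise-linear centerline. Returns arc-length
# position and signed perpendicular distance (positive left of the tangent).
project_polyline <- function(pts, cl) {
  nseg <- nrow(cl) - 1L
  seg_vec <- cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg_vec^2))
  if (any(seg_len <= 0)) stop("degenerate centerline: zero-length segment")
  cum0 <- c(0, cumsum(seg_len))
  n <- nrow(pts)
  best_d2 <- rep(Inf, n); best_arc <- numeric(n); best_sgn <- numeric(n)
  for (s in seq_len(nseg)) {
    a <- cl[s, ]; v <- seg_vec[s, ] / seg_len[s]
    rel <- sweep(pts, 2, a, `-`)
    t_along <- rel %*% v
    t_cl <- pmin(pmax(t_along, 0), seg_len[s])
    perp <- rel - t_cl %*% t(v)
    d2 <- rowSums(perp^2)
    cross <- v[1] * rel[, 2] - v[2] * rel[, 1]   # >0 means left of tangent
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum0[s] + t_cl[upd]
    best_sgn[upd] <- sign(cross[upd]) * sqrt(d2[upd])
  }
  list(arc = best_arc, signed_dist = best_sgn)
}

#' Flag localizations in the cylindrical part of the cell
#'
#' Keeps spots whose absolute axial position y (px, along the centerline)
#' satisfies R < y < L - R (strict); spots in the hemispherical endcaps are
#' flagged. Downstream transverse-position histograms use only cylindrical
#' spots, where the 2D projection model applies.
#'
#' @param normspots output of [normalize_spots()].
#' @param cells the cell list.
#' @param drop if TRUE return only cylindrical spots, else return all with
#'   an \code{in_cylinder} flag.
#' @return \code{normspots} with an \code{in_cylinder} logical column.
#' @export
cylinder_filter <- function(normspots, cells, drop = FALSE) {
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  Rv <- vapply(cells, `[[`, numeric(1), "R_px")
  Lv <- vapply(cells, `[[`, numeric(1), "L_px")
  j <- match(normspots$cell_id, ids)
  normspots$in_cylinder <- normspots$y_px > Rv[j] &
    normspots$y_px < Lv[j] - Rv[j]
  if (drop) normspots[normspots$in_cylinder, , drop = FALSE] else normspots
}

#' Build a transverse-position (xNorm) histogram with bootstrap SEM
#'
#' Uses only the first \code{frames_per_track} localizations of each track
#' (tracks shorter than that are dropped), so every track contributes
#' equally. Bin probabilities are the fraction of contributing spots per
#' bin; the SEM is estimated by bootstrap resampling of whole tracks, which
#' respects the within-track dependence of the contributed points.
#'
#' @param normspots normalized spots; if an \code{in_cylinder} column is
#'   present only cylindrical spots are used.
#' @param bin bin width on the xNorm axis.
#' @param frames_per_track number of leading localizations per track.
#' @param n_boot bootstrap replicates (0 reports zero SEM); with at
#'   least 30 replicates the full bin covariance is also returned
#'   (\code{boot_cov}), which [fit_mb()] uses to whiten its objective.
#' @param absolute if TRUE, fold xNorm to |xNorm| on [0, 1]; otherwise
#'   signed bins on [-1, 1].
#' @return An \code{xnorm_histogram}: list with bin_lo, bin_hi, prob, sem,
#'   n_spots, n_tracks, absolute, bin.
#' @export
build_xnorm_histogram <- function(normspots, bin = 0.04,
                                  frames_per_track = 4, n_boot = 100,
                                  absolute = TRUE) {
  d <- normspots
  if (!is.null(d$in_cylinder)) d <- d[d$in_cylinder, , drop = FALSE]
  if (nrow(d) == 0L) stop("no spots left after filtering")
  d <- d[order(d$track_id, d$frame), , drop = FALSE]
  first_k <- unlist(lapply(split(seq_len(nrow(d)), d$track_id),
                           function(i) if (length(i) >= frames_per_track)
                             i[seq_len(frames_per_track)] else integer(0)),
                    use.names = FALSE)
  if (length(first_k) == 0L)
    stop("no tracks with at least ", frames_per_track, " localizations")
  x <- d$xNorm[first_k]
  tid <- d$track_id[first_k]
  if (absolute) x <- abs(x)
  lim <- if (absolute) c(0, 1) else c(-1, 1)
  edges <- seq(lim[1], lim[2], by = bin)
  if (abs(edges[length(edges)] - lim[2]) > 1e-12)
    edges <- c(edges, lim[2])
  bin_of <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                      1L), length(edges) - 1L)
  nb <- length(edges) - 1L
  prob <- tabulate(bin_of, nb) / length(x)

  sem <- rep(0, nb)
  boot_cov <- NULL
  if (n_boot > 0) {
    by_track <- split(bin_of, tid)
    nt <- length(by_track)
    boot <- matrix(0, n_boot, nb)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(nt, nt, replace = TRUE)
      bb <- unlist(by_track[pick], use.names = FALSE)
      boot[b, ] <- tabulate(bb, nb) / length(bb)
    }
    sem <- apply(boot, 2, sd)
    # full bin covariance (needs enough replicates to be usable)
    if (n_boot >= 30) boot_cov <- stats::cov(boot)
  }
  structure(list(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 prob = prob, sem = sem, boot_cov = boot_cov,
                 n_boot = n_boot, n_spots = length(x),
                 n_tracks = length(unique(tid)), absolute = absolute,
                 bin = bin),
            class = "xnorm_histogram")
}

#' @export
print.xnorm_histogram <- function(x, ...) {
  cat("xnorm_histogram:", length(x$prob), "bins of width", x$bin,
      if (x$absolute) "(absolute)" else "(signed)", "|", x$n_spots,
      "spots from", x$n_tracks, "tracks\n")
  invisible(x)
}

#' Write / read an xNorm histogram as delimited text
#'
#' Columns: bin_lo, bin_hi, prob, sem; n_spots, n_tracks and the absolute
#' flag are stored in comment header lines.
#'
#' @param hist an \code{xnorm_histogram}.
#' @param path file path.
#' @return \code{read_xnorm_histogram} returns an \code{xnorm_histogram}.
#' @export
write_xnorm_histogram <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_spots=%d n_tracks=%d absolute=%d bin=%.17g",
                     hist$n_spots, hist$n_tracks,
                     as.integer(hist$absolute), hist$bin), con)
  write.table(data.frame(bin_lo = hist$bin_lo, bin_hi = hist$bin_hi,
                         prob = hist$prob, sem = hist$sem),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xnorm_histogram
#' @export
read_xnorm_histogram <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.numeric(sub(".*=", "",
                         strsplit(sub("^# ", "", hdr), " ")[[1]]))
  df <- read.delim(path, comment.char = "#")
  structure(list(bin_lo = df$bin_lo, bin_hi = df$bin_hi, prob = df$prob,
                 sem = df$sem, n_spots = meta[1], n_tracks = meta[2],
                 absolute = as.logical(meta[3]), bin = meta[4]),
            class = "xnorm_histogram")
}
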