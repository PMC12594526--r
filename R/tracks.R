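#' Simulate single-molecule tracks in spherocylindrical cells
#'
#' Each molecule is assigned to the membrane with probability
#' \code{m_true}, otherwise to the cytoplasm. Membrane molecules diffuse on
#' the cylinder surface in the flattened (arc-length, axial) chart with
#' coefficient \code{D_mem}, reflecting at the cap junctions; cytoplasmic
#' molecules diffuse in 3D with \code{D_cyto} inside the cell body,
#' reflecting at the membrane radius and at the poles. The membrane (and
#' with it the whole molecular compartment) sits inside the bright-field
#' outline at radius R / \code{dilF_true}. Motion blur is
#' emulated by recording the average of \code{n_sub} substep positions per
#' frame; isotropic Gaussian localization noise of SD \code{sigma_loc} is
#' added in the image plane. A frame is detected with probability
#' \code{Phi((f_depth + z) / sigma_z)} where z is the frame-mean depth
#' relative to the midplane (the side away from the objective is
#' suppressed); missed frames split a molecule's trajectory into separate
#' tracks, as a tracker without gap closing would. Track lifetimes are
#' geometric with per-frame bleaching probability \code{p_bleach}.
#'
#' @param cells a \code{cell_collection} from [simulate_cells()].
#' @param config the [sim_config()] used to generate \code{cells}.
#' @return A list with elements:
#' \describe{
#'   \item{tracks}{data.frame with movie_id, track_id, frame, x_px, y_px.}
#'   \item{truth}{ground truth: \code{molecules} (molecule_id, cell_id,
#'     compartment, D_true, n_frames), \code{positions} (true per-frame
#'     blurred 3D positions in the cell frame, um, with a detected flag)
#'     and \code{track_map} (track_id to molecule_id).}
#' }
#' @export
simulate_tracks <- function(cells, config) {
  validate_sim_config(config)
  if (length(cells) == 0L) stop("cells must be non-empty")
  px <- config$pixel_size
  n_cells <- length(cells)

  # molecule bookkeeping, vectorized across all cells
  n_mol_per <- pmax(1L, rpois(n_cells,
                              config$spots_per_cell * config$p_bleach))
  n_mol <- sum(n_mol_per)
  cell_idx <- rep(seq_len(n_cells), n_mol_per)
  R_um <- vapply(cells, function(c) c$R_px, numeric(1))[cell_idx] * px
  L_um <- vapply(cells, function(c) c$L_px, numeric(1))[cell_idx] * px
  ox_px <- vapply(cells, function(c) c$centerline[1, 1],
                  numeric(1))[cell_idx]
  oy_px <- vapply(cells, function(c) c$centerline[1, 2],
                  numeric(1))[cell_idx]
  # molecules live on/inside the inner membrane, which sits inside the
  # bright-field outline by the true dilation factor
  r_um <- R_um / config$dilF_true

  is_mem <- runif(n_mol) < config$m_true
  D <- ifelse(is_mem, config$D_mem, config$D_cyto)
  lifetime <- rgeom(n_mol, config$p_bleach) + 1L
  f_cap <- max(10L, ceiling(log(1e-4) / log(1 - config$p_bleach)))
  lifetime <- pmin(lifetime, f_cap)

  # initial positions: membrane uniform on the cylindrical surface,
  # cytoplasm uniform in the cell body
  theta <- runif(n_mol, 0, 2 * pi)
  ya <- numeric(n_mol)
  xt <- numeric(n_mol)
  zd <- numeric(n_mol)
  mem <- which(is_mem); cyt <- which(!is_mem)
  ya[mem] <- runif(length(mem), R_um[mem], L_um[mem] - R_um[mem])
  xt[mem] <- r_um[mem] * cos(theta[mem])
  zd[mem] <- r_um[mem] * sin(theta[mem])
  if (length(cyt)) {
    # uniform in the membrane-bounded spherocylinder body by rejection
    # from the bounding cylinder
    need <- cyt
    while (length(need)) {
      rho <- r_um[need] * sqrt(runif(length(need)))
      ang <- runif(length(need), 0, 2 * pi)
      xc <- rho * cos(ang); zc <- rho * sin(ang)
      ylo <- R_um[need] - r_um[need]
      yc <- runif(length(need), ylo, L_um[need] - ylo)
      ys <- pmin(pmax(yc, R_um[need]), L_um[need] - R_um[need])
      ok <- (yc - ys)^2 + xc^2 + zc^2 <= r_um[need]^2
      xt[need[ok]] <- xc[ok]; zd[need[ok]] <- zc[ok]
      ya[need[ok]] <- yc[ok]
      need <- need[!ok]
    }
  }
  arc <- r_um * theta   # membrane arc-length coordinate

  n_sub <- config$n_sub
  sub_sd <- sqrt(2 * D * config$dt / n_sub)   # per-axis substep SD
  max_f <- max(lifetime)
  frames <- vector("list", max_f)

  for (f in seq_len(max_f)) {
    act <- which(lifetime >= f)
    sa <- sub_sd[act]
    m_act <- act[is_mem[act]]
    c_act <- act[!is_mem[act]]
    acc_a <- numeric(length(act)); acc_x <- acc_a; acc_z <- acc_a
    pos_m <- match(m_act, act); pos_c <- match(c_act, act)
    for (s in seq_len(n_sub)) {
      if (length(m_act)) {
        sm <- sub_sd[m_act]
        arc[m_act] <- arc[m_act] + rnorm(length(m_act), 0, sm)
        yn <- ya[m_act] + rnorm(length(m_act), 0, sm)
        lo <- R_um[m_act]; hi <- L_um[m_act] - R_um[m_act]
        yn <- ifelse(yn < lo, 2 * lo - yn, yn)
        yn <- ifelse(yn > hi, 2 * hi - yn, yn)
        ya[m_act] <- pmin(pmax(yn, lo), hi)
        th <- arc[m_act] / r_um[m_act]
        xt[m_act] <- r_um[m_act] * cos(th)
        zd[m_act] <- r_um[m_act] * sin(th)
      }
      if (length(c_act)) {
        sc <- sub_sd[c_act]
        Rc <- R_um[c_act]; Lc <- L_um[c_act]; rc <- r_um[c_act]
        xn <- xt[c_act] + rnorm(length(c_act), 0, sc)
        zn <- zd[c_act] + rnorm(length(c_act), 0, sc)
        yn <- ya[c_act] + rnorm(length(c_act), 0, sc)
        # reflect at the spherocylinder boundary: fold the distance to
        # the axis spine (axial clamped to the cylindrical range), which
        # handles the lateral wall and both caps uniformly
        ys <- pmin(pmax(yn, Rc), Lc - Rc)
        dd <- sqrt(xn^2 + zn^2 + (yn - ys)^2)
        out <- dd > rc
        if (any(out)) {
          scl <- pmax((2 * rc[out] - dd[out]) / dd[out], 0)
          xn[out] <- xn[out] * scl
          zn[out] <- zn[out] * scl
          yn[out] <- ys[out] + (yn[out] - ys[out]) * scl
        }
        xt[c_act] <- xn; zd[c_act] <- zn; ya[c_act] <- yn
      }
      acc_a <- acc_a + ya[act]
      acc_x <- acc_x + xt[act]
      acc_z <- acc_z + zd[act]
    }
    frames[[f]] <- data.frame(mol = act, frame = f - 1L,
                              a_um = acc_a / n_sub,
                              xt_um = acc_x / n_sub,
                              z_um = acc_z / n_sub)
  }
  pos <- do.call(rbind, frames)
  pos <- pos[order(pos$mol, pos$frame), , drop = FALSE]

  # detection: soft focal cutoff on the frame-mean depth
  if (config$sigma_z > 0) {
    p_det <- pnorm((config$f_depth + pos$z_um) / config$sigma_z)
  } else {
    p_det <- as.numeric(pos$z_um > -config$f_depth)
  }
  pos$detected <- runif(nrow(pos)) < p_det

  # recorded localizations with noise, in global pixel coordinates
  det <- pos[pos$detected, , drop = FALSE]
  ci <- cell_idx[det$mol]
  x_px <- ox_px[det$mol] + det$a_um / px +
    rnorm(nrow(det), 0, config$sigma_loc) / px
  y_px <- oy_px[det$mol] + det$xt_um / px +
    rnorm(nrow(det), 0, config$sigma_loc) / px

  # split each molecule's detected frames into gapless track segments
  new_seg <- c(TRUE, diff(det$mol) != 0L | diff(det$frame) != 1L)
  seg_id <- cumsum(new_seg)
  track_id <- sprintf("t%07d", seg_id)

  tracks <- data.frame(
    movie_id = vapply(cells, `[[`, character(1), "movie_id")[ci],
    track_id = track_id, frame = det$frame,
    x_px = x_px, y_px = y_px, stringsAsFactors = FALSE)

  molecules <- data.frame(
    molecule_id = seq_len(n_mol),
    cell_id = vapply(cells, `[[`, character(1), "cell_id")[cell_idx],
    compartment = ifelse(is_mem, "membrane", "cytoplasm"),
    D_true = D, n_frames = lifetime, stringsAsFactors = FALSE)
  track_map <- data.frame(track_id = track_id[new_seg],
                          molecule_id = det$mol[new_seg],
                          stringsAsFactors = FALSE)
  names(pos)[names(pos) == "mol"] <- "molecule_id"

  list(tracks = tracks,
       truth = list(molecules = molecules, positions = pos,
                    track_map = track_map))
}

#' Simulate free planar Brownian tracks
#'
#' Unconfined 2D Brownian motion with motion blur (substep averaging) and
#' Gaussian localization noise; the elementary ground truth for validating
#' the MSD machinery. This is also the flattened-chart representation of
#' diffusion on the cylinder surface, and with \code{D = 0} it emulates the
#' stationary surface-immobilized emitter control.
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track.
#' @param D diffusion coefficient, um^2/s.
#' @param dt frame interval, s.
#' @param n_sub motion-blur substeps per frame.
#' @param sigma_loc localization error SD, um.
#' @return A list of data.frames (frame, x, y) in um, one per track.
#' @export
simulate_point_tracks <- function(n_tracks, n_frames, D, dt = 0.0217,
                                  n_sub = 10, sigma_loc = 0.02) {
  stopifnot(n_tracks >= 1, n_frames >= 2, D >= 0, dt > 0, n_sub >= 1,
            sigma_loc >= 0)
  sub_sd <- sqrt(2 * D * dt / n_sub)
  n_sub <- as.integer(n_sub)
  one_axis <- function() {
    steps <- matrix(rnorm(n_tracks * n_frames * n_sub, 0, sub_sd),
                    nrow = n_tracks)
    path <- t(apply(steps, 1, cumsum))
    # frame position = mean of the n_sub substep positions
    idx <- matrix(seq_len(n_frames * n_sub), nrow = n_sub)
    blurred <- apply(idx, 2, function(j) rowMeans(path[, j, drop = FALSE]))
    if (n_tracks == 1L) blurred <- matrix(blurred, nrow = 1L)
    blurred + matrix(rnorm(n_tracks * n_frames, 0, sigma_loc),
                     nrow = n_tracks)
  }
  xs <- one_axis(); ys <- one_axis()
  lapply(seq_len(n_tracks), function(i)
    data.frame(frame = seq_len(n_frames) - 1L, x = xs[i, ], y = ys[i, ]))
}

#' Write / read track tables as delimited text
#'
#' Columns: movie_id, track_id, frame, x_px, y_px (tab-separated).
#'
#' @param tracks track data.frame.
#' @param path file path.
#' @return \code{read_tracks} returns the track data.frame.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("movie_id", "track_id", "frame", "x_px", "y_px")
                %in% names(tracks)))
  write.table(tracks[, c("movie_id", "track_id", "frame", "x_px", "y_px")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$track_id <- as.character(df$track_id)
  df
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth the \code{truth} element returned by [simulate_tracks()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Split a pixel-coordinate track table into per-track um trajectories
#'
#' @param tracks track data.frame with track_id, frame, x_px, y_px.
#' @param pixel_size um per pixel.
#' @return Named list of data.frames (frame, x, y) in um, ordered by frame.
#' @export
split_tracks <- function(tracks, pixel_size = 0.160) {
  sp <- split(tracks, tracks$track_id)
  lapply(sp, function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    data.frame(frame = d$frame, x = d$x_px * pixel_size,
               y = d$y_px * pixel_size)
  })
}
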