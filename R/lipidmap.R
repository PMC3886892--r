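#' Align a trajectory onto one body's reference pose
#'
#' Every frame is rigidly transformed (translation plus least-squares
#' planar rotation over the body's particles, Kabsch in 2D) so the chosen
#' protein superposes on its pose in the reference frame; lipids (taken
#' minimum-image relative to the protein) are carried by the same
#' transform.  A reflection-optimal fit is an error.
#'
#' @param traj A `toy_trajectory` with stored lipid frames.
#' @param body Body index or label to align on.
#' @param reference Reference frame index.
#' @return A `toy_trajectory` in the aligned frame, with an attribute
#'   `transforms` (per-frame rotation angles, radians).
#' @export
align_frames <- function(traj, body = 1, reference = 1) {
  if (is.character(body)) body <- match(body, c("protein_A", "protein_B"))
  if (is.null(traj$lipid_xy)) stop("trajectory has no stored lipid frames")
  nf <- length(traj$time)
  stopifnot(reference >= 1, reference <= nf)
  L <- traj$config$box_side
  ref_pts <- body_particles(traj, reference, body)
  ref_com <- traj$com[reference, body, ]
  out <- traj
  ang <- numeric(nf)
  np <- traj$config$n_proteins
  for (i in seq_len(nf)) {
    cur <- body_particles(traj, i, body)
    dphi <- .kabsch2d(sweep(cur, 2, colMeans(cur)),
                      sweep(ref_pts, 2, colMeans(ref_pts)))
    ang[i] <- dphi
    cs <- cos(dphi); sn <- sin(dphi)
    com_i <- traj$com[i, body, ]
    rel <- cbind(traj$lipid_xy[i, , 1] - com_i[1],
                 traj$lipid_xy[i, , 2] - com_i[2])
    rel <- rel - L * round(rel / L)
    out$lipid_xy[i, , 1] <- ref_com[1] + cs * rel[, 1] - sn * rel[, 2]
    out$lipid_xy[i, , 2] <- ref_com[2] + sn * rel[, 1] + cs * rel[, 2]
    for (p in seq_len(np)) {
      relc <- traj$com[i, p, ] - com_i
      relc <- relc - L * round(relc / L)
      out$com[i, p, ] <- ref_com + c(cs * relc[1] - sn * relc[2],
                                     sn * relc[1] + cs * relc[2])
      out$angle[i, p] <- traj$angle[i, p] + dphi
    }
  }
  attr(out, "transforms") <- ang
  out
}

#' Accumulate the 2D lipid density around the aligned protein
#'
#' Counts lipid observations per cell of a square grid centred on the
#' (aligned) protein's centre of mass, over all frames, for the selected
#' leaflet channel.  Frames are weighted equally; the reported density is
#' raw counts per cell (divide by `n_frames` for counts per frame).
#'
#' @param traj An aligned `toy_trajectory` (see [align_frames()]).
#' @param side Side of the square accumulation region.
#' @param cell Grid cell size; must divide `side`.
#' @param channel `"both"`, `"upper"` or `"lower"` leaflet.
#' @param body Body whose COM anchors the region.
#' @return Object of class `density_map`: `counts` (matrix, x by y),
#'   `side`, `cell`, `center`, `n_frames`, `channel`.
#' @export
accumulate_density <- function(traj, side = 8, cell = side / 120,
                               channel = c("both", "upper", "lower"),
                               body = 1) {
  channel <- match.arg(channel)
  if (is.null(traj$lipid_xy) || length(traj$time) == 0)
    stop("empty trajectory: no lipid frames to accumulate")
  nx <- side / cell
  if (abs(nx - round(nx)) > 1e-9) stop("cell size must divide region side")
  nx <- as.integer(round(nx))
  center <- traj$com[1, body, ]
  sel <- if (channel == "both") rep(TRUE, length(traj$leaflet))
         else traj$leaflet == channel
  x <- as.vector(traj$lipid_xy[, sel, 1]) - center[1]
  y <- as.vector(traj$lipid_xy[, sel, 2]) - center[2]
  inr <- abs(x) < side / 2 & abs(y) < side / 2
  ix <- floor((x[inr] + side / 2) / cell) + 1
  iy <- floor((y[inr] + side / 2) / cell) + 1
  counts <- matrix(tabulate((iy - 1) * nx + ix, nbins = nx * nx),
                   nrow = nx, ncol = nx)
  structure(list(counts = counts, side = side, cell = cell,
                 center = center, n_frames = length(traj$time),
                 channel = channel),
            class = "density_map")
}

# bilinear interpolation of a cell-centred grid at points (px, py)
# relative to the map centre; outside values are 0
.interp_map <- function(map, px, py) {
  n <- nrow(map$counts)
  g <- map$counts / map$n_frames
  u <- (px + map$side / 2) / map$cell + 0.5 # grid coordinates (1-based)
  v <- (py + map$side / 2) / map$cell + 0.5
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  val <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    z <- numeric(length(i))
    z[ok] <- g[cbind(i[ok], j[ok])]
    z
  }
  val(i0, j0) * (1 - fu) * (1 - fv) + val(i0 + 1, j0) * fu * (1 - fv) +
    val(i0, j0 + 1) * (1 - fu) * fv + val(i0 + 1, j0 + 1) * fu * fv
}

#' Project the 2D density onto lines from the protein centre
#'
#' Samples the density map by bilinear interpolation along a fan of lines
#' emanating from the protein's centre of mass — `direction` plus/minus
#' offsets up to `half_window` at `spacing` — and averages across the
#' lines into distance bins.
#'
#' @param map A [accumulate_density()] result.
#' @param direction Central direction, degrees.
#' @param half_window Angular half-window, degrees (> 0).
#' @param spacing Angular spacing between lines, degrees
#'   (`<= 2 * half_window`).
#' @param line_length Length of the projection lines; every line must
#'   stay inside the map region.
#' @return Object of class `radial_profile`: data frame
#'   `distance`, `density`, with full provenance attributes.
#' @export
radial_projection <- function(map, direction, half_window = 15,
                              spacing = 1, line_length = map$side / 2) {
  stopifnot(inherits(map, "density_map"), half_window > 0,
            spacing <= 2 * half_window, spacing > 0)
  offs <- seq(-half_window, half_window, by = spacing)
  if (half_window >= 180) offs <- offs[offs < 180] # avoid duplicate line
  angs <- (direction + offs) * pi / 180
  if (any(line_length * pmax(abs(cos(angs)), abs(sin(angs))) >
          map$side / 2 + 1e-9))
    stop("projection line extends beyond the density region")
  dr <- map$cell
  r <- seq(dr / 2, line_length, by = dr)
  prof <- rowMeans(vapply(angs, function(a) {
    .interp_map(map, r * cos(a), r * sin(a))
  }, numeric(length(r))))
  structure(data.frame(distance = r, density = prof),
            direction = direction, half_window = half_window,
            spacing = spacing, line_length = line_length,
            channel = map$channel, n_lines = length(angs),
            class = c("radial_profile", "data.frame"))
}

#' Mean of radial profiles over channels / leaflets
#'
#' @param profiles List of [radial_projection()] results with identical
#'   distance bins.
#' @return A `radial_profile` of the unweighted per-bin mean; the
#'   `channel` attribute lists the averaged inputs.
#' @export
mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  d0 <- profiles[[1]]$distance
  for (p in profiles) {
    if (length(p$distance) != length(d0) ||
        max(abs(p$distance - d0)) > 1e-9)
      stop("profiles have mismatched distance bins")
  }
  dens <- rowMeans(vapply(profiles, `[[`, numeric(length(d0)), "density"))
  out <- profiles[[1]]
  out$density <- dens
  attr(out, "channel") <-
    paste(vapply(profiles, function(p) attr(p, "channel"), ""),
          collapse = "+")
  out
}

#' Detect lipid-shell peaks in a radial profile
#'
#' Local maxima passing prominence and minimum-spacing filters (greedy,
#' keeping the higher peak), refined to sub-bin resolution by three-point
#' parabolic interpolation.
#'
#' @param profile A `radial_profile`.
#' @param min_prominence Minimum peak prominence (density units).
#' @param min_separation Minimum spacing between retained peaks.
#' @return Object of class `peak_set`: data frame `position`, `height`
#'   (strictly increasing positions; possibly zero rows).
#' @export
detect_peaks <- function(profile, min_prominence = 0, min_separation = 0) {
  y <- profile$density; x <- profile$distance
  n <- length(y)
  stopifnot(n >= 1)
  cand <- which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && y[i] > y[i - 1] && y[i] > y[i + 1]
  }, logical(1)))
  if (min_prominence > 0 && length(cand)) {
    cand <- cand[vapply(cand, function(i) {
      .prominence(-y, i) >= min_prominence
    }, logical(1))]
  }
  if (min_separation > 0 && length(cand) > 1) {
    keep <- integer(0)
    for (i in cand[order(-y[cand])]) {
      if (!length(keep) || all(abs(x[i] - x[keep]) >= min_separation))
        keep <- c(keep, i)
    }
    cand <- sort(keep)
  }
  pos <- hei <- numeric(length(cand))
  dr <- if (n > 1) x[2] - x[1] else 0
  for (j in seq_along(cand)) {
    i <- cand[j]
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    pos[j] <- x[i] + delta * dr
    hei[j] <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta
  }
  structure(data.frame(position = pos, height = hei),
            min_prominence = min_prominence,
            min_separation = min_separation,
            class = c("peak_set", "data.frame"))
}

#' Predict packed inter-protein separations from shell peaks
#'
#' Overlay the single-protein radial density with its x-reversed copy,
#' the reversed origin placed at a trial separation `s` (reversed peak
#' `j` lands at `s - r_j`), and choose `s` so the prescribed peak pairs
#' coincide:
#' * 1 intervening lipid: first peak on first reversed peak,
#'   `s = 2 r_1`;
#' * 2 intervening lipids: first peak on second reversed peak,
#'   `s = r_1 + r_2`;
#' * 3 intervening lipids: first on third *and* second on second —
#'   overdetermined, resolved by least squares over the two pairs,
#'   `s = ((r_1 + r_3) + 2 r_2) / 2`.
#'
#' The predicted separation is the position of the reversed profile's
#' origin edge, i.e. the predicted position of the second protein's
#' centre of mass.
#'
#' @param peaks A [detect_peaks()] result (or data frame with a
#'   `position` column), >= `n_intervening` peaks.
#' @param n_intervening Number of intervening lipids (1, 2 or 3).
#' @return Object of class `separation_prediction`: `n_intervening`,
#'   `separation`, `pairs` (matrix of matched peak indices).
#' @export
predict_separations <- function(peaks, n_intervening) {
  r <- peaks$position
  if (n_intervening < 1) stop("n_intervening must be >= 1")
  if (n_intervening > 3)
    stop("peak pairings are defined only for up to 3 intervening lipids")
  if (length(r) < n_intervening)
    stop(sprintf("need at least %d peaks, have %d", n_intervening,
                 length(r)))
  pairs <- switch(n_intervening,
                  rbind(c(1, 1)),
                  rbind(c(1, 2)),
                  rbind(c(1, 3), c(2, 2)))
  # least squares over matched pairs of r_i = s - r_j
  s <- mean(r[pairs[, 1]] + r[pairs[, 2]])
  structure(list(n_intervening = as.integer(n_intervening),
                 separation = s, pairs = pairs),
            class = "separation_prediction")
}

#' @export
print.separation_prediction <- function(x, ...) {
  cat(sprintf("predicted separation %.4f with %d intervening lipid(s)\n",
              x$separation, x$n_intervening))
  invisible(x)
}

#' Count lipids in the inter-protein gap
#'
#' For each stored frame of a two-body trajectory, counts the lipids
#' whose centres lie strictly between the two bodies' facing surfaces
#' (within `half_width` of the inter-COM axis).  Used to classify PMF
#' minima by the number of intervening lipids.
#'
#' @param traj A two-body `toy_trajectory` with lipid frames.
#' @param half_width Half-width of the counting channel perpendicular to
#'   the inter-COM axis (default: one lipid diameter).
#' @return Numeric vector of per-frame counts.
#' @export
count_intervening_lipids <- function(traj, half_width = NULL) {
  stopifnot(traj$config$n_proteins == 2L)
  if (is.null(traj$lipid_xy)) stop("trajectory has no stored lipid frames")
  if (is.null(half_width)) half_width <- traj$config$lipid_diameter
  L <- traj$config$box_side
  ab <- traj$config$protein_semi_axes
  # ellipse support: extent along a direction at angle psi to the body
  # x-axis is sqrt((a cos psi)^2 + (b sin psi)^2)
  extent <- function(phi, ux, uy) {
    cs <- cos(phi); sn <- sin(phi)
    bx <- ux * cs + uy * sn
    by <- -ux * sn + uy * cs
    sqrt((ab[1] * bx)^2 + (ab[2] * by)^2)
  }
  vapply(seq_along(traj$time), function(i) {
    dvec <- traj$com[i, 2, ] - traj$com[i, 1, ]
    dvec <- dvec - L * round(dvec / L)
    d <- sqrt(sum(dvec^2))
    u <- dvec / d
    hA <- extent(traj$angle[i, 1], u[1], u[2])
    hB <- extent(traj$angle[i, 2], -u[1], -u[2])
    rel <- cbind(traj$lipid_xy[i, , 1] - traj$com[i, 1, 1],
                 traj$lipid_xy[i, , 2] - traj$com[i, 1, 2])
    rel <- rel - L * round(rel / L)
    s_par <- rel[, 1] * u[1] + rel[, 2] * u[2]
    s_perp <- -rel[, 1] * u[2] + rel[, 2] * u[1]
    sum(s_par > hA & s_par < d - hB & abs(s_perp) < half_width)
  }, numeric(1))
}
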