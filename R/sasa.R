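#' Deterministic unit-sphere test points (generalized spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n = 960) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- i * pi * (3 - sqrt(5)) # golden-angle spiral
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Probe-accessible surface area (Shrake-Rupley)
#'
#' Numerical accessible surface area of a set of spheres: for each
#' particle, the fraction of a deterministic point set on its
#' probe-inflated sphere not buried inside any other inflated sphere,
#' times that sphere's area.  Deterministic for a fixed point count.
#'
#' @param centers n x 3 matrix of particle centres (for planar toy
#'   bodies, supply `z = 0`).
#' @param radii Particle radii (recycled if scalar), all > 0.
#' @param probe Probe radius (>= 0); the lipid-sized probe of the buried
#'   surface analysis.
#' @param n_points Test points per sphere.
#' @return Total accessible area, with per-particle areas as attribute
#'   `per_particle`.
#' @export
accessible_area <- function(centers, radii, probe = 0.4, n_points = 960) {
  centers <- as.matrix(centers)
  if (ncol(centers) == 2) centers <- cbind(centers, 0)
  n <- nrow(centers)
  radii <- rep_len(radii, n)
  stopifnot(all(radii > 0), probe >= 0)
  if (n > 1) {
    dmin <- min(dist(centers))
    if (dmin < 1e-9) stop("coincident particle centres")
  }
  pts <- sphere_points(n_points)
  R <- radii + probe
  per <- numeric(n)
  cc2 <- as.matrix(dist(centers))^2
  for (i in seq_len(n)) {
    nb <- which(cc2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    if (!length(nb)) {
      per[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, centers[i, ], "+")
    # squared distance of every test point to every neighbour in one go
    cn <- centers[nb, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(cn^2), "+") - 2 * p %*% t(cn)
    buried <- rowSums(d2 < matrix(R[nb]^2, n_points, length(nb),
                                  byrow = TRUE)) > 0
    per[i] <- 4 * pi * R[i]^2 * (1 - mean(buried))
  }
  structure(sum(per), per_particle = per)
}

#' Buried surface area of a two-body complex
#'
#' `buried = area_A + area_B - area_complex`, all three computed with the
#' same probe on the same particle sets.  Toy bodies are treated as
#' spheres of the configured ring-particle radius stacked in the membrane
#' plane (fixed out-of-plane coordinate).
#'
#' @param coords_A,coords_B Particle centres of the two bodies
#'   (n x 2 or n x 3 matrices).
#' @param radius_A,radius_B Particle radii (scalars or vectors).
#' @param probe Probe radius.
#' @param n_points Test points per sphere.
#' @param separation Optional separation annotation carried in the
#'   record.
#' @return Object of class `surface_area_record`: `area_A`, `area_B`,
#'   `area_complex`, `buried`, `probe`, `separation`.
#' @export
buried_area <- function(coords_A, coords_B, radius_A, radius_B,
                        probe = 0.4, n_points = 960, separation = NA) {
  to3 <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) == 2) cbind(m, 0) else m
  }
  A <- to3(coords_A); B <- to3(coords_B)
  rA <- rep_len(radius_A, nrow(A)); rB <- rep_len(radius_B, nrow(B))
  aA <- as.numeric(accessible_area(A, rA, probe, n_points))
  aB <- as.numeric(accessible_area(B, rB, probe, n_points))
  aC <- as.numeric(accessible_area(rbind(A, B), c(rA, rB), probe, n_points))
  structure(list(area_A = aA, area_B = aB, area_complex = aC,
                 buried = aA + aB - aC, probe = probe,
                 separation = separation),
            class = "surface_area_record")
}

#' @export
print.surface_area_record <- function(x, ...) {
  cat(sprintf("SASA: A %.2f, B %.2f, complex %.2f -> buried %.2f (probe %.2f)\n",
              x$area_A, x$area_B, x$area_complex, x$buried, x$probe))
  invisible(x)
}

#' Buried area of one toy-trajectory frame
#'
#' @param traj A two-body `toy_trajectory`.
#' @param frame Frame index.
#' @param probe Probe radius (default: the toy lipid radius, the
#'   lipid-sized probe).
#' @param n_points Test points per sphere.
#' @return A `surface_area_record`.
#' @export
toy_buried_area <- function(traj, frame, probe = NULL, n_points = 480) {
  stopifnot(traj$config$n_proteins == 2L)
  if (is.null(probe)) probe <- traj$config$lipid_diameter / 2
  rb <- traj$config$body_particle_diameter / 2
  L <- traj$config$box_side
  A <- body_particles(traj, frame, 1)
  B <- body_particles(traj, frame, 2)
  # bring B minimum-image next to A so the periodic wrap cannot split
  # the complex
  dc <- traj$com[frame, 2, ] - traj$com[frame, 1, ]
  shift <- -L * round(dc / L)
  B <- sweep(B, 2, shift, "+")
  d <- sqrt(sum((dc + shift)^2))
  buried_area(A, B, rb, rb, probe, n_points, separation = d)
}

#' Buried-area profile along the reaction coordinate
#'
#' Frame-averaged buried surface area per umbrella window, with the
#' abscissa expressed as distance of the window centre from the PMF
#' minimum (removing the protein-radius offset between orientational
#' configurations).
#'
#' @param windows List of [umbrella_window()]s with attached
#'   trajectories, ordered by separation.
#' @param minimum_location Location of the PMF minimum for this
#'   configuration.
#' @param probe Probe radius.
#' @param frame_stride Analyse every `frame_stride`-th stored frame.
#' @param n_points Test points per sphere.
#' @return Data frame (class `buried_area_profile`) with one row per
#'   window: `center`, `distance_from_min`, `mean_buried`, `sd_buried`
#'   (standard deviation over analysed frames), `n_frames`.
#' @export
buried_area_profile <- function(windows, minimum_location, probe = NULL,
                                frame_stride = 1L, n_points = 480) {
  if (is.na(minimum_location)) stop("missing PMF minimum location")
  # monomer areas are constant for rigid bodies: compute once
  aAB <- NULL
  rows <- lapply(windows, function(w) {
    traj <- w$trajectory
    if (is.null(traj)) stop("window has no attached trajectory")
    if (is.null(probe)) probe <<- traj$config$lipid_diameter / 2
    rb <- traj$config$body_particle_diameter / 2
    if (is.null(aAB)) {
      ring <- body_particles(traj, 1, 1)
      aAB <<- as.numeric(accessible_area(cbind(ring, 0), rb, probe,
                                         n_points))
    }
    L <- traj$config$box_side
    idx <- seq(1, length(traj$time), by = frame_stride)
    b <- vapply(idx, function(i) {
      A <- body_particles(traj, i, 1)
      B <- body_particles(traj, i, 2)
      dc <- traj$com[i, 2, ] - traj$com[i, 1, ]
      B <- sweep(B, 2, -L * round(dc / L), "+")
      comp <- as.numeric(accessible_area(rbind(cbind(A, 0), cbind(B, 0)),
                                         rb, probe, n_points))
      2 * aAB - comp
    }, numeric(1))
    data.frame(center = w$bias$center,
               distance_from_min = w$bias$center - minimum_location,
               mean_buried = mean(b),
               sd_buried = if (length(b) > 1) sd(b) else 0,
               n_frames = length(b))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("buried_area_profile", "data.frame")
  out
}

#' Buried area at the PMF minimum by local straight-line fit
#'
#' Ordinary least-squares line over the profile points within
#' `half_range` of the minimum (abscissa 0), evaluated at 0.
#'
#' @param profile A [buried_area_profile()].
#' @param half_range Fit half-range around the minimum.
#' @return Fitted buried area at the minimum; attribute `extrapolated`
#'   flags fits whose points all lie on one side of 0; attribute
#'   `slope` carries the fitted slope.
#' @export
area_at_minimum <- function(profile, half_range = 0.3) {
  sel <- abs(profile$distance_from_min) <= half_range
  if (sum(sel) < 3) stop("fewer than 3 profile points within the fit range")
  x <- profile$distance_from_min[sel]
  y <- profile$mean_buried[sel]
  co <- coef(lm(y ~ x))
  structure(unname(co[1]),
            slope = unname(co[2]),
            extrapolated = all(x > 0) || all(x < 0))
}

#' Well depth versus buried surface area across configurations
#'
#' Ordinary least squares of well depth on buried area at the minimum,
#' plus the Pearson correlation — the deeper-well / larger-interface
#' relation across orientational configurations.
#'
#' @param points Data frame with columns `depth` (well depths, negative
#'   energies) and `area` (buried areas at the respective minima); >= 3
#'   configurations with non-degenerate areas.
#' @return List `slope`, `intercept`, `correlation`, `n`.
#' @export
depth_vs_area <- function(points) {
  stopifnot(nrow(points) >= 3)
  if (sd(points$area) < 1e-12)
    stop("degenerate buried areas: no spread to regress on")
  fit <- lm(depth ~ area, data = points)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       correlation = cor(points$area, points$depth), n = nrow(points))
}
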