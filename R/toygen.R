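#' Configuration of the quasi-2D toy membrane
#'
#' The toy membrane is a periodic square box in the membrane plane holding
#' up to two rigid protein bodies of elliptical cross-section (each a ring
#' of particles) and a sea of repulsive lipid discs, evolved by overdamped
#' Langevin dynamics at fixed temperature.  It is a seeded stand-in for
#' coarse-grained bilayer simulations: it reproduces their *statistical*
#' structure (Boltzmann sampling, annular lipid shells, discrete packing
#' between approaching bodies), not their chemistry.
#'
#' All quantities are in dimensionless toy units; `length_scale_nm`
#' declares the nominal nm-equivalent of one toy length unit and is echoed
#' into all outputs so that no toy number can masquerade as a physical one.
#'
#' @param box_side Side of the periodic square box.
#' @param n_lipids Number of lipid discs.
#' @param lipid_diameter Diameter of a lipid disc.
#' @param protein_semi_axes Length-2 vector `c(wide, narrow)` of the
#'   elliptical body semi-axes; `wide >= narrow`.
#' @param n_body_particles Number of particles on each body's perimeter
#'   ring; must be a multiple of 4 so a marker particle sits exactly on
#'   the wide face (end of the minor axis).
#' @param body_particle_diameter Diameter of each body ring particle.
#' @param temperature Thermal energy (k_B T) in toy energy units.
#' @param friction Friction coefficient per particle (inverse time).
#' @param epsilon_rep Strength of the half-harmonic soft-core repulsion,
#'   in units of the toy energy; large values approach hard discs.
#' @param timestep Integration timestep.
#' @param n_steps Default number of integration steps.
#' @param frame_stride Steps between stored frames.
#' @param sample_stride Steps between reaction-coordinate samples.
#' @param n_proteins 1 (single diffusing body) or 2 (dimerization setup).
#' @param seed Default random seed.
#' @param length_scale_nm Declared nm-equivalent of one toy length unit.
#'
#' @return An object of class `toy_config`.
#' @export
toy_config <- function(box_side = 15, n_lipids = 240, lipid_diameter = 0.8,
                       protein_semi_axes = c(1.5, 1.0),
                       n_body_particles = 24, body_particle_diameter = 0.6,
                       temperature = 1, friction = 1, epsilon_rep = 60,
                       timestep = 1e-3, n_steps = 20000L,
                       frame_stride = 200L, sample_stride = 10L,
                       n_proteins = 2L, seed = 1L, length_scale_nm = 1) {
  stopifnot(length(protein_semi_axes) == 2)
  if (protein_semi_axes[1] < protein_semi_axes[2])
    stop("protein_semi_axes must satisfy wide >= narrow")
  if (n_lipids < 0 || timestep <= 0 || temperature <= 0 || friction <= 0)
    stop("require n_lipids >= 0, timestep > 0, temperature > 0, friction > 0")
  if (box_side <= 2 * (max(protein_semi_axes) + 2 * lipid_diameter))
    stop("box_side too small: must exceed 2*(largest semi-axis + 2 lipid diameters)")
  if (n_body_particles %% 4 != 0 || n_body_particles < 8)
    stop("n_body_particles must be a multiple of 4, >= 8")
  if (!n_proteins %in% c(1L, 2L)) stop("n_proteins must be 1 or 2")
  structure(list(
    box_side = box_side, n_lipids = as.integer(n_lipids),
    lipid_diameter = lipid_diameter, protein_semi_axes = protein_semi_axes,
    n_body_particles = as.integer(n_body_particles),
    body_particle_diameter = body_particle_diameter,
    temperature = temperature, friction = friction,
    epsilon_rep = epsilon_rep, timestep = timestep,
    n_steps = as.integer(n_steps), frame_stride = as.integer(frame_stride),
    sample_stride = as.integer(sample_stride),
    n_proteins = as.integer(n_proteins), seed = as.integer(seed),
    length_scale_nm = length_scale_nm
  ), class = "toy_config")
}

#' @export
print.toy_config <- function(x, ...) {
  cat("Toy membrane configuration (", x$n_proteins, " protein(s), ",
      x$n_lipids, " lipids, box ", x$box_side, " x ", x$box_side, ")\n",
      sep = "")
  cat("  semi-axes ", x$protein_semi_axes[1], "/", x$protein_semi_axes[2],
      ", lipid diameter ", x$lipid_diameter, ", T = ", x$temperature,
      ", dt = ", x$timestep, "\n", sep = "")
  cat("  1 toy length unit ~ ", x$length_scale_nm, " nm (declared scale)\n",
      sep = "")
  invisible(x)
}

#' Body-frame ring coordinates of a toy protein
#'
#' Particles are placed on the ellipse `(a cos t, b sin t)`; the marker
#' particle used for orientation angles sits at body-frame `(0, b)`, i.e.
#' on the wide face at the end of the minor axis.
#'
#' @param config A [toy_config()].
#' @return A matrix with `n_body_particles` rows and attribute
#'   `marker_index`.
#' @export
toy_body_ring <- function(config) {
  n <- config$n_body_particles
  t <- 2 * pi * (seq_len(n) - 1) / n
  xy <- cbind(config$protein_semi_axes[1] * cos(t),
              config$protein_semi_axes[2] * sin(t))
  attr(xy, "marker_index") <- n / 4 + 1L # parameter angle 90 deg -> (0, b)
  xy
}

# internal: body rotation angle phi (radians) realizing an orientation
# angle theta (degrees, measured from the A->B line to the COM->marker
# arrow, counter-clockwise from the extracellular side).  The marker is at
# body (0, b), whose direction in the lab frame is phi + 90 deg.
.phi_from_theta <- function(theta_deg) (theta_deg - 90) * pi / 180

#' Simulate the toy membrane
#'
#' Runs seeded overdamped Langevin dynamics of the configured system,
#' optionally under a harmonic umbrella bias on the inter-body
#' centre-of-mass separation and torque-only orientational restraints.
#' Identical `(config, restraints, seed)` give bit-identical trajectories.
#'
#' @param config A [toy_config()].
#' @param restraints A [restraint_set()] (may be `NULL` for free dynamics).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param separation Initial centre-of-mass separation for two-body
#'   systems; defaults to the umbrella centre if a bias is present.
#' @param orientations Initial orientation angles (degrees) of the bodies,
#'   `c(theta_A, theta_B)`; also the restraint target when rotational
#'   restraints are present without explicit references.
#' @param n_steps,store_frames Override the configured step count; choose
#'   whether per-frame lipid coordinates are kept (body poses always are).
#'
#' @return An object of class `toy_trajectory` with elements `time`,
#'   `lipid_xy` (`n_frames x n_lipids x 2`, or `NULL`), `com`
#'   (`n_frames x n_proteins x 2`), `angle`, `separation` (data frame of
#'   the reaction-coordinate series), `leaflet`, `body_xy`, `config`,
#'   and a metadata echo of the restraints and seed.
#' @export
simulate_toy_membrane <- function(config, restraints = NULL,
                                  seed = config$seed, separation = NULL,
                                  orientations = c(0, 0),
                                  n_steps = config$n_steps,
                                  store_frames = TRUE, gap_lipids = 0L) {
  stopifnot(inherits(config, "toy_config"))
  if (!is.null(restraints) && !inherits(restraints, "restraint_set"))
    stop("restraints must be a restraint_set or NULL")
  bias <- restraints$bias
  np <- config$n_proteins
  if (is.null(separation))
    separation <- if (!is.null(bias)) bias$center else 0.45 * config$box_side
  if (np == 2 && separation >= config$box_side / 2)
    stop("initial separation must be below half the box side")

  body_xy <- toy_body_ring(config)
  half <- config$box_side / 2
  if (np == 2) {
    com0 <- c(half - separation / 2, half, half + separation / 2, half)
    phi0 <- .phi_from_theta(orientations[1:2])
  } else {
    com0 <- c(half, half)
    phi0 <- .phi_from_theta(orientations[1])
  }

  # rotational restraint parameters: target angles from the reference
  # positions when given, otherwise the initial orientations
  k_rot <- 0
  eps_reg <- 1e-2
  theta_ref <- phi0
  rots <- restraints$rotational
  if (length(rots)) {
    k_rot <- rots[[1]]$force_constant
    eps_reg <- rots[[1]]$epsilon
    for (r in rots) {
      p <- match(r$body, c("protein_A", "protein_B"))
      if (!is.na(p) && p <= np && !is.null(r$reference)) {
        rel <- sweep(r$reference, 2, colMeans(r$reference))
        theta_ref[p] <- .fit_rotation_angle(body_xy, rel)
      }
    }
  }

  set.seed(seed)
  lipids0 <- .place_lipids(config, com0, phi0, body_xy,
                           gap_lipids = gap_lipids)

  sig_l <- config$lipid_diameter
  sig_b <- config$body_particle_diameter
  res <- cpp_sim_run(
    lipids0, body_xy, com0, phi0, np,
    config$box_side, config$timestep, config$temperature, config$friction,
    config$epsilon_rep, sig_l, (sig_l + sig_b) / 2, sig_b,
    if (is.null(bias)) -1 else bias$force_constant,
    if (is.null(bias)) 0 else bias$center,
    k_rot, eps_reg, theta_ref,
    as.integer(n_steps), config$frame_stride, config$sample_stride,
    isTRUE(store_frames)
  )

  nf <- res$n_frames
  nl <- config$n_lipids
  lipid_xy <- NULL
  if (isTRUE(store_frames) && nl > 0) {
    lipid_xy <- aperm(array(res$lipid_frames, dim = c(2, nl, nf)), c(3, 2, 1))
  }
  com <- aperm(array(res$com_frames, dim = c(2, np, nf)), c(3, 2, 1))
  angle <- matrix(res$angle_frames, nrow = nf, ncol = np, byrow = TRUE)
  sep <- if (np == 2)
    data.frame(time = res$sample_time, separation = res$sep_series)
  else NULL

  structure(list(
    time = res$frame_time, lipid_xy = lipid_xy, com = com, angle = angle,
    separation = sep,
    leaflet = rep_len(c("upper", "lower"), nl),
    body_xy = body_xy, config = config, seed = as.integer(seed),
    restraints = list(
      k_umb = if (is.null(bias)) 0 else bias$force_constant,
      d0 = if (is.null(bias)) NA_real_ else bias$center,
      k_rot = k_rot, epsilon = eps_reg,
      theta_ref_deg = theta_ref * 180 / pi + 90
    )
  ), class = "toy_trajectory")
}

# jittered-lattice lipid placement excluding body interiors, with bounded
# rejection retries per particle; optionally seeds `gap_lipids` lipids in
# single file between the two bodies (the lipidated start of the
# lipidation/delipidation protocol)
.place_lipids <- function(config, com0, phi0, body_xy, gap_lipids = 0L) {
  nl <- config$n_lipids
  if (nl == 0) return(matrix(numeric(0), 0, 2))
  L <- config$box_side
  np <- config$n_proteins
  sig_lb <- (config$lipid_diameter + config$body_particle_diameter) / 2

  gap_pts <- NULL
  if (gap_lipids > 0 && np == 2) {
    ab <- config$protein_semi_axes
    ext <- function(phi, ux, uy) {
      bx <- ux * cos(phi) + uy * sin(phi)
      by <- -ux * sin(phi) + uy * cos(phi)
      sqrt((ab[1] * bx)^2 + (ab[2] * by)^2)
    }
    dvec <- c(com0[3] - com0[1], com0[4] - com0[2])
    d <- sqrt(sum(dvec^2))
    u <- dvec / d
    hA <- ext(phi0[1], u[1], u[2]) + config$body_particle_diameter / 2
    hB <- ext(phi0[2], -u[1], -u[2]) + config$body_particle_diameter / 2
    slot <- d - hA - hB
    s <- hA + (seq_len(gap_lipids) - 0.5) * slot / gap_lipids
    gap_pts <- cbind(com0[1] + s * u[1], com0[2] + s * u[2])
  }

  world <- NULL # all body particles, world frame
  for (p in seq_len(np)) {
    cs <- cos(phi0[p]); sn <- sin(phi0[p])
    world <- rbind(world, cbind(
      com0[2 * p - 1] + cs * body_xy[, 1] - sn * body_xy[, 2],
      com0[2 * p] + sn * body_xy[, 1] + cs * body_xy[, 2]
    ))
  }
  min_dist2 <- function(pts) {
    d2 <- rep(Inf, nrow(pts))
    for (k in seq_len(nrow(world))) {
      dx <- pts[, 1] - world[k, 1]; dx <- dx - L * round(dx / L)
      dy <- pts[, 2] - world[k, 2]; dy <- dy - L * round(dy / L)
      d2 <- pmin(d2, dx^2 + dy^2)
    }
    d2
  }

  n_gap <- if (is.null(gap_pts)) 0L else nrow(gap_pts)
  n_bulk <- nl - n_gap
  m <- floor(L / config$lipid_diameter)
  sp <- L / m
  g <- (seq_len(m) - 0.5) * sp
  sites <- as.matrix(expand.grid(x = g, y = g))
  # exclude sites inside/too close to a body (with jitter head-room)
  ok <- min_dist2(sites) > (sig_lb + 0.15 * sp)^2
  if (n_gap > 0) {
    for (k in seq_len(n_gap)) {
      dx <- sites[, 1] - gap_pts[k, 1]; dx <- dx - L * round(dx / L)
      dy <- sites[, 2] - gap_pts[k, 2]; dy <- dy - L * round(dy / L)
      ok <- ok & (dx^2 + dy^2 > config$lipid_diameter^2)
    }
  }
  sites <- sites[ok, , drop = FALSE]
  if (nrow(sites) < n_bulk)
    stop(sprintf("placement error: only %d usable lattice sites for %d lipids",
                 nrow(sites), n_bulk))
  sites <- sites[sample.int(nrow(sites), n_bulk), , drop = FALSE]
  jit <- matrix(runif(2 * n_bulk, -0.1 * sp, 0.1 * sp), ncol = 2)
  pts <- rbind(gap_pts, sites + jit)
  # re-jitter bulk lipids that landed too close to a body; gap lipids are
  # deliberately wall-adjacent and exempt
  bulk <- seq_len(nl) > n_gap
  bad <- min_dist2(pts) <= sig_lb^2 & bulk
  tries <- 0
  while (any(bad) && tries < 25) {
    pts[bad, ] <- sites[bad[bulk], , drop = FALSE] +
      matrix(runif(2 * sum(bad), -0.05 * sp, 0.05 * sp), ncol = 2)
    bad <- min_dist2(pts) <= sig_lb^2 & bulk
    tries <- tries + 1
  }
  if (any(bad)) stop("placement error: unresolved lipid-protein overlap")
  pts[, 1] <- pts[, 1] %% L
  pts[, 2] <- pts[, 2] %% L
  pts
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat("Toy trajectory:", length(x$time), "frames,",
      x$config$n_proteins, "protein(s),", x$config$n_lipids, "lipids\n")
  cat("  seed", x$seed, "| k_umb", x$restraints$k_umb,
      "| k_rot", x$restraints$k_rot, "\n")
  invisible(x)
}

#' World-frame body particle coordinates in one frame
#'
#' @param traj A `toy_trajectory`.
#' @param frame Frame index.
#' @param body 1 or 2, or `"protein_A"`/`"protein_B"`.
#' @return Matrix of particle coordinates (one row per ring particle).
#' @export
body_particles <- function(traj, frame, body = 1) {
  if (is.character(body)) body <- match(body, c("protein_A", "protein_B"))
  phi <- traj$angle[frame, body]
  cs <- cos(phi); sn <- sin(phi)
  cbind(traj$com[frame, body, 1] + cs * traj$body_xy[, 1] - sn * traj$body_xy[, 2],
        traj$com[frame, body, 2] + sn * traj$body_xy[, 1] + cs * traj$body_xy[, 2])
}

#' Extract one frame as a labelled particle table
#'
#' @param traj A `toy_trajectory` (with stored lipid frames).
#' @param frame Frame index.
#' @return Data frame with columns `time`, `body_label`, `lipid_id`,
#'   `leaflet`, `x`, `y` — one row per particle.
#' @export
as_frame <- function(traj, frame) {
  np <- traj$config$n_proteins
  out <- NULL
  for (p in seq_len(np)) {
    bp <- body_particles(traj, frame, p)
    out <- rbind(out, data.frame(
      time = traj$time[frame],
      body_label = c("protein_A", "protein_B")[p],
      lipid_id = NA_integer_, leaflet = NA_character_,
      x = bp[, 1], y = bp[, 2]))
  }
  if (!is.null(traj$lipid_xy)) {
    nl <- dim(traj$lipid_xy)[2]
    out <- rbind(out, data.frame(
      time = traj$time[frame], body_label = "lipid",
      lipid_id = seq_len(nl), leaflet = traj$leaflet,
      x = traj$lipid_xy[frame, , 1], y = traj$lipid_xy[frame, , 2]))
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# exact 1D reference systems

#' Define a 1D reference potential
#'
#' Analytic 1D systems used as exact oracles for the umbrella-sampling /
#' WHAM machinery.  Forms: `"flat"` (no parameters), `"harmonic"`
#' (`params = c(a, m)`, U = a/2 (x-m)^2), `"double_well"`
#' (`params = c(center, half_separation, barrier_height)`, a quartic with
#' minima at `center +- half_separation`), `"tabulated"`
#' (`params = list(x, u)` with strictly increasing `x`).
#'
#' @param form One of `"flat"`, `"harmonic"`, `"double_well"`,
#'   `"tabulated"`.
#' @param params Numeric parameters (see above).
#' @param domain Length-2 vector `c(min, max)`.
#' @return An object of class `potential_spec_1d`.
#' @export
potential_spec_1d <- function(form = c("flat", "harmonic", "double_well",
                                       "tabulated"),
                              params = NULL, domain = c(0, 1)) {
  form <- match.arg(form)
  stopifnot(length(domain) == 2, domain[2] > domain[1])
  if (form == "tabulated") {
    stopifnot(is.list(params), all(diff(params$x) > 0))
  }
  spec <- structure(list(form = form, params = params, domain = domain),
                    class = "potential_spec_1d")
  u <- potential_energy_1d(spec, seq(domain[1], domain[2], length.out = 101))
  if (any(!is.finite(u))) stop("potential must be finite on its domain")
  spec
}

#' Evaluate a 1D reference potential
#'
#' @param spec A [potential_spec_1d()].
#' @param x Positions.
#' @return Potential energies at `x`.
#' @export
potential_energy_1d <- function(spec, x) {
  p <- spec$params
  switch(spec$form,
    flat = rep(0, length(x)),
    harmonic = 0.5 * p[1] * (x - p[2])^2,
    double_well = p[3] * ((x - p[1])^2 - p[2]^2)^2 / p[2]^4,
    tabulated = approx(p$x, p$u, xout = x, rule = 2)$y
  )
}

#' Exact i.i.d. sampling from a (biased) 1D Boltzmann density
#'
#' Draws from the normalized density proportional to
#' `exp(-(U(x) + bias(x)) / T)` by inverse-CDF transform on a fine grid.
#'
#' @param spec A [potential_spec_1d()].
#' @param bias Optional [harmonic_bias()] added to the potential.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param temperature Thermal energy.
#' @param grid_n Grid resolution for the inverse CDF.
#' @return Numeric vector of `n` draws.
#' @export
sample_boltzmann_1d <- function(spec, bias = NULL, n, seed = 1,
                                temperature = 1, grid_n = 8192) {
  x <- seq(spec$domain[1], spec$domain[2], length.out = grid_n)
  u <- potential_energy_1d(spec, x)
  if (!is.null(bias)) u <- u + umbrella_energy_force(x, bias)$energy
  w <- exp(-(u - min(u)) / temperature)
  if (!all(is.finite(w)) || sum(w) == 0)
    stop("non-integrable biased density on the domain")
  dx <- diff(x)
  cdf <- c(0, cumsum((w[-1] + w[-grid_n]) / 2 * dx))
  cdf <- cdf / cdf[grid_n]
  keep <- c(TRUE, diff(cdf) > 0) # approx() needs strictly increasing knots
  set.seed(seed)
  approx(cdf[keep], x[keep], xout = runif(n), rule = 2)$y
}

#' Exact binned free energy of a 1D reference potential
#'
#' `F(bin) = -T log( integral over the bin of exp(-U/T) dx )`, computed by
#' composite trapezoidal quadrature on a fine sub-grid; the returned
#' profile is unreferenced (apply [zero_reference()] to pin a zero).
#'
#' @param spec A [potential_spec_1d()].
#' @param bin_edges Strictly increasing bin edges.
#' @param temperature Thermal energy.
#' @param subdiv Quadrature sub-intervals per bin.
#' @return A [pmf_profile()] on the bin centres.
#' @export
exact_free_energy_1d <- function(spec, bin_edges, temperature = 1,
                                 subdiv = 64) {
  stopifnot(all(diff(bin_edges) > 0))
  nb <- length(bin_edges) - 1
  f <- numeric(nb)
  for (b in seq_len(nb)) {
    xs <- seq(bin_edges[b], bin_edges[b + 1], length.out = subdiv + 1)
    u <- potential_energy_1d(spec, xs)
    w <- exp(-(u - min(u)) / temperature)
    z <- sum((w[-1] + w[-length(w)]) / 2) * diff(xs)[1]
    if (z <= 0) stop("bin of zero measure in exact free energy")
    f[b] <- -temperature * log(z) + min(u)
  }
  pmf_profile(centers = (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2,
              free_energy = f, temperature = temperature)
}

# ---------------------------------------------------------------------------
# umbrella dataset generation

#' Generate a set of umbrella-sampling windows
#'
#' One biased window per centre, each carrying its bias parameters and the
#' sampled reaction-coordinate series; per-window seeds are derived
#' deterministically from the master seed.  For a 1D reference system the
#' samples are exact Boltzmann draws; for a toy membrane each window is a
#' restrained Langevin simulation (two bodies, umbrella at the centre,
#' orientational restraints holding `orientations`).
#'
#' @param system A [potential_spec_1d()] or [toy_config()].
#' @param centers Strictly increasing umbrella centres.
#' @param k_umb Umbrella force constant.
#' @param n_samples Reaction-coordinate samples per window.
#' @param seed Master seed.
#' @param ... Passed to methods: toy systems accept `orientations`,
#'   `k_rot`, `epsilon`, `equil_steps`, `store_frames`, `delipidated`.
#' @return List of [umbrella_window()] objects.
#' @export
generate_umbrella_dataset <- function(system, centers, k_umb, n_samples,
                                      seed = 1, ...) {
  if (length(centers) == 0) stop("centers must be non-empty")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  UseMethod("generate_umbrella_dataset")
}

.window_seed <- function(master, i) as.integer((master + 104729 * i) %% 2147483647)

#' @rdname generate_umbrella_dataset
#' @param temperature Thermal energy (1D systems).
#' @export
generate_umbrella_dataset.potential_spec_1d <- function(system, centers,
                                                        k_umb, n_samples,
                                                        seed = 1,
                                                        temperature = 1, ...) {
  lapply(seq_along(centers), function(i) {
    b <- harmonic_bias(centers[i], k_umb)
    s <- .window_seed(seed, i)
    umbrella_window(
      samples = sample_boltzmann_1d(system, b, n_samples, seed = s,
                                    temperature = temperature),
      bias = b, temperature = temperature,
      metadata = list(seed = s, delipidated = FALSE))
  })
}

#' @rdname generate_umbrella_dataset
#' @param orientations Orientation angles (degrees) restrained in each toy
#'   window.
#' @param k_rot,epsilon Orientational restraint constants.
#' @param equil_steps Equilibration steps discarded before sampling.
#' @param store_frames Keep per-frame lipid coordinates in each window's
#'   attached trajectory.
#' @param delipidated Provenance flag marking windows started from a
#'   manually delipidated interface.
#' @export
generate_umbrella_dataset.toy_config <- function(system, centers, k_umb,
                                                 n_samples, seed = 1,
                                                 orientations = c(0, 0),
                                                 k_rot = 60, epsilon = 1e-2,
                                                 equil_steps = 4000L,
                                                 store_frames = FALSE,
                                                 start = "delipidated", ...) {
  stopifnot(system$n_proteins == 2L)
  start <- match.arg(start, c("delipidated", "lipidated"))
  prod_steps <- as.integer(n_samples) * system$sample_stride
  contact <- toy_contact_separation(system, orientations)
  lapply(seq_along(centers), function(i) {
    s <- .window_seed(seed, i)
    rs <- toy_restraint_set(system, d0 = centers[i], k_umb = k_umb,
                            orientations = orientations, k_rot = k_rot,
                            epsilon = epsilon)
    n_gap <- if (start == "lipidated")
      max(0L, floor((centers[i] - contact + 0.3) / system$lipid_diameter))
    else 0L
    traj <- simulate_toy_membrane(system, rs, seed = s,
                                  separation = centers[i],
                                  orientations = orientations,
                                  n_steps = equil_steps + prod_steps,
                                  store_frames = store_frames,
                                  gap_lipids = n_gap)
    keep <- traj$separation$time > equil_steps * system$timestep
    umbrella_window(
      samples = traj$separation$separation[keep],
      bias = harmonic_bias(centers[i], k_umb),
      temperature = system$temperature,
      metadata = list(seed = s, delipidated = (n_gap == 0L),
                      start = start, gap_lipids = n_gap,
                      orientations = orientations,
                      equil_steps = equil_steps),
      trajectory = traj)
  })
}

#' Geometric contact separation of the two toy bodies
#'
#' The centre-of-mass separation at which the two rings touch along the
#' inter-COM line for a given pair of orientation angles: the sum of the
#' two ellipse extents along that line plus one ring-particle diameter.
#'
#' @param config A [toy_config()].
#' @param orientations Orientation angles (degrees), `c(theta_A,
#'   theta_B)`.
#' @return Contact separation (toy length units).
#' @export
toy_contact_separation <- function(config, orientations = c(0, 0)) {
  ab <- config$protein_semi_axes
  ext <- function(theta_deg, ux) {
    phi <- .phi_from_theta(theta_deg)
    # direction (ux, 0) expressed in the body frame
    bx <- ux * cos(phi)
    by <- -ux * sin(phi)
    sqrt((ab[1] * bx)^2 + (ab[2] * by)^2)
  }
  ext(orientations[1], 1) + ext(orientations[2], -1) +
    config$body_particle_diameter
}
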