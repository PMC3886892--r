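#' Harmonic umbrella bias on the inter-protein separation
#'
#' @param center Target separation `d0`.
#' @param force_constant Force constant `k` (energy / length^2), `k >= 0`.
#' @return Object of class `harmonic_bias`.
#' @export
harmonic_bias <- function(center, force_constant) {
  stopifnot(is.finite(center), is.finite(force_constant),
            force_constant >= 0)
  structure(list(center = center, force_constant = force_constant),
            class = "harmonic_bias")
}

#' Umbrella energy and scalar restoring force
#'
#' `E = k/2 (d - d0)^2`, `f = -k (d - d0)` along the inter-COM line.  The
#' caller apportions `f` equally and oppositely to the two centres of
#' mass.
#'
#' @param separation Separation(s) `d >= 0`.
#' @param bias A [harmonic_bias()].
#' @return List with vectors `energy` and `force`.
#' @export
umbrella_energy_force <- function(separation, bias) {
  stopifnot(inherits(bias, "harmonic_bias"), all(separation >= 0))
  d <- separation - bias$center
  list(energy = 0.5 * bias$force_constant * d^2,
       force = -bias$force_constant * d)
}

#' Torque-only orientational restraint
#'
#' A pivot-free enforced-rotation potential acting on a set of particles
#' about the out-of-plane axis through their centre of mass:
#' \deqn{V = \frac{k}{2} \sum_i
#'   \frac{[(\mathbf v \times \mathbf r_i) \cdot \Omega \mathbf r_i^0]^2}
#'        {|\mathbf v \times \mathbf r_i|^2 + \epsilon'}}
#' where \eqn{\mathbf r_i = \mathbf x_i - \mathbf x_c} are positions
#' relative to the current centre of mass, \eqn{\mathbf r_i^0} the
#' reference positions relative to the reference centre of mass,
#' \eqn{\Omega} a rotation matrix (identity to hold a fixed orientation),
#' and \eqn{\epsilon'} a small area-scale regularizer avoiding the
#' singularity on the rotation axis.  Because the potential depends only
#' on COM-relative positions, the restraint forces sum to zero (no net
#' translation is injected) and their resultant is a pure torque along
#' the rotation axis; radial force components vanish to second order in
#' the angular displacement.
#'
#' @param reference Matrix (n x 2, n >= 3) of reference particle
#'   positions (lab frame); must not be collinear.
#' @param force_constant `k_rot >= 0` (energy / length^2).
#' @param epsilon Regularizer `epsilon' > 0` (length^2).
#' @param body Which body the restraint addresses (`"protein_A"` or
#'   `"protein_B"`), used by the toy simulator.
#' @param rotation 2x2 rotation matrix `Omega` (identity by default).
#' @param axis Unit rotation axis; the toy membrane is planar, so this is
#'   the out-of-plane normal.
#' @return Object of class `rotational_restraint`.
#' @export
rotational_restraint <- function(reference, force_constant = 60,
                                 epsilon = 1e-2, body = "protein_A",
                                 rotation = diag(2), axis = c(0, 0, 1)) {
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 2, nrow(reference) >= 3,
            force_constant >= 0, epsilon > 0,
            abs(sum(axis^2) - 1) < 1e-12,
            all(dim(rotation) == c(2, 2)),
            abs(det(rotation) - 1) < 1e-8,
            max(abs(crossprod(rotation) - diag(2))) < 1e-8)
  rel <- sweep(reference, 2, colMeans(reference))
  # collinearity check: second singular value must be non-negligible
  sv <- svd(rel)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate reference: particles are collinear")
  structure(list(reference = reference, force_constant = force_constant,
                 epsilon = epsilon, body = body, rotation = rotation,
                 axis = axis),
            class = "rotational_restraint")
}

#' Set of restraints for a toy run
#'
#' @param bias Optional [harmonic_bias()].
#' @param rotational List of zero, one or two [rotational_restraint()]s,
#'   each addressing a distinct body.
#' @return Object of class `restraint_set`.
#' @export
restraint_set <- function(bias = NULL, rotational = list()) {
  if (!is.null(bias)) stopifnot(inherits(bias, "harmonic_bias"))
  if (inherits(rotational, "rotational_restraint"))
    rotational <- list(rotational)
  stopifnot(length(rotational) <= 2)
  bodies <- vapply(rotational, `[[`, "", "body")
  if (anyDuplicated(bodies))
    stop("each rotational restraint must reference a distinct body")
  structure(list(bias = bias, rotational = rotational),
            class = "restraint_set")
}

#' Build the canonical restraint set for a toy umbrella window
#'
#' Convenience constructor: a harmonic umbrella at `d0` plus rotational
#' restraints holding both bodies at the given orientation angles, with
#' reference particle positions generated from the toy body ring.
#'
#' @param config A [toy_config()].
#' @param d0,k_umb Umbrella centre and force constant (`k_umb = 0` or
#'   `d0 = NULL` omits the bias).
#' @param orientations Target orientation angles (degrees).
#' @param k_rot,epsilon Rotational restraint constants (`k_rot = 0` omits
#'   the rotational restraints).
#' @return A [restraint_set()].
#' @export
toy_restraint_set <- function(config, d0 = NULL, k_umb = 100,
                              orientations = c(0, 0), k_rot = 60,
                              epsilon = 1e-2) {
  bias <- if (!is.null(d0) && k_umb > 0) harmonic_bias(d0, k_umb) else NULL
  rot <- list()
  if (k_rot > 0) {
    ring <- toy_body_ring(config)
    for (p in seq_len(config$n_proteins)) {
      phi <- .phi_from_theta(orientations[p])
      cs <- cos(phi); sn <- sin(phi)
      ref <- cbind(cs * ring[, 1] - sn * ring[, 2],
                   sn * ring[, 1] + cs * ring[, 2])
      rot[[p]] <- rotational_restraint(ref, force_constant = k_rot,
                                       epsilon = epsilon,
                                       body = c("protein_A", "protein_B")[p])
    }
  }
  restraint_set(bias = bias, rotational = rot)
}

#' Energy and per-particle forces of the orientational restraint
#'
#' @param x Matrix (n x 2) of current particle positions; rows must match
#'   the restraint's reference.
#' @param restraint A [rotational_restraint()].
#' @return List with `energy` (scalar, >= 0), `forces` (n x 2), and
#'   `torque` (net torque about the COM, along the out-of-plane axis).
#' @export
rotational_energy_forces <- function(x, restraint) {
  stopifnot(inherits(restraint, "rotational_restraint"))
  x <- as.matrix(x)
  ref <- restraint$reference
  stopifnot(nrow(x) == nrow(ref), ncol(x) == 2)
  k <- restraint$force_constant
  eps <- restraint$epsilon
  n <- nrow(x)

  r <- sweep(x, 2, colMeans(x))                    # current, COM-relative
  r0 <- sweep(ref, 2, colMeans(ref)) %*% t(restraint$rotation)
  a <- r[, 1] * r0[, 2] - r[, 2] * r0[, 1]         # (v x r) . r0
  b <- rowSums(r^2) + eps
  energy <- 0.5 * k * sum(a^2 / b)

  # dV/dr_i, then project out the COM coupling so forces sum to zero
  g <- k * (cbind(a / b * r0[, 2], -a / b * r0[, 1]) - (a^2 / b^2) * r)
  g_mean <- colMeans(g)
  forces <- -(g - matrix(g_mean, n, 2, byrow = TRUE))
  torque <- sum(r[, 1] * forces[, 2] - r[, 2] * forces[, 1])
  list(energy = energy, forces = forces, torque = torque)
}

# 2D Kabsch: least-squares proper rotation angle carrying P onto Q
# (both are centred internally); errors if a reflection fits better.
.kabsch2d <- function(P, Q) {
  P <- sweep(as.matrix(P), 2, colMeans(P))
  Q <- sweep(as.matrix(Q), 2, colMeans(Q))
  H <- crossprod(P, Q)
  if (det(H) < 0)
    stop("improper (reflection) fit: body configurations are mirror images")
  atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
}

.fit_rotation_angle <- function(P, Q) .kabsch2d(P, Q)

#' Per-frame rotational drift of a restrained body
#'
#' For every frame, the best-fit planar rotation angle (least squares over
#' the body particles) carrying the restraint's reference configuration
#' onto the body's current configuration, in degrees.  Bounded drift over
#' a run indicates the orientational restraint is holding.
#'
#' @param traj A `toy_trajectory`.
#' @param restraint A [rotational_restraint()] (its reference defines the
#'   zero of drift).
#' @param body Body index or label.
#' @return Numeric vector of angles (degrees), one per frame.
#' @export
rotational_drift <- function(traj, restraint, body = restraint$body) {
  if (is.character(body)) body <- match(body, c("protein_A", "protein_B"))
  ref_rel <- sweep(restraint$reference, 2, colMeans(restraint$reference))
  vapply(seq_along(traj$time), function(i) {
    .kabsch2d(ref_rel, body_particles(traj, i, body)) * 180 / pi
  }, numeric(1))
}

#' Orientation angles of both bodies in a frame
#'
#' The orientation angle of each protein is measured from the directed
#' line COM(A) -> COM(B) to the arrow COM -> marker particle,
#' counter-clockwise as viewed from the extracellular side, in
#' `[0, 360)` degrees.
#'
#' @param traj A `toy_trajectory` with two bodies.
#' @param frame Frame index.
#' @return Named vector `c(theta_A, theta_B)` in degrees.
#' @export
orientation_angles <- function(traj, frame) {
  stopifnot(traj$config$n_proteins == 2L)
  L <- traj$config$box_side
  d <- traj$com[frame, 2, ] - traj$com[frame, 1, ]
  d <- d - L * round(d / L)
  if (sqrt(sum(d^2)) < 1e-12) stop("coincident centres of mass")
  line_ang <- atan2(d[2], d[1])
  mk <- attr(traj$body_xy, "marker_index")
  th <- vapply(1:2, function(p) {
    m <- body_particles(traj, frame, p)[mk, ] - traj$com[frame, p, ]
    ((atan2(m[2], m[1]) - line_ang) * 180 / pi) %% 360
  }, numeric(1))
  setNames(th, c("theta_A", "theta_B"))
}
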