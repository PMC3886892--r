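test_that("umbrella energy and force follow the closed form", {
  b <- harmonic_bias(3, 2)
  ef <- umbrella_energy_force(3, b)
  expect_equal(ef$energy, 0)
  expect_equal(ef$force, 0)
  ef <- umbrella_energy_force(4, b) # k = 2, d - d0 = 1
  expect_equal(ef$energy, 1)
  expect_equal(ef$force, -2)
  expect_error(harmonic_bias(3, -1))

  # -dE/dd equals the force (central finite difference), random cases
  set.seed(1)
  for (i in 1:20) {
    d0 <- runif(1, 2, 6); k <- runif(1, 1, 500); d <- runif(1, 0.5, 8)
    bb <- harmonic_bias(d0, k)
    h <- 1e-5
    fd <- -(umbrella_energy_force(d + h, bb)$energy -
              umbrella_energy_force(d - h, bb)$energy) / (2 * h)
    f <- umbrella_energy_force(d, bb)$force
    expect_equal(fd, f, tolerance = 1e-6)
  }
})

# a reference ring used by most rotational-restraint tests
rot_fixture <- function(k = 50, eps = 1e-2) {
  ring <- toy_body_ring(toy_config())
  rotational_restraint(sweep(ring, 2, c(4, 6), "+"), force_constant = k,
                       epsilon = eps)
}

rotate2 <- function(x, phi, about = colMeans(x)) {
  rel <- sweep(x, 2, about)
  sweep(rel %*% t(matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)),
        2, about, "+")
}

test_that("rotational restraint is zero at the reference and translation invariant", {
  r <- rot_fixture()
  ef <- rotational_energy_forces(r$reference, r)
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)

  shifted <- sweep(r$reference, 2, c(-2.3, 11.7), "+")
  ef2 <- rotational_energy_forces(rotate2(shifted, 0.3), r)
  ef3 <- rotational_energy_forces(rotate2(r$reference, 0.3), r)
  expect_equal(ef2$energy, ef3$energy, tolerance = 1e-12)
  expect_equal(ef2$forces, ef3$forces, tolerance = 1e-10)
})

test_that("restraint forces are a pure torque: zero net force, axis-aligned torque", {
  r <- rot_fixture()
  for (phi in c(0.05, 0.4, 1.2)) {
    x <- rotate2(r$reference, phi)
    ef <- rotational_energy_forces(x, r)
    expect_lt(max(abs(colSums(ef$forces))), 1e-8) # no injected momentum
    # in-plane force components only -> torque strictly along +-v
    expect_true(is.finite(ef$torque))
    # restoring: torque opposes the displacement
    expect_lt(ef$torque * phi, 0)
  }
})

test_that("restoring torque matches finite differences of the energy", {
  r <- rot_fixture()
  for (phi in c(0.1, 0.6)) {
    x <- rotate2(r$reference, phi)
    h <- 1e-6
    e_p <- rotational_energy_forces(rotate2(r$reference, phi + h), r)$energy
    e_m <- rotational_energy_forces(rotate2(r$reference, phi - h), r)$energy
    tau_fd <- -(e_p - e_m) / (2 * h)
    expect_equal(rotational_energy_forces(x, r)$torque, tau_fd,
                 tolerance = 1e-5)
  }
})

test_that("per-particle forces agree with numerical differentiation", {
  r <- rot_fixture()
  x <- rotate2(r$reference, 0.2)
  x[3, ] <- x[3, ] + c(0.05, -0.08) # break exact rigidity
  ef <- rotational_energy_forces(x, r)
  h <- 1e-5
  for (i in c(1, 3, 11)) {
    for (dim in 1:2) {
      xp <- x; xp[i, dim] <- xp[i, dim] + h
      xm <- x; xm[i, dim] <- xm[i, dim] - h
      fd <- -(rotational_energy_forces(xp, r)$energy -
                rotational_energy_forces(xm, r)$energy) / (2 * h)
      expect_equal(ef$forces[i, dim], fd,
                   tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("radial force components are second order in the rotation angle", {
  r <- rot_fixture(eps = 1e-6)
  rad_frac <- vapply(c(0.2, 0.02), function(phi) {
    x <- rotate2(r$reference, phi)
    ef <- rotational_energy_forces(x, r)
    rel <- sweep(x, 2, colMeans(x))
    rhat <- rel / sqrt(rowSums(rel^2))
    radial <- abs(rowSums(ef$forces * rhat))
    tang <- abs(ef$forces[, 1] * -rhat[, 2] + ef$forces[, 2] * rhat[, 1])
    max(radial) / max(tang)
  }, numeric(1))
  # radial/tangential ratio shrinks linearly with the angle
  expect_lt(rad_frac[2], rad_frac[1] / 5)
  expect_lt(rad_frac[2], 0.03)
})

test_that("degenerate references are rejected", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(rotational_restraint(line), "collinear")
  expect_error(restraint_set(rotational = list(
    rot_fixture(), rot_fixture())), "distinct body")
})

test_that("rotational drift reads back imposed rigid rotations", {
  cfg <- toy_config(n_lipids = 0)
  rs <- toy_restraint_set(cfg, orientations = c(0, 0))
  r <- rs$rotational[[1]]
  phi0 <- memdimer:::.phi_from_theta(0)
  com <- array(rep(c(5, 5, 9, 5), each = 4), dim = c(4, 2, 2))
  ang <- cbind(rep(phi0, 4), rep(phi0, 4))
  traj <- synthetic_traj(com, ang, cfg)
  expect_equal(rotational_drift(traj, r, 1), rep(0, 4), tolerance = 1e-10)

  ang7 <- cbind(rep(phi0 + 7 * pi / 180, 4), rep(phi0, 4))
  traj7 <- synthetic_traj(com, ang7, cfg)
  expect_equal(rotational_drift(traj7, r, 1), rep(7, 4), tolerance = 1e-8)
})

test_that("mirror-image configurations raise an improper-rotation error", {
  ring <- toy_body_ring(toy_config())
  r <- rotational_restraint(ring, force_constant = 10)
  mirrored <- ring
  mirrored[, 1] <- -mirrored[, 1]
  cfg <- toy_config(n_lipids = 0)
  traj <- synthetic_traj(array(5, dim = c(1, 2, 2)),
                         matrix(0, 1, 2), cfg)
  traj$body_xy <- mirrored
  expect_error(rotational_drift(traj, r, 1), "mirror")
})

test_that("orientation angles follow the arrow convention", {
  cfg <- toy_config(n_lipids = 0)
  phiA <- memdimer:::.phi_from_theta(0)
  com <- array(c(4, 8, 5, 5), dim = c(1, 2, 2)) # A at (4,5), B at (8,5)
  # A's marker on the A->B line beyond A's COM -> theta_A = 0
  ang <- matrix(c(phiA, memdimer:::.phi_from_theta(90)), 1, 2)
  traj <- synthetic_traj(com, ang, cfg)
  th <- orientation_angles(traj, 1)
  expect_equal(unname(th["theta_A"]), 0, tolerance = 1e-8)
  expect_equal(unname(th["theta_B"]), 90, tolerance = 1e-8)

  # random geometries agree with a direct atan2 evaluation
  set.seed(7)
  for (i in 1:10) {
    a1 <- runif(1, 0, 2 * pi); a2 <- runif(1, 0, 2 * pi)
    traj$angle <- matrix(c(a1, a2), 1, 2)
    th <- orientation_angles(traj, 1)
    mk <- attr(traj$body_xy, "marker_index")
    for (p in 1:2) {
      m <- body_particles(traj, 1, p)[mk, ] - traj$com[1, p, ]
      want <- ((atan2(m[2], m[1]) - atan2(0, 1)) * 180 / pi) %% 360
      expect_equal(unname(th[p]), want, tolerance = 1e-8)
    }
  }
})

test_that("both restraints together hold a toy window stationary", {
  cfg <- tiny_config(n_lipids = 30)
  rs <- toy_restraint_set(cfg, d0 = 3.2, k_umb = 150, k_rot = 60,
                          orientations = c(0, 0))
  traj <- simulate_toy_membrane(cfg, rs, seed = 12, n_steps = 12000L)
  dr <- rotational_drift(traj, rs$rotational[[1]], 1)
  expect_lt(max(abs(dr)), 12)
  # drift does not grow with time: late-half spread comparable to early
  n <- length(dr)
  expect_lt(max(abs(dr[(n %/% 2):n])), max(abs(dr)) + 1e-9)
  s <- traj$separation$separation
  expect_lt(abs(mean(s) - 3.2), 0.15)
  # stationarity of the reaction coordinate about d0
  first <- mean(s[seq_len(length(s) %/% 2)])
  second <- mean(s[-seq_len(length(s) %/% 2)])
  expect_lt(abs(first - second), 0.15)
})

test_that("umbrella forces act equally and oppositely on the two bodies", {
  # vacuum relaxation at negligible temperature: the COM midpoint is
  # invariant (no net momentum) while the separation relaxes to d0
  cfg <- toy_config(box_side = 12, n_lipids = 0, temperature = 1e-16,
                    frame_stride = 50L)
  rs <- toy_restraint_set(cfg, d0 = 4.0, k_umb = 80, k_rot = 0)
  traj <- simulate_toy_membrane(cfg, rs, seed = 3, separation = 5.0,
                                n_steps = 4000L)
  mid <- (traj$com[, 1, ] + traj$com[, 2, ]) / 2
  expect_lt(max(abs(sweep(mid, 2, mid[1, ]))), 1e-6)
  nf <- length(traj$time)
  final_sep <- sqrt(sum((traj$com[nf, 2, ] - traj$com[nf, 1, ])^2))
  expect_equal(final_sep, 4.0, tolerance = 1e-3)
})
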