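# build a synthetic single-protein trajectory with prescribed lipid
# positions (one frame per row of poses)
lipid_traj <- function(lipids_by_frame, com = c(7.5, 7.5), angle = 0,
                       config = toy_config(n_lipids = ncol(lipids_by_frame) / 2,
                                           n_proteins = 1L)) {
  nf <- nrow(lipids_by_frame)
  nl <- ncol(lipids_by_frame) / 2
  arr <- array(NA_real_, dim = c(nf, nl, 2))
  arr[, , 1] <- lipids_by_frame[, seq(1, 2 * nl, 2), drop = FALSE]
  arr[, , 2] <- lipids_by_frame[, seq(2, 2 * nl, 2), drop = FALSE]
  synthetic_traj(array(rep(com, each = nf), dim = c(nf, 1, 2)),
                 matrix(angle, nf, 1), config, lipid_xy = arr)
}

test_that("align_frames recovers imposed rigid transforms", {
  cfg <- tiny_config()
  traj <- simulate_toy_membrane(cfg, seed = 3, n_steps = 500L)
  a0 <- align_frames(traj, 1, 1)
  # rotate every frame of the aligned trajectory by a known angle about
  # the protein COM; alignment must undo it exactly
  nf <- length(a0$time)
  phis <- seq(0.1, 1.5, length.out = nf)
  twisted <- a0
  ctr <- a0$com[1, 1, ]
  rot <- function(xy, phi, ctr) {
    rel <- sweep(xy, 2, ctr)
    sweep(rel %*% t(matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)),
          2, ctr, "+")
  }
  for (i in seq_len(nf)) {
    twisted$lipid_xy[i, , ] <- rot(a0$lipid_xy[i, , ], phis[i], ctr)
    twisted$angle[i, ] <- a0$angle[i, ] + phis[i]
  }
  fixed <- align_frames(twisted, 1, 1)
  # alignment references the (twisted) first frame, so the recovered
  # rotations are phis[1] - phis and lipids land in that frame's pose
  expect_equal(attr(fixed, "transforms"), phis[1] - phis,
               tolerance = 1e-8, ignore_attr = TRUE)
  got <- fixed$lipid_xy[nf, , ]
  want <- rot(a0$lipid_xy[nf, , ], phis[1], ctr)
  # exact agreement holds inside the minimum-image disc around the
  # protein (beyond it, wrapping and rotation do not commute)
  near <- sqrt(rowSums(sweep(a0$lipid_xy[nf, , ], 2, ctr)^2)) <
    cfg$box_side / 2 - 0.1
  expect_gt(sum(near), 5)
  expect_lt(max(abs(got[near, ] - want[near, ])), 1e-8)

  # alignment can only lower the protein RMSD to the reference
  ref <- body_particles(traj, 1, 1)
  for (i in c(2, 5, 9)) {
    before <- sqrt(mean((body_particles(traj, i, 1) - ref)^2))
    after <- sqrt(mean((body_particles(fixed, i, 1) -
                          body_particles(fixed, 1, 1))^2))
    expect_lte(after, before + 1e-9)
  }
})

test_that("accumulate_density conserves counts and splits channels", {
  # one static lipid at a fixed in-region point over N frames
  nf <- 25
  lip <- matrix(rep(c(8.6, 7.2), each = nf), nf, 2)
  traj <- lipid_traj(lip)
  map <- accumulate_density(traj, side = 6, cell = 0.1)
  expect_equal(sum(map$counts), nf)
  expect_equal(max(map$counts), nf) # a single occupied cell

  # uniform random lipids: cellwise counts Poisson-homogeneous
  set.seed(8)
  nl <- 60
  U <- matrix(runif(2 * nl * 40, 7.5 - 2.4, 7.5 + 2.4), 40, 2 * nl)
  tru <- lipid_traj(U)
  mu <- accumulate_density(tru, side = 4.8, cell = 0.6)
  counts <- as.vector(mu$counts)
  disp <- var(counts) / mean(counts) # index of dispersion ~ 1
  n <- length(counts)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / (n - 1)))

  up <- accumulate_density(tru, side = 4.8, cell = 0.6, channel = "upper")
  lo <- accumulate_density(tru, side = 4.8, cell = 0.6, channel = "lower")
  expect_equal(up$counts + lo$counts, mu$counts)

  expect_error(accumulate_density(synthetic_traj(
    array(0, c(1, 1, 2)), matrix(0, 1, 1))), "empty")
  expect_error(accumulate_density(tru, side = 4.8, cell = 0.7),
               "divide")
})

test_that("radial projection finds a ring at its radius in any direction", {
  # Gaussian ring of radius 1.6 centred on the protein
  n <- 120; side <- 6; cell <- side / n
  ax <- (seq_len(n) - 0.5) * cell - side / 2
  g <- outer(ax, ax, function(x, y) exp(-(sqrt(x^2 + y^2) - 1.6)^2 / 0.02))
  map <- structure(list(counts = g, side = side, cell = cell,
                        center = c(0, 0), n_frames = 1, channel = "both"),
                   class = "density_map")
  for (dir in c(0, 37, 90, 211)) {
    prof <- radial_projection(map, dir, half_window = 10, spacing = 1,
                              line_length = 2.8)
    pk <- detect_peaks(prof, min_prominence = 0.1)
    expect_equal(pk$position[which.max(pk$height)], 1.6, tolerance = cell)
  }
  # equivariance: rotating the map and the direction together
  p0 <- radial_projection(map, 15, 10, 1, 2.8)
  m90 <- map; m90$counts <- t(g)[, n:1] # rotate the grid by +90 degrees
  p90 <- radial_projection(m90, 105, 10, 1, 2.8)
  expect_equal(p90$density, p0$density, tolerance = 1e-6)

  zero <- map; zero$counts <- 0 * g
  expect_true(all(radial_projection(zero, 0, 10, 1, 2.8)$density == 0))
  expect_error(radial_projection(map, 0, 10, 1, 4), "beyond")
})

test_that("mean_profile averages bins and is order-invariant", {
  d <- seq(0.05, 2, by = 0.05)
  mk <- function(v) structure(data.frame(distance = d, density = v),
                              channel = "x",
                              class = c("radial_profile", "data.frame"))
  p1 <- mk(rep(1, length(d))); p3 <- mk(rep(3, length(d)))
  expect_true(all(mean_profile(list(p1, p3))$density == 2))
  expect_identical(mean_profile(list(p1, p1))$density, p1$density)
  expect_identical(mean_profile(list(p3, p1))$density,
                   mean_profile(list(p1, p3))$density)
  bad <- mk(rep(1, length(d))); bad$distance <- bad$distance + 0.01
  expect_error(mean_profile(list(p1, bad)), "mismatched")
})

test_that("detect_peaks resolves bumps and respects its filters", {
  d <- seq(0.02, 3.5, by = 0.02)
  mk <- function(v) structure(data.frame(distance = d, density = v),
                              class = c("radial_profile", "data.frame"))
  one <- mk(exp(-(d - 1.62)^2 / 0.02))
  pk <- detect_peaks(one, min_prominence = 0.1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 1.62, tolerance = 0.011)

  # three bumps 0.39 apart survive a 0.2 minimum separation
  three <- mk(exp(-(d - 1.62)^2 / 0.005) + 0.8 * exp(-(d - 2.01)^2 / 0.005) +
                0.6 * exp(-(d - 2.40)^2 / 0.005))
  pk3 <- detect_peaks(three, min_prominence = 0.05, min_separation = 0.2)
  expect_equal(pk3$position, c(1.62, 2.01, 2.40), tolerance = 0.02)

  expect_equal(nrow(detect_peaks(mk(rep(1, length(d))))), 0)
})

test_that("predict_separations implements the overlay pairings", {
  pk <- data.frame(position = c(1, 2, 3))
  expect_equal(predict_separations(pk, 1)$separation, 2)
  expect_equal(predict_separations(pk, 2)$separation, 3)
  expect_equal(predict_separations(pk, 3)$separation, 4)
  expect_error(predict_separations(pk, 4), "3 intervening")
  expect_error(predict_separations(data.frame(position = 1), 2),
               "at least 2 peaks")

  # non-equally-spaced peaks: the n = 3 estimate lies between the two
  # pairwise solutions and minimizes the overlay misalignment
  r <- c(1.5, 2.1, 3.0)
  s3 <- predict_separations(data.frame(position = r), 3)$separation
  expect_gte(s3, min(r[1] + r[3], 2 * r[2]))
  expect_lte(s3, max(r[1] + r[3], 2 * r[2]))
  expect_equal(s3, overlay_oracle(r, 3), tolerance = 1e-3)
})

test_that("intervening-lipid counting sees the single-file channel", {
  cfg <- toy_config(n_lipids = 2, n_proteins = 2L)
  com <- array(c(6, 9.4, 7.5, 7.5), dim = c(1, 2, 2)) # separation 3.4
  ang <- matrix(memdimer:::.phi_from_theta(c(0, 0)), 1, 2)
  # one lipid dead centre between the walls, one far away
  lip <- array(c(7.7, 2.0, 7.5, 2.0), dim = c(1, 2, 2))
  traj <- synthetic_traj(com, ang, cfg, lipid_xy = lip)
  expect_equal(count_intervening_lipids(traj), 1)
})
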