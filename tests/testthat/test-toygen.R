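test_that("toy_config validates its invariants", {
  expect_s3_class(toy_config(), "toy_config")
  expect_error(toy_config(protein_semi_axes = c(1, 1.5)), "wide >= narrow")
  expect_error(toy_config(box_side = 4), "box_side too small")
  expect_error(toy_config(temperature = 0), "temperature")
  expect_error(toy_config(n_proteins = 3), "n_proteins")
})

test_that("equal seeds give bit-identical trajectories", {
  cfg <- tiny_config()
  rs <- toy_restraint_set(cfg, d0 = 3.0, k_umb = 100)
  t1 <- simulate_toy_membrane(cfg, rs, seed = 9, n_steps = 600L)
  t2 <- simulate_toy_membrane(cfg, rs, seed = 9, n_steps = 600L)
  expect_identical(t1$lipid_xy, t2$lipid_xy)
  expect_identical(t1$com, t2$com)
  expect_identical(t1$separation, t2$separation)
  t3 <- simulate_toy_membrane(cfg, rs, seed = 10, n_steps = 600L)
  expect_false(identical(t1$lipid_xy, t3$lipid_xy))
})

test_that("zero-temperature, zero-force system is stationary", {
  cfg <- toy_config(box_side = 10, n_lipids = 0, temperature = 1e-14,
                    n_proteins = 1L, frame_stride = 20L)
  traj <- simulate_toy_membrane(cfg, seed = 1, n_steps = 400L)
  drift <- max(abs(sweep(traj$com[, 1, ], 2, traj$com[1, 1, ])))
  expect_lt(drift, 1e-6)
  expect_lt(max(abs(traj$angle - traj$angle[1, 1])), 1e-6)
})

test_that("free diffusion satisfies the Einstein relation", {
  # one lipid in a large box: MSD ~ 4 (T / friction) t.  Time-averaged
  # MSD slopes are noisy at long lags, so keep lags short and average
  # over replicate runs.
  cfg <- toy_config(box_side = 13, n_lipids = 1, n_proteins = 1L,
                    frame_stride = 10L, temperature = 1.4, friction = 2)
  dt_frame <- cfg$timestep * 10
  lags <- seq(5, 80, by = 5)
  slope_one <- function(seed) {
    traj <- simulate_toy_membrane(cfg, seed = seed, n_steps = 60000L)
    xy <- traj$lipid_xy[, 1, ]
    d <- apply(xy, 2, diff)
    d <- d - cfg$box_side * round(d / cfg$box_side) # unwrap
    xy_un <- apply(rbind(0, d), 2, cumsum)
    msd <- vapply(lags, function(L) {
      dx <- xy_un[-seq_len(L), ] - xy_un[seq_len(nrow(xy_un) - L), ]
      mean(rowSums(dx^2))
    }, numeric(1))
    unname(coef(lm(msd ~ 0 + I(lags * dt_frame)))[1])
  }
  slope <- mean(vapply(c(21, 22, 23), slope_one, numeric(1)))
  expect_equal(slope, 4 * cfg$temperature / cfg$friction, tolerance = 0.1)
})

test_that("a stiff umbrella holds the mean separation at its centre", {
  cfg <- toy_config(box_side = 12, n_lipids = 0, sample_stride = 5L)
  rs <- toy_restraint_set(cfg, d0 = 4.0, k_umb = 200)
  traj <- simulate_toy_membrane(cfg, rs, seed = 4, n_steps = 20000L)
  s <- traj$separation$separation
  expect_lt(abs(mean(s) - 4.0), 0.05)
  expect_lt(sd(s), 3 * sqrt(cfg$temperature / 200))
})

test_that("bodies are exactly rigid and lipid identities conserved", {
  cfg <- tiny_config()
  traj <- simulate_toy_membrane(cfg, seed = 2, n_steps = 500L)
  d1 <- dist(body_particles(traj, 1, 1))
  for (i in c(3, 7, 10))
    expect_lt(max(abs(dist(body_particles(traj, i, 1)) - d1)), 1e-9)
  f1 <- as_frame(traj, 1)
  f2 <- as_frame(traj, length(traj$time))
  expect_identical(f1$lipid_id, f2$lipid_id)
  expect_identical(f1$leaflet, f2$leaflet)
  expect_equal(sum(f1$body_label == "lipid"), cfg$n_lipids)
})

test_that("impossible lipid placement raises a placement error", {
  expect_error(
    simulate_toy_membrane(toy_config(box_side = 8.2, n_lipids = 120),
                          seed = 1, n_steps = 10L),
    "placement error")
})

test_that("sample_boltzmann_1d draws from the right densities", {
  flat <- potential_spec_1d("flat", domain = c(1, 3))
  x <- sample_boltzmann_1d(flat, NULL, n = 10000, seed = 3)
  ks <- suppressWarnings(ks.test(x, "punif", 1, 3))
  expect_gt(ks$p.value, 0.01)

  # harmonic: mean m, variance T/a within 3 sigma
  a <- 6; m <- 5
  spec <- harmonic_spec(a, m, domain = c(2, 8))
  y <- sample_boltzmann_1d(spec, NULL, n = 20000, seed = 4, temperature = 1)
  se_mean <- sqrt(1 / a) / sqrt(length(y))
  expect_lt(abs(mean(y) - m), 3 * se_mean)
  expect_lt(abs(var(y) - 1 / a), 3 * sqrt(2 / length(y)) * (1 / a))

  # flat potential + harmonic bias: Gaussian centred at the bias
  b <- harmonic_bias(2.2, 10)
  z <- sample_boltzmann_1d(flat, b, n = 20000, seed = 5)
  expect_lt(abs(mean(z) - 2.2), 3 * sqrt(1 / 10) / sqrt(length(z)))
})

test_that("exact_free_energy_1d matches closed forms", {
  flat <- potential_spec_1d("flat", domain = c(0, 2))
  pmf <- zero_reference(exact_free_energy_1d(flat, seq(0, 2, 0.1)), 1.05)
  expect_lt(max(abs(pmf$free_energy)), 1e-12)

  spec <- harmonic_spec(a = 5, m = 5, domain = c(3, 7))
  edges <- seq(3, 7, by = 0.01)
  pmf <- exact_free_energy_1d(spec, edges)
  u <- potential_energy_1d(spec, pmf$center)
  dev <- (pmf$free_energy - pmf$free_energy[1]) - (u - u[1])
  expect_lt(max(abs(dev)), 1e-3)

  dw <- double_well_spec()
  pmfd <- exact_free_energy_1d(dw, seq(2, 6.5, by = 0.05))
  idx <- brute_minima(pmfd$free_energy)
  expect_equal(sort(pmfd$center[idx]), c(3.025, 5.025), tolerance = 0.03)
})

test_that("generate_umbrella_dataset covers the grid deterministically", {
  # the canonical production grid: 2.8 to 8.0 nm at 0.1 nm spacing
  centers <- seq(2.8, 8.0, by = 0.1)
  expect_length(centers, 53)
  flat <- potential_spec_1d("flat", domain = c(2, 9))
  ws <- generate_umbrella_dataset(flat, centers, k_umb = 50,
                                  n_samples = 400, seed = 6)
  expect_length(ws, 53)
  for (w in ws[c(1, 27, 53)]) {
    se <- sqrt(1 / 50) / sqrt(400)
    expect_lt(abs(mean(w$samples) - w$bias$center), 4 * se)
  }
  ws2 <- generate_umbrella_dataset(flat, centers, k_umb = 50,
                                   n_samples = 400, seed = 6)
  expect_identical(lapply(ws, `[[`, "samples"), lapply(ws2, `[[`, "samples"))
  expect_error(generate_umbrella_dataset(flat, numeric(0), 50, 10), "non-empty")
  expect_error(generate_umbrella_dataset(flat, c(3, 3), 50, 10),
               "strictly increasing")
})

test_that("lipid shells form around a single protein", {
  cfg <- toy_config(n_proteins = 1L, n_lipids = 248, frame_stride = 100L)
  traj <- simulate_toy_membrane(cfg, seed = 31, n_steps = 40000L)
  atraj <- align_frames(traj, 1, 1)
  map <- accumulate_density(atraj, side = 8, cell = 8 / 80)
  direction <- (atraj$angle[1, 1] + pi / 2) * 180 / pi # wide-face normal
  prof <- radial_projection(map, direction, half_window = 20, spacing = 2,
                            line_length = 3.8)
  pk <- detect_peaks(prof, min_prominence = 0.05 * max(prof$density),
                     min_separation = 0.4)
  expect_gte(nrow(pk), 2)
  gaps <- diff(pk$position)
  expect_true(any(abs(gaps - cfg$lipid_diameter) < 0.35))
})
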