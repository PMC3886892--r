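mk_window <- function(samples, center, k = 10, temperature = 1)
  umbrella_window(samples, harmonic_bias(center, k), temperature)

test_that("build_histograms counts and conserves samples", {
  w <- mk_window(c(3.0, 3.0, 3.1), 3)
  h <- build_histograms(list(w), 0.1)
  occ <- h$counts[1, h$counts[1, ] > 0]
  expect_equal(sort(occ), c(1, 2))
  expect_equal(sum(h$counts[1, ]), 3)

  w2 <- mk_window(rep(2.5, 20), 2.5)
  h2 <- build_histograms(list(w2), 0.1)
  expect_equal(sum(h2$counts[1, ] > 0), 1)

  set.seed(3)
  ws <- lapply(1:4, function(i) mk_window(rnorm(200, i, 0.3), i))
  h3 <- build_histograms(ws, 0.05)
  expect_equal(rowSums(h3$counts) + h3$out_of_range, h3$totals)
  expect_true(all(diff(h3$edges) > 0))

  # explicit range: out-of-range samples are counted, never lost
  h4 <- build_histograms(ws, 0.05, range = c(1.5, 3.5))
  expect_equal(rowSums(h4$counts) + h4$out_of_range, h4$totals)
  expect_gt(sum(h4$out_of_range), 0)
})

test_that("overlap diagnostics report the intersection fraction", {
  a <- mk_window(rep(c(1.02, 1.08), 50), 1)
  h <- build_histograms(list(a, a), 0.1)
  ov <- overlap_diagnostics(h)
  expect_equal(ov$overlap, 1.0)

  b <- mk_window(rep(5.05, 100), 5)
  h2 <- build_histograms(list(a, b), 0.1)
  expect_equal(overlap_diagnostics(h2)$overlap, 0.0)

  # hand-countable: two unit-mass histograms sharing exactly half
  c1 <- mk_window(c(rep(1.05, 50), rep(1.15, 50)), 1)
  c2 <- mk_window(c(rep(1.15, 50), rep(1.25, 50)), 1.1)
  h3 <- build_histograms(list(c1, c2), 0.1)
  expect_equal(overlap_diagnostics(h3)$overlap, 0.5)
  expect_true(overlap_diagnostics(h3, threshold = 0.6)$flagged)
})

test_that("an unbiased window on a flat potential gives a flat PMF", {
  flat <- potential_spec_1d("flat", domain = c(0, 2))
  w <- umbrella_window(sample_boltzmann_1d(flat, NULL, 20000, seed = 8),
                       harmonic_bias(1, 0))
  h <- build_histograms(list(w), 0.1, range = c(0, 2))
  pmf <- solve_wham(h)
  # counts should be uniform: chi-squared goodness of fit
  counts <- h$counts[1, ]
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  expect_lt(diff(range(pmf$free_energy)), 0.2)
})

test_that("WHAM recovers a harmonic free energy from 11 windows", {
  spec <- harmonic_spec(a = 4, m = 5, domain = c(2, 8))
  ws <- generate_umbrella_dataset(spec, seq(3, 7, length.out = 11),
                                  k_umb = 20, n_samples = 5000, seed = 2)
  h <- build_histograms(ws, 0.05)
  pmf <- zero_reference(solve_wham(h), 5)
  exact <- zero_reference(exact_free_energy_1d(spec, h$edges), 5)
  good <- colSums(h$counts) >= 100
  dev <- pmf$free_energy[good] - exact$free_energy[good]
  expect_lt(sqrt(mean(dev^2)), 0.1)
})

test_that("WHAM is deterministic and window-order invariant", {
  spec <- harmonic_spec(a = 4, m = 5, domain = c(2, 8))
  ws <- generate_umbrella_dataset(spec, seq(3.5, 6.5, 0.5), k_umb = 15,
                                  n_samples = 2000, seed = 9)
  h1 <- build_histograms(ws, 0.05)
  p1 <- solve_wham(h1)
  p2 <- solve_wham(h1)
  expect_identical(p1$free_energy, p2$free_energy)
  h3 <- build_histograms(rev(ws), 0.05)
  p3 <- solve_wham(h3)
  expect_equal(p3$free_energy, p1$free_energy, tolerance = 1e-6)
})

test_that("disconnected window support is an error naming the gap", {
  w1 <- mk_window(rnorm(500, 1, 0.05), 1, k = 100)
  w2 <- mk_window(rnorm(500, 5, 0.05), 5, k = 100)
  h <- build_histograms(list(w1, w2), 0.05)
  expect_error(solve_wham(h), "disconnected")
})

test_that("doubling all umbrella force constants leaves the PMF unchanged", {
  spec <- double_well_spec()
  centers <- seq(2.5, 6, 0.25)
  ws1 <- generate_umbrella_dataset(spec, centers, 30, 4000, seed = 3)
  ws2 <- generate_umbrella_dataset(spec, centers, 60, 4000, seed = 4)
  p1 <- zero_reference(solve_wham(build_histograms(ws1, 0.05,
                                                   range = c(2.5, 6))), 4)
  p2 <- zero_reference(solve_wham(build_histograms(ws2, 0.05,
                                                   range = c(2.5, 6))), 4)
  dev <- p1$free_energy - p2$free_energy
  dev <- dev[is.finite(dev)]
  expect_lt(sqrt(mean(dev^2)), 0.1)
})

test_that("free energies scale linearly with temperature", {
  # same sampled densities, bias energies scaled with T
  spec <- harmonic_spec(a = 4, m = 5, domain = c(2, 8))
  ws <- generate_umbrella_dataset(spec, seq(3.5, 6.5, 0.5), k_umb = 15,
                                  n_samples = 3000, seed = 5)
  ws2x <- lapply(ws, function(w)
    umbrella_window(w$samples,
                    harmonic_bias(w$bias$center, 2 * w$bias$force_constant),
                    temperature = 2))
  p1 <- zero_reference(solve_wham(build_histograms(ws, 0.05)), 5)
  p2 <- zero_reference(solve_wham(build_histograms(ws2x, 0.05)), 5)
  expect_equal(p2$free_energy, 2 * p1$free_energy, tolerance = 1e-6)
})

test_that("WHAM error shrinks as sampling grows (oracle equivalence)", {
  spec <- double_well_spec()
  centers <- seq(2.5, 6, 0.25)
  rms_at <- function(n, seed) {
    ws <- generate_umbrella_dataset(spec, centers, 40, n, seed = seed)
    h <- build_histograms(ws, 0.05, range = c(2.5, 6))
    pmf <- zero_reference(solve_wham(h), 4)
    exact <- zero_reference(exact_free_energy_1d(spec, h$edges), 4)
    good <- is.finite(pmf$free_energy) & colSums(h$counts) >= 20
    sqrt(mean((pmf$free_energy[good] - exact$free_energy[good])^2))
  }
  expect_lt(rms_at(20000, 7), rms_at(500, 7))
})

test_that("zero referencing pins the reference bin and is idempotent", {
  pmf <- pmf_profile(seq(1, 3, 0.1), sin(seq(1, 3, 0.1)))
  z1 <- zero_reference(pmf, 2.0)
  i <- which.min(abs(z1$center - 2.0))
  expect_identical(z1$free_energy[i], 0)
  z2 <- zero_reference(z1, 2.0)
  expect_identical(z1$free_energy, z2$free_energy)
  expect_equal(attr(z2, "reference_separation"), 2.0)

  const <- pmf_profile(1:10, rep(3.3, 10))
  expect_true(all(zero_reference(const, 5)$free_energy == 0))
  expect_error(zero_reference(pmf, 9), "outside")
})

test_that("split-half convergence is zero for duplicated samples", {
  spec <- harmonic_spec(a = 6, m = 5, domain = c(3, 7))
  ws <- generate_umbrella_dataset(spec, seq(4, 6, 0.25), 20, 800, seed = 11)
  dup <- lapply(ws, function(w)
    umbrella_window(rep(w$samples, 2), w$bias, w$temperature))
  res <- split_half_convergence(dup, 0.05, reference = 5)
  expect_equal(res$max_discrepancy, 0, tolerance = 1e-9)

  # the split is contiguous in time, not shuffled: reordering changes it
  shuf <- lapply(dup, function(w) {
    set.seed(1)
    umbrella_window(sample(w$samples), w$bias, w$temperature)
  })
  res2 <- split_half_convergence(shuf, 0.05, reference = 5)
  expect_false(isTRUE(all.equal(res2$max_discrepancy, 0)))

  short <- c(ws[-1], list(umbrella_window(3.3, ws[[1]]$bias)))
  expect_error(split_half_convergence(short, 0.05), "too short")
})
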