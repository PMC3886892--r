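# Shared fixtures, all built in code.

# a small, fast toy system for dynamics tests
tiny_config <- function(n_lipids = 40, ...) {
  toy_config(box_side = 10, n_lipids = n_lipids, n_steps = 2000L,
             frame_stride = 50L, seed = 42L, ...)
}

# harmonic 1D reference: U = a/2 (x - m)^2
harmonic_spec <- function(a = 8, m = 5, domain = c(2, 8)) {
  potential_spec_1d("harmonic", params = c(a, m), domain = domain)
}

# the double-well 1D fixture used for WHAM oracle checks:
# minima at 4 +- 1, barrier 3 T
double_well_spec <- function() {
  potential_spec_1d("double_well", params = c(4, 1, 3), domain = c(2, 6.5))
}

# synthetic rigid-body "trajectory" object with prescribed poses, for
# geometry-only tests (no dynamics involved)
synthetic_traj <- function(com, angle, config = toy_config(n_lipids = 0),
                           lipid_xy = NULL, time = seq_len(nrow(angle))) {
  structure(list(
    time = time, lipid_xy = lipid_xy, com = com, angle = angle,
    separation = NULL,
    leaflet = if (is.null(lipid_xy)) character(0) else
      rep_len(c("upper", "lower"), dim(lipid_xy)[2]),
    body_xy = toy_body_ring(config), config = config, seed = 0L,
    restraints = list(k_umb = 0, d0 = NA, k_rot = 0, epsilon = 1e-2,
                      theta_ref_deg = c(0, 0))
  ), class = "toy_trajectory")
}

# brute-force scan oracle for discrete local minima (no prominence)
brute_minima <- function(f) {
  which(vapply(seq_along(f), function(i) {
    i > 1 && i < length(f) && is.finite(f[i - 1]) && is.finite(f[i + 1]) &&
      f[i] < f[i - 1] && f[i] < f[i + 1]
  }, logical(1)))
}

# exhaustive shift-search oracle for the peak-overlay prediction: find s
# minimizing the summed squared misalignment of the prescribed pairs
overlay_oracle <- function(r, n, s_grid = seq(0.5, 10, by = 1e-4)) {
  pairs <- switch(n, rbind(c(1, 1)), rbind(c(1, 2)), rbind(c(1, 3), c(2, 2)))
  cost <- vapply(s_grid, function(s)
    sum((r[pairs[, 1]] - (s - r[pairs[, 2]]))^2), numeric(1))
  s_grid[which.min(cost)]
}
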