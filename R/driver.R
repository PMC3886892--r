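#' The four canonical orientational configurations
#'
#' Orientation-angle presets, `0` degrees meaning the wide face points at
#' the partner: two maximal-contact configurations with both wide faces
#' in contact (parallel and anti-parallel marker arrows — degenerate by
#' construction for the mirror-symmetric toy ellipse), one intermediate
#' wide-narrow configuration, and the minimal-contact narrow-narrow
#' configuration.
#'
#' @return Named list of `c(theta_A, theta_B)` pairs (degrees).
#' @export
canonical_orientations <- function() {
  list(wide_wide_parallel = c(0, 0),
       wide_wide_antiparallel = c(0, 180),
       wide_narrow = c(0, 90),
       narrow_narrow = c(90, 90))
}

#' Plan a full dimerization free-energy experiment
#'
#' Bundles every parameter of the canonical end-to-end recipe: the
#' orientational configurations, the coarse and fine umbrella-window
#' grids with their force constants, restraint constants, the toy
#' configuration, analysis parameters, and the master seed.
#'
#' @param orientations Named list of `c(theta_A, theta_B)` presets.
#' @param config Toy membrane configuration for the two-body windows.
#' @param coarse_centers,k_coarse,n_coarse Coarse window grid, umbrella
#'   force constant and samples per window.
#' @param fine_centers,k_fine,n_fine Fine (stiffer) window grid around
#'   the contact region; these windows keep their frames and feed the
#'   surface-area analysis.
#' @param equil_steps Equilibration steps discarded per window.
#' @param k_rot,epsilon Orientational restraint constants.
#' @param bin_width,reference WHAM bin width and the separation at which
#'   PMFs are pinned to zero.
#' @param prominence Minimum prominence for reported PMF minima.
#' @param barrier_range Separation range searched for the outer barrier.
#' @param probe SASA probe radius (the lipid-sized probe).
#' @param sasa_half_range Half-range of the straight-line fit giving the
#'   buried area at the minimum.
#' @param single_n_steps,single_n_lipids Length and lipid count of the
#'   single-protein run feeding the annulus-density prediction
#'   (`single_n_lipids` keeps the lipid packing fraction of the two-body
#'   system once the second body's area is freed).
#' @param peak_min_separation Minimum spacing between annulus peaks.
#' @param seed Master seed.
#' @return Object of class `experiment_plan`.
#' @export
experiment_plan <- function(orientations = canonical_orientations(),
                            config = toy_config(),
                            coarse_centers = seq(4.6, 6.1, by = 0.15),
                            k_coarse = 100, n_coarse = 6000,
                            fine_centers = seq(2.4, 4.6, by = 0.05),
                            k_fine = 400, n_fine = 1400,
                            equil_steps = 5000L, k_rot = 60,
                            epsilon = 1e-2, bin_width = 0.02,
                            reference = 6.1, prominence = 0.06,
                            barrier_range = c(4.6, 5.9), probe = 0.4,
                            sasa_half_range = 0.3,
                            single_n_steps = 216000L,
                            single_n_lipids = 245L,
                            peak_min_separation = 0.4,
                            peak_min_prominence_frac = 0.05, seed = 1L) {
  stopifnot(length(coarse_centers) > 0, all(diff(coarse_centers) > 0))
  if (length(fine_centers))
    stopifnot(all(diff(fine_centers) > 0))
  stopifnot(length(orientations) >= 1, inherits(config, "toy_config"))
  structure(list(
    orientations = orientations, config = config,
    coarse_centers = coarse_centers, k_coarse = k_coarse,
    n_coarse = n_coarse, fine_centers = fine_centers, k_fine = k_fine,
    n_fine = n_fine, equil_steps = as.integer(equil_steps),
    k_rot = k_rot, epsilon = epsilon, bin_width = bin_width,
    reference = reference, prominence = prominence,
    barrier_range = barrier_range, probe = probe,
    sasa_half_range = sasa_half_range,
    single_n_steps = as.integer(single_n_steps),
    single_n_lipids = as.integer(single_n_lipids),
    peak_min_separation = peak_min_separation,
    peak_min_prominence_frac = peak_min_prominence_frac,
    seed = as.integer(seed)
  ), class = "experiment_plan")
}

# per-configuration deterministic seed
.config_seed <- function(master, i) as.integer((master + 7919 * i) %% 2147483647)

#' Umbrella windows, PMF and landscape anatomy for one configuration
#'
#' Generates the coarse and fine toy umbrella windows for one
#' orientational configuration, pools them into one WHAM input set,
#' zero-references the PMF, and extracts minima (classified by the mean
#' number of intervening lipids in the nearest frame-stored window),
#' barrier, and the buried-area profile of the stiffer windows.
#'
#' @param plan An [experiment_plan()].
#' @param name Name of the configuration in `plan$orientations`.
#' @param index Its index (drives the derived seed).
#' @param keep_windows Keep the window list (with trajectories) in the
#'   result.
#' @return List with `pmf`, `overlap`, `minima`, `minima_table`,
#'   `barrier`, `depth`, `sasa_profile`, `area_at_min`, `wham_meta`.
#' @export
run_configuration <- function(plan, name, index = match(name, names(plan$orientations)),
                              keep_windows = FALSE) {
  ori <- plan$orientations[[name]]
  seed_c <- .config_seed(plan$seed, index)
  # windows far below the bodies' geometric contact separation cannot be
  # sampled (the rings would interlock); start each grid just below
  # contact for this orientation, like starting the separation scan at
  # the edge of the repulsive wall
  contact <- toy_contact_separation(plan$config, ori)
  keep_c <- plan$coarse_centers >= contact - 0.3
  keep_f <- plan$fine_centers >= contact - 0.3
  coarse <- generate_umbrella_dataset(
    plan$config, plan$coarse_centers[keep_c], plan$k_coarse, plan$n_coarse,
    seed = seed_c, orientations = ori, k_rot = plan$k_rot,
    epsilon = plan$epsilon, equil_steps = plan$equil_steps)
  # lipid exchange between the walls is slow at close range, so every
  # fine centre is sampled from both branches of the hysteresis: a
  # delipidated start and a lipidated (gap-filled) start, pooled
  fine <- list()
  if (any(keep_f)) {
    half <- ceiling(plan$n_fine / 2)
    fine_d <- generate_umbrella_dataset(
      plan$config, plan$fine_centers[keep_f], plan$k_fine, half,
      seed = seed_c + 1L, orientations = ori, k_rot = plan$k_rot,
      epsilon = plan$epsilon, equil_steps = plan$equil_steps,
      store_frames = TRUE, start = "delipidated")
    fine_l <- generate_umbrella_dataset(
      plan$config, plan$fine_centers[keep_f], plan$k_fine, half,
      seed = seed_c + 2L, orientations = ori, k_rot = plan$k_rot,
      epsilon = plan$epsilon, equil_steps = plan$equil_steps,
      store_frames = TRUE, start = "lipidated")
    fine <- c(fine_d, fine_l)
  }
  windows <- c(coarse, fine)
  ctr <- vapply(windows, function(w) w$bias$center, numeric(1))
  h <- build_histograms(windows, plan$bin_width, range = range(ctr))
  pmf <- zero_reference(solve_wham(h), plan$reference)
  minima <- fit_minima(pmf, plan$prominence)

  # classify minima by intervening-lipid count of the nearest stored window
  n_int <- rep(NA_real_, length(minima))
  if (length(fine)) {
    fctr <- vapply(fine, function(w) w$bias$center, numeric(1))
    for (j in seq_along(minima)) {
      near <- which(abs(fctr - minima[[j]]$location) <
                      abs(fctr[which.min(abs(fctr - minima[[j]]$location))] -
                            minima[[j]]$location) + 1e-9)
      if (length(near) &&
          abs(fctr[near[1]] - minima[[j]]$location) < 0.15)
        n_int[j] <- mean(vapply(near, function(k)
          mean(count_intervening_lipids(
            fine[[k]]$trajectory,
            half_width = 0.75 * plan$config$lipid_diameter)),
          numeric(1)))
    }
  }
  minima_table <- if (length(minima)) data.frame(
    location = vapply(minima, `[[`, numeric(1), "location"),
    depth = vapply(minima, `[[`, numeric(1), "depth"),
    curvature = vapply(minima, `[[`, numeric(1), "curvature"),
    classification = vapply(minima, `[[`, "", "classification"),
    mean_intervening = n_int) else NULL

  # the restrained global minimum is the potential well of the contact
  # region (the region the stiff windows sample); ripples in the
  # long-range tail are never promoted to "the well"
  gmin <- NA_real_
  depth <- NA_real_
  if (length(minima)) {
    in_contact <- minima_table$location <= max(plan$fine_centers) + 0.2
    if (any(in_contact)) {
      j <- which(in_contact)[which.min(minima_table$depth[in_contact])]
      gmin <- minima_table$location[j]
      depth <- minima_table$depth[j]
    }
  }
  # the buried-area abscissa is anchored at the delipidated contact
  # minimum (intervening-lipid count ~ 0) when one exists: its location
  # is set by geometry and is robust to free-energy offsets.  If no
  # delipidated minimum was resolved, fall back to the deepest minimum
  # within half a lipid diameter of geometric contact, then to the
  # deepest contact-region minimum.
  gmin_contact <- gmin
  if (length(minima)) {
    at_contact <- which(!is.na(n_int) & round(n_int) == 0)
    if (!length(at_contact))
      at_contact <- which(minima_table$location <=
                            contact + 0.75 * plan$config$lipid_diameter)
    if (length(at_contact))
      gmin_contact <- minima_table$location[at_contact[
        which.min(minima_table$depth[at_contact])]]
  }

  sasa_profile <- NULL
  area_min <- NA_real_
  if (length(fine) && is.finite(gmin_contact)) {
    sasa_profile <- buried_area_profile(fine, gmin_contact,
                                        probe = plan$probe,
                                        frame_stride = 5L)
    area_min <- tryCatch(
      as.numeric(area_at_minimum(sasa_profile, plan$sasa_half_range)),
      error = function(e) NA_real_)
  }
  list(name = name, orientations = ori, seed = seed_c, pmf = pmf,
       overlap = overlap_diagnostics(h), minima = minima,
       minima_table = minima_table,
       barrier = find_barrier(pmf, plan$barrier_range), depth = depth,
       global_minimum = gmin, contact_minimum = gmin_contact,
       sasa_profile = sasa_profile,
       area_at_min = area_min,
       windows = if (keep_windows) windows else NULL)
}

#' Annulus density profile and separation predictions from one protein
#'
#' Runs the long single-protein simulation, aligns every frame on the
#' protein's reference pose, accumulates the 2D lipid density, projects
#' it along the wide-face (marker) direction, detects the shell peaks
#' and predicts the packed separations for 1-3 intervening lipids.
#'
#' @param plan An [experiment_plan()].
#' @return List with `profile`, `peaks`, `predictions` (data frame
#'   `n_intervening`, `separation`), and the `map`.
#' @export
run_single_protein_analysis <- function(plan) {
  cfg1 <- plan$config
  cfg1$n_proteins <- 1L
  cfg1$n_lipids <- plan$single_n_lipids
  cfg1$frame_stride <- 100L
  traj <- simulate_toy_membrane(cfg1, seed = .config_seed(plan$seed, 0L),
                                orientations = c(0, 0),
                                n_steps = plan$single_n_steps)
  atraj <- align_frames(traj, 1, 1)
  map <- accumulate_density(atraj, side = 8, cell = 8 / 120)
  direction <- (atraj$angle[1, 1] + pi / 2) * 180 / pi # wide-face normal
  profs <- lapply(c("upper", "lower"), function(ch) {
    m <- accumulate_density(atraj, side = 8, cell = 8 / 120, channel = ch)
    radial_projection(m, direction, half_window = 15, spacing = 1,
                      line_length = 3.8)
  })
  profile <- mean_profile(profs)
  frac <- plan$peak_min_prominence_frac
  if (is.null(frac)) frac <- 0.05
  peaks <- detect_peaks(profile,
                        min_prominence = frac * max(profile$density),
                        min_separation = plan$peak_min_separation)
  preds <- lapply(seq_len(min(3, nrow(peaks))), function(n)
    predict_separations(peaks, n))
  predictions <- data.frame(
    n_intervening = vapply(preds, `[[`, integer(1), "n_intervening"),
    separation = vapply(preds, `[[`, numeric(1), "separation"))
  list(profile = profile, peaks = peaks, predictions = predictions,
       map = map)
}

#' Run the canonical end-to-end experiment
#'
#' For every configured orientation: umbrella windows, WHAM PMF, minima,
#' barrier and buried-surface-area analysis; plus the single-protein
#' annulus analysis and its separation predictions, and the well-depth
#' versus buried-area regression across configurations.  All outputs and
#' a machine-readable manifest are written when `outdir` is given;
#' re-running the same plan reproduces the manifest bit-for-bit.
#'
#' @param plan An [experiment_plan()].
#' @param outdir Optional output directory (created if needed).
#' @param configurations Subset of configuration names to run.
#' @param quiet Suppress per-stage progress messages.
#' @return Result bundle: `configurations` (per-name results of
#'   [run_configuration()]), `prediction`
#'   ([run_single_protein_analysis()] output), `depth_area` (table),
#'   `depth_area_fit` ([depth_vs_area()] output or `NULL`), `manifest`.
#' @export
run_experiment <- function(plan, outdir = NULL,
                           configurations = names(plan$orientations),
                           quiet = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  say <- function(...) if (!quiet) message(...)
  cfgs <- list()
  for (nm in configurations) {
    say("configuration ", nm, " ...")
    cfgs[[nm]] <- tryCatch(
      run_configuration(plan, nm),
      error = function(e) stop("stage 'configuration ", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  say("single-protein annulus analysis ...")
  pred <- tryCatch(run_single_protein_analysis(plan),
                   error = function(e) stop("stage 'lipidmap' failed: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  depth_area <- data.frame(
    configuration = names(cfgs),
    depth = vapply(cfgs, `[[`, numeric(1), "depth"),
    area = vapply(cfgs, `[[`, numeric(1), "area_at_min"),
    row.names = NULL)
  fit <- NULL
  ok <- is.finite(depth_area$depth) & is.finite(depth_area$area)
  if (sum(ok) >= 3)
    fit <- depth_vs_area(setNames(depth_area[ok, c("depth", "area")],
                                  c("depth", "area")))

  manifest <- .experiment_manifest(plan, cfgs, pred, depth_area, fit)
  out <- list(configurations = cfgs, prediction = pred,
              depth_area = depth_area, depth_area_fit = fit,
              plan = plan, manifest = manifest)
  if (!is.null(outdir)) .write_experiment(out, outdir)
  out
}

.experiment_manifest <- function(plan, cfgs, pred, depth_area, fit) {
  p <- unclass(plan)
  p$orientations <- lapply(p$orientations, as.numeric)
  p$config <- unclass(p$config)
  files <- c(
    vapply(names(cfgs), function(nm)
      sprintf("pmf_%s.tsv", nm), character(1), USE.NAMES = FALSE),
    vapply(names(cfgs), function(nm)
      sprintf("minima_%s.tsv", nm), character(1), USE.NAMES = FALSE),
    vapply(names(cfgs), function(nm)
      sprintf("sasa_%s.tsv", nm), character(1), USE.NAMES = FALSE),
    "annulus_profile.tsv", "annulus_peaks.tsv", "predictions.tsv",
    "depth_vs_area.tsv")
  list(tool = "memdimer", seed = plan$seed, parameters = p,
       configurations = lapply(cfgs, function(cf)
         list(orientations = as.numeric(cf$orientations), seed = cf$seed,
              depth = cf$depth, global_minimum = cf$global_minimum)),
       files = files)
}

.write_experiment <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr_tsv <- function(df, path, hdr) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  }
  for (nm in names(out$configurations)) {
    cf <- out$configurations[[nm]]
    write_pmf_tsv(cf$pmf, file.path(outdir, sprintf("pmf_%s.tsv", nm)))
    if (!is.null(cf$minima_table))
      hdr_tsv(cf$minima_table, file.path(outdir, sprintf("minima_%s.tsv", nm)),
              sprintf("memdimer minima | configuration=%s seed=%d", nm, cf$seed))
    if (!is.null(cf$sasa_profile))
      hdr_tsv(cf$sasa_profile, file.path(outdir, sprintf("sasa_%s.tsv", nm)),
              sprintf("memdimer buried-area profile | configuration=%s probe=%g",
                      nm, out$plan$probe))
  }
  hdr_tsv(out$prediction$profile, file.path(outdir, "annulus_profile.tsv"),
          "memdimer annulus radial profile (mean over leaflets)")
  hdr_tsv(out$prediction$peaks, file.path(outdir, "annulus_peaks.tsv"),
          "memdimer annulus shell peaks")
  hdr_tsv(out$prediction$predictions, file.path(outdir, "predictions.tsv"),
          "memdimer predicted packed separations")
  hdr_tsv(out$depth_area, file.path(outdir, "depth_vs_area.tsv"),
          "memdimer well depth vs buried area at minimum")
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Orientationally-unrestrained control PMF
#'
#' The same umbrella pipeline with the rotational restraint force
#' constant set to zero for both proteins: the bodies rotate freely in
#' each window, so the discrete lipid-packing shoulders wash out while
#' the contact well and the outer barrier persist.
#'
#' @param plan An [experiment_plan()].
#' @param orientation Initial orientation angles (degrees) for the
#'   windows (the bodies drift away from them freely).
#' @return A zero-referenced [pmf_profile()] with attribute `control`
#'   echoing `k_rot = 0`.
#' @export
run_unrestrained_control <- function(plan, orientation = c(0, 0)) {
  stopifnot(inherits(plan, "experiment_plan"))
  seed_c <- .config_seed(plan$seed, 99L)
  contact <- toy_contact_separation(plan$config, orientation)
  coarse <- generate_umbrella_dataset(
    plan$config, plan$coarse_centers[plan$coarse_centers >= contact - 0.3],
    plan$k_coarse, plan$n_coarse,
    seed = seed_c, orientations = orientation, k_rot = 0,
    equil_steps = plan$equil_steps)
  fine <- list()
  keep_f <- plan$fine_centers >= contact - 0.3
  if (any(keep_f))
    fine <- generate_umbrella_dataset(
      plan$config, plan$fine_centers[keep_f], plan$k_fine, plan$n_fine,
      seed = seed_c + 1L, orientations = orientation, k_rot = 0,
      equil_steps = plan$equil_steps)
  windows <- c(coarse, fine)
  ctr <- vapply(windows, function(w) w$bias$center, numeric(1))
  h <- build_histograms(windows, plan$bin_width, range = range(ctr))
  pmf <- zero_reference(solve_wham(h), plan$reference)
  attr(pmf, "control") <- list(k_rot = 0, seed = seed_c)
  pmf
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat("Experiment plan:", length(x$orientations), "configurations,",
      length(x$coarse_centers), "coarse +", length(x$fine_centers),
      "fine windows each, seed", x$seed, "\n")
  invisible(x)
}

#' Plot a PMF profile
#'
#' @param x A [pmf_profile()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$center, x$free_energy, type = "l",
                 xlab = "inter-protein separation (toy units)",
                 ylab = "free energy (T)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Plot a radial annulus profile
#'
#' @param x A `radial_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$distance, x$density, type = "l",
                 xlab = "distance from protein COM (toy units)",
                 ylab = "lipid density (counts/frame/cell)", ...)
  invisible(x)
}
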