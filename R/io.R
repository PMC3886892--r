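#' Write a trajectory as columnar TSV
#'
#' One row per particle per stored frame, columns `frame`, `time`,
#' `body_label`, `lipid_id`, `leaflet`, `x`, `y`; `#`-prefixed header
#' lines echo the configuration and master seed.
#'
#' @param traj A `toy_trajectory` with stored lipid frames.
#' @param path Output file.
#' @param frames Frame indices to write (default: all).
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path, frames = seq_along(traj$time)) {
  cfg <- traj$config
  hdr <- c(
    "# memdimer toy trajectory",
    sprintf("# seed=%d", traj$seed),
    sprintf("# box_side=%g n_lipids=%d lipid_diameter=%g", cfg$box_side,
            cfg$n_lipids, cfg$lipid_diameter),
    sprintf("# semi_axes=%g,%g n_body_particles=%d", cfg$protein_semi_axes[1],
            cfg$protein_semi_axes[2], cfg$n_body_particles),
    sprintf("# temperature=%g friction=%g timestep=%g", cfg$temperature,
            cfg$friction, cfg$timestep),
    sprintf("# length_scale_nm=%g", cfg$length_scale_nm),
    sprintf("# k_umb=%g d0=%g k_rot=%g", traj$restraints$k_umb,
            traj$restraints$d0, traj$restraints$k_rot))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tabs <- lapply(frames, function(i) cbind(frame = i, as_frame(traj, i)))
  tab <- do.call(rbind, tabs)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read umbrella windows from two-column TSV files
#'
#' Reads the generic `(time, separation)` dialect (whitespace- or
#' tab-separated, `#` comments; extra columns ignored), one file per
#' window.  This covers externally produced pull-coordinate series as
#' well as files written by [write_window_tsv()].
#'
#' @param paths Character vector of file paths.
#' @param centers,k_umb Bias centre and force constant per window
#'   (recycled).
#' @param temperature Thermal energy.
#' @return List of [umbrella_window()]s.
#' @export
read_umbrella_windows <- function(paths, centers, k_umb, temperature = 1) {
  centers <- rep_len(centers, length(paths))
  k_umb <- rep_len(k_umb, length(paths))
  lapply(seq_along(paths), function(i) {
    tab <- read.table(paths[i], comment.char = "#", header = FALSE)
    umbrella_window(tab[[2]], harmonic_bias(centers[i], k_umb[i]),
                    temperature = temperature,
                    metadata = list(file = basename(paths[i])))
  })
}

#' Write one window's reaction-coordinate series as TSV
#'
#' @param window An [umbrella_window()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_window_tsv <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# umbrella window d0=%g k=%g T=%g",
                       window$bias$center, window$bias$force_constant,
                       window$temperature),
               sprintf("# delipidated=%s",
                       isTRUE(window$metadata$delipidated))), con)
  write.table(data.frame(time = seq_along(window$samples),
                         separation = window$samples),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a PMF profile as TSV
#'
#' Two columns (bin centre, free energy) with `#`-prefixed metadata
#' header lines.
#'
#' @param pmf A [pmf_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# memdimer PMF profile",
               sprintf("# reference_separation=%s",
                       attr(pmf, "reference_separation")),
               sprintf("# temperature=%g iterations=%s residual=%s",
                       attr(pmf, "temperature"), attr(pmf, "iterations"),
                       attr(pmf, "residual")),
               "# center\tfree_energy"), con)
  write.table(data.frame(pmf$center, pmf$free_energy), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PMF profile written by [write_pmf_tsv()]
#'
#' @param path Input file.
#' @return A [pmf_profile()].
#' @export
read_pmf_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  ref <- NA_real_
  m <- regmatches(hdr, regexec("reference_separation=([-0-9.eENA]+)", hdr))
  for (mm in m) if (length(mm) == 2 && mm[2] != "NA")
    ref <- as.numeric(mm[2])
  tab <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  pmf_profile(tab[[1]], tab[[2]], reference_separation = ref)
}

#' Write / read a flat key-value configuration file
#'
#' The dialect used for toy configurations and restraint echoes:
#' `key = value` lines, `#` comments, values parsed as numeric where
#' possible; `include = <path>` lines pull in another file (relative to
#' the including file).
#'
#' @param x Named list of scalar values.
#' @param path File path.
#' @return For write: `path` invisibly; for read: a named list.
#' @export
write_keyvalue <- function(x, path) {
  writeLines(sprintf("%s = %s", names(x),
                     vapply(x, function(v) paste(v, collapse = ","), "")),
             path)
  invisible(path)
}

#' @rdname write_keyvalue
#' @export
read_keyvalue <- function(path) {
  out <- list()
  for (line in readLines(path)) {
    line <- sub("#.*", "", line)
    if (!nzchar(trimws(line))) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (key == "include") {
      inc <- read_keyvalue(file.path(dirname(path), val))
      out[names(inc)] <- inc
      next
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Read a trajectory written by [write_trajectory_tsv()]
#'
#' @param path Input file.
#' @return A long data frame (one row per particle per frame) with the
#'   header metadata attached as attribute `metadata`.
#' @export
read_trajectory_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  for (hl in hdr) {
    for (kv in regmatches(hl,
                          gregexpr("[a-zA-Z_][a-zA-Z_0-9]*=[-0-9.eE,]+",
                                   hl))[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- as.numeric(strsplit(parts[2], ",")[[1]])
    }
  }
  tab <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t")
  attr(tab, "metadata") <- meta
  tab
}

#' Rebuild an umbrella window from a trajectory table
#'
#' Computes the per-frame inter-protein centre-of-mass separation
#' (minimum image if the box side is known) from a long trajectory table
#' and wraps it as an [umbrella_window()].
#'
#' @param tab A data frame from [read_trajectory_tsv()] (two protein
#'   bodies required).
#' @param bias The window's [harmonic_bias()] (defaults to the header's
#'   `k_umb`/`d0` echo when present).
#' @param temperature Thermal energy.
#' @return An [umbrella_window()].
#' @export
window_from_trajectory <- function(tab, bias = NULL, temperature = 1) {
  meta <- attr(tab, "metadata")
  if (is.null(bias)) {
    if (is.null(meta$k_umb) || is.null(meta$d0))
      stop("no bias given and none recorded in the trajectory header")
    bias <- harmonic_bias(meta$d0, meta$k_umb)
  }
  L <- meta$box_side
  seps <- vapply(split(tab, tab$frame), function(fr) {
    a <- colMeans(fr[fr$body_label == "protein_A", c("x", "y")])
    b <- colMeans(fr[fr$body_label == "protein_B", c("x", "y")])
    d <- b - a
    if (!is.null(L)) d <- d - L * round(d / L)
    sqrt(sum(d^2))
  }, numeric(1))
  umbrella_window(unname(seps), bias, temperature,
                  metadata = list(source = "trajectory"))
}

#' Persist a 2D density map as text
#'
#' A dense matrix format with a JSON header line (grid geometry, channel,
#' frame count) prefixed by `#`.
#'
#' @param map A [accumulate_density()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(side = map$side, cell = map$cell,
                               center = map$center,
                               n_frames = map$n_frames,
                               channel = map$channel),
                          auto_unbox = TRUE, digits = NA)
  writeLines(paste0("# ", hdr), con)
  write.table(map$counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  counts <- as.matrix(read.table(text = lines[-1], sep = "\t"))
  dimnames(counts) <- NULL
  structure(list(counts = counts, side = meta$side, cell = meta$cell,
                 center = meta$center, n_frames = meta$n_frames,
                 channel = meta$channel),
            class = "density_map")
}

#' Serialize a restraint set in the key-value config dialect
#'
#' @param rs A [restraint_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_restraints_config <- function(rs, path) {
  out <- list()
  if (!is.null(rs$bias)) {
    out$d0 <- rs$bias$center
    out$k_umb <- rs$bias$force_constant
  }
  for (r in rs$rotational) {
    tag <- if (identical(r$body, "protein_B")) "B" else "A"
    out[[paste0("k_rot_", tag)]] <- r$force_constant
    out[[paste0("epsilon_", tag)]] <- r$epsilon
  }
  write_keyvalue(out, path)
}
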