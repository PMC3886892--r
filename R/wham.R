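#' An umbrella-sampling window
#'
#' One biased simulation's restraint parameters plus its sampled
#' reaction-coordinate series.
#'
#' @param samples Non-empty, finite reaction-coordinate series.
#' @param bias The window's [harmonic_bias()].
#' @param temperature Thermal energy (> 0).
#' @param metadata List of provenance entries (seed, duration,
#'   `delipidated` flag, ...).
#' @param trajectory Optional attached `toy_trajectory` the samples came
#'   from (kept for surface-area and lipid-counting analyses).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(samples, bias, temperature = 1,
                            metadata = list(), trajectory = NULL) {
  stopifnot(length(samples) > 0, all(is.finite(samples)),
            inherits(bias, "harmonic_bias"), temperature > 0)
  structure(list(samples = as.numeric(samples), bias = bias,
                 temperature = temperature, metadata = metadata,
                 trajectory = trajectory),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window: d0 = %.3f, k = %g, %d samples%s\n",
              x$bias$center, x$bias$force_constant, length(x$samples),
              if (isTRUE(x$metadata$delipidated)) " (delipidated)" else ""))
  invisible(x)
}

#' Histogram the windows onto a common grid
#'
#' Builds shared bin edges spanning all samples (aligned to multiples of
#' `bin_width`) and per-window counts.  If an explicit `range` is given,
#' out-of-range samples are counted and reported in the `out_of_range`
#' field — never silently dropped from the totals.
#'
#' @param windows List of [umbrella_window()]s (non-empty).
#' @param bin_width Bin width (> 0).
#' @param range Optional `c(min, max)` overriding the automatic span.
#' @return Object of class `histogram_set`: `edges`, `centers`, `counts`
#'   (window x bin matrix), `totals`, `out_of_range`, `biases`,
#'   `temperature`.
#' @export
build_histograms <- function(windows, bin_width, range = NULL) {
  stopifnot(length(windows) >= 1, bin_width > 0)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!inherits(w, "umbrella_window") || length(w$samples) == 0)
      stop(sprintf("window %d is empty or not an umbrella_window", i))
  }
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-12)
    stop("all windows must share one temperature")
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range)) {
    lo <- floor(min(all_s) / bin_width) * bin_width
    hi <- ceiling(max(all_s) / bin_width) * bin_width
    if (hi <= max(all_s)) hi <- hi + bin_width # keep the top sample interior
  } else {
    lo <- range[1]; hi <- range[2]
  }
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  nb <- length(edges) - 1
  counts <- matrix(0L, nrow = length(windows), ncol = nb)
  oor <- integer(length(windows))
  for (i in seq_along(windows)) {
    s <- windows[[i]]$samples
    inr <- s >= lo & s <= hi
    oor[i] <- sum(!inr)
    idx <- pmin(pmax(findInterval(s[inr], edges, rightmost.closed = TRUE),
                     1L), nb)
    counts[i, ] <- tabulate(idx, nbins = nb)
  }
  structure(list(
    edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
    counts = counts,
    totals = vapply(windows, function(w) length(w$samples), integer(1)),
    out_of_range = oor,
    biases = lapply(windows, `[[`, "bias"),
    temperature = temps[1]
  ), class = "histogram_set")
}

#' Adjacent-window histogram overlap diagnostics
#'
#' For WHAM to connect windows, adjacent histograms must overlap.  For
#' each adjacent pair (ordered by bias centre) this reports the histogram
#' intersection fraction — the summed bin-wise minimum of the two
#' normalized histograms, in `[0, 1]` — and flags pairs below
#' `threshold`.
#'
#' @param hists A [build_histograms()] result with >= 2 windows.
#' @param threshold Flagging threshold.
#' @return Data frame with one row per adjacent pair: centres, `overlap`,
#'   `flagged`.
#' @export
overlap_diagnostics <- function(hists, threshold = 0.1) {
  stopifnot(inherits(hists, "histogram_set"), nrow(hists$counts) >= 2)
  ctr <- vapply(hists$biases, `[[`, numeric(1), "center")
  ord <- order(ctr)
  h <- hists$counts[ord, , drop = FALSE]
  h <- h / pmax(rowSums(h), 1)
  n <- nrow(h) - 1
  ov <- vapply(seq_len(n), function(i) sum(pmin(h[i, ], h[i + 1, ])),
               numeric(1))
  data.frame(center_lo = ctr[ord][seq_len(n)],
             center_hi = ctr[ord][seq_len(n) + 1],
             overlap = ov, flagged = ov < threshold)
}

#' A potential-of-mean-force profile
#'
#' @param centers Bin centres.
#' @param free_energy Free energies (may contain `NA` at unsampled bins,
#'   which are reported as gaps, never interpolated).
#' @param reference_separation Declared zero-reference separation
#'   (`NA` while unreferenced).
#' @param temperature Thermal energy the profile is expressed in.
#' @param iterations,residual WHAM convergence metadata.
#' @return Object of class `pmf_profile` (a data frame with columns
#'   `center`, `free_energy` and metadata attributes).
#' @export
pmf_profile <- function(centers, free_energy, reference_separation = NA,
                        temperature = 1, iterations = NA_integer_,
                        residual = NA_real_) {
  stopifnot(length(centers) == length(free_energy),
            all(diff(centers) > 0))
  structure(data.frame(center = centers, free_energy = free_energy),
            reference_separation = reference_separation,
            temperature = temperature, iterations = iterations,
            residual = residual,
            class = c("pmf_profile", "data.frame"))
}

#' @export
print.pmf_profile <- function(x, ...) {
  ref <- attr(x, "reference_separation")
  cat(sprintf("PMF profile: %d bins on [%.3f, %.3f], %s\n",
              nrow(x), min(x$center), max(x$center),
              if (is.na(ref)) "unreferenced"
              else sprintf("zero at %.3f", ref)))
  if (!is.na(attr(x, "iterations")))
    cat(sprintf("  WHAM: %d iterations, final residual %.2e\n",
                attr(x, "iterations"), attr(x, "residual")))
  invisible(x)
}

#' Solve the WHAM equations
#'
#' Standard self-consistent iteration over the per-window free-energy
#' shifts \eqn{f_k} and the unbiased bin probabilities:
#' \deqn{p_b \propto \frac{\sum_k n_{kb}}
#'   {\sum_k N_k e^{(f_k - U_k(x_b))/T}}, \qquad
#'   e^{-f_k/T} = \sum_b e^{-U_k(x_b)/T} p_b,}
#' declared converged when the largest change of any \eqn{f_k} between
#' iterations falls below `tolerance` (energy units).  Bins with zero
#' total counts are reported as gaps (`NA` free energy); windows that are
#' not connected through jointly occupied bins are an error.
#'
#' @param hists A [build_histograms()] result.
#' @param biases Optional list of [harmonic_bias()] overriding those in
#'   `hists`.
#' @param temperature Thermal energy (defaults to the windows').
#' @param tolerance Convergence tolerance on the `f_k` (energy units).
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   final residual.
#' @return An unreferenced [pmf_profile()] with convergence metadata.
#' @export
solve_wham <- function(hists, biases = NULL,
                       temperature = hists$temperature,
                       tolerance = 1e-6, max_iter = 100000L) {
  stopifnot(inherits(hists, "histogram_set"), tolerance > 0)
  if (is.null(biases)) biases <- hists$biases
  K <- nrow(hists$counts)
  x <- hists$centers
  Nk <- rowSums(hists$counts) # in-range totals actually histogrammed
  Hb <- colSums(hists$counts)
  occ <- Hb > 0

  # connectivity of windows through jointly occupied bins
  if (K > 1) {
    adj <- (hists$counts[, occ, drop = FALSE] > 0) %*%
      t(hists$counts[, occ, drop = FALSE] > 0) > 0
    comp <- .connected_components(adj)
    if (max(comp) > 1) {
      gaps <- x[!occ]
      stop(sprintf(
        "disconnected sampling support (%d groups of windows); gap bins near %s",
        max(comp),
        paste(sprintf("%.3f", head(gaps, 5)), collapse = ", ")))
    }
  }

  # bias energies at bin centers: K x B
  U <- t(vapply(biases, function(b) umbrella_energy_force(x, b)$energy,
                numeric(length(x))))
  C <- exp(-U / temperature)
  f <- rep(1, K) # f_k here are the exponential shifts exp(f/T), init 1
  g_old <- rep(0, K)
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- colSums((Nk * f) * C) # length B
    p <- ifelse(occ, Hb / denom, 0)
    p <- p / sum(p)
    finv <- as.numeric(C %*% p)
    f <- 1 / finv
    g <- -temperature * log(f)
    g <- g - g[1]
    resid <- max(abs(g - g_old))
    g_old <- g
    if (resid < tolerance) break
    if (it >= max_iter)
      stop(sprintf("WHAM failed to converge in %d iterations (residual %.3e)",
                   max_iter, resid))
  }
  fe <- ifelse(occ, -temperature * log(p), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  pmf_profile(x, fe, temperature = temperature, iterations = it,
              residual = resid)
}

.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Pin a PMF to zero at a reference separation
#'
#' Subtracts the value of the bin containing `reference_separation`, so
#' that bin is exactly zero afterwards; idempotent.
#'
#' @param pmf A [pmf_profile()].
#' @param reference_separation Separation inside the sampled support.
#' @return The referenced [pmf_profile()].
#' @export
zero_reference <- function(pmf, reference_separation) {
  stopifnot(inherits(pmf, "pmf_profile"))
  i <- which.min(abs(pmf$center - reference_separation))
  half <- if (nrow(pmf) > 1) diff(pmf$center[1:2]) / 2 else Inf
  if (abs(pmf$center[i] - reference_separation) > half + 1e-12)
    stop("reference separation outside the profile support")
  if (!is.finite(pmf$free_energy[i]))
    stop("reference bin is an unsampled gap")
  out <- pmf
  out$free_energy <- pmf$free_energy - pmf$free_energy[i]
  attr(out, "reference_separation") <- reference_separation
  out
}

#' Split-half convergence assessment
#'
#' Splits every window's sample series into two contiguous-in-time,
#' non-intersecting halves, solves WHAM independently on each half, pins
#' both to the same zero reference, and reports the maximum absolute
#' pointwise discrepancy over the jointly sampled support.  This is the
#' pipeline's only statistical error estimate.
#'
#' @param windows List of [umbrella_window()]s, each with >= 2 samples.
#' @param bin_width Histogram bin width.
#' @param tolerance WHAM convergence tolerance.
#' @param reference Zero-reference separation (defaults to the largest
#'   bias centre).
#' @param min_counts Bins enter the discrepancy comparison only where
#'   each half holds at least this many counts (the same spirit as
#'   restricting oracle comparisons to well-sampled bins): a pointwise
#'   free energy backed by a handful of extreme excursions carries no
#'   information about convergence.
#' @return List `pmf_first_half`, `pmf_second_half`, `max_discrepancy`.
#' @export
split_half_convergence <- function(windows, bin_width, tolerance = 1e-6,
                                   reference = NULL, min_counts = 100) {
  for (i in seq_along(windows)) {
    if (length(windows[[i]]$samples) < 2)
      stop(sprintf("window %d too short to split", i))
  }
  if (is.null(reference))
    reference <- max(vapply(windows, function(w) w$bias$center, numeric(1)))
  halves <- function(which_half) {
    lapply(windows, function(w) {
      n <- length(w$samples)
      idx <- if (which_half == 1) seq_len(floor(n / 2))
             else (floor(n / 2) + 1):n
      umbrella_window(w$samples[idx], w$bias, w$temperature, w$metadata)
    })
  }
  h1 <- build_histograms(halves(1), bin_width)
  h2 <- build_histograms(halves(2), bin_width)
  p1 <- zero_reference(solve_wham(h1, tolerance = tolerance), reference)
  p2 <- zero_reference(solve_wham(h2, tolerance = tolerance), reference)
  key1 <- round(p1$center / bin_width)
  key2 <- round(p2$center / bin_width)
  common <- intersect(key1, key2)
  i1 <- match(common, key1)
  i2 <- match(common, key2)
  ok <- is.finite(p1$free_energy[i1]) & is.finite(p2$free_energy[i2]) &
    colSums(h1$counts)[i1] >= min_counts &
    colSums(h2$counts)[i2] >= min_counts
  list(pmf_first_half = p1, pmf_second_half = p2,
       max_discrepancy = max(abs(p1$free_energy[i1][ok] -
                                   p2$free_energy[i2][ok])))
}
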