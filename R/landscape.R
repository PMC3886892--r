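#' Candidate local minima of a PMF
#'
#' Interior bins strictly lower than both neighbours, filtered by
#' prominence: the smaller of the two barriers that must be climbed
#' (leftwards / rightwards, stopping where the profile first drops below
#' the candidate or at the ends of the support) must reach at least
#' `prominence_threshold` above the candidate.  The threshold suppresses
#' sampling ripple while keeping genuinely shallow metastable states.
#'
#' @param pmf A [pmf_profile()] (>= 3 finite bins).
#' @param prominence_threshold Minimum prominence (energy units).
#' @return Integer vector of bin indices, sorted by location (possibly
#'   empty).
#' @export
find_local_minima <- function(pmf, prominence_threshold = 0.25) {
  f <- pmf$free_energy
  n <- length(f)
  stopifnot(n >= 3)
  cand <- which(vapply(2:(n - 1), function(i) {
    is.finite(f[i]) && is.finite(f[i - 1]) && is.finite(f[i + 1]) &&
      f[i] < f[i - 1] && f[i] < f[i + 1]
  }, logical(1))) + 1L
  keep <- vapply(cand, function(i) {
    .prominence(f, i) >= prominence_threshold
  }, logical(1))
  sort(cand[keep])
}

# prominence of a discrete local minimum: min over both directions of the
# highest point passed before first dropping below f[i] (or the end)
.prominence <- function(f, i) {
  climb <- function(idx_seq) {
    hi <- -Inf
    for (j in idx_seq) {
      if (!is.finite(f[j])) break
      if (f[j] < f[i]) break
      hi <- max(hi, f[j])
    }
    hi
  }
  l <- climb(rev(seq_len(i - 1)))
  r <- climb(seq(i + 1, length(f)))
  min(l, r) - f[i]
}

#' Quadratic (sub-bin) location of a PMF minimum
#'
#' Least-squares parabola over the bins within `half_window` of a
#' discrete candidate minimum; the reported location is the vertex
#' abscissa (not necessarily a bin centre) and the depth its ordinate.
#' A sensitivity range — the spread of vertex locations when the window
#' is shrunk/grown by one bin — accompanies every record.
#'
#' @param pmf A [pmf_profile()].
#' @param index Bin index of a discrete local minimum (e.g. from
#'   [find_local_minima()]).
#' @param half_window Half-width of the fit window in length units
#'   (default: two bins on each side).
#' @param classification `"global"` or `"local"` label carried in the
#'   record.
#' @return Object of class `minimum_record`: `location`, `depth`,
#'   `curvature`, `fit_window`, `classification`,
#'   `location_sensitivity`.
#' @export
quadratic_fit_minimum <- function(pmf, index,
                                  half_window = NULL,
                                  classification = "local") {
  x <- pmf$center; f <- pmf$free_energy
  bw <- diff(x[1:2])
  if (is.null(half_window)) half_window <- 2 * bw

  fit_at <- function(hw) {
    sel <- which(abs(x - x[index]) <= hw + 1e-9 & is.finite(f))
    if (length(sel) < 3) return(NULL)
    # centre the abscissa for numerical conditioning
    xx <- x[sel] - x[index]
    co <- coef(lm(f[sel] ~ xx + I(xx^2)))
    a <- co[3]; b <- co[2]; c0 <- co[1]
    list(a = a, loc = x[index] - b / (2 * a),
         depth = c0 - b^2 / (4 * a), window = range(x[sel]))
  }
  main <- fit_at(half_window)
  if (is.null(main)) stop("fewer than 3 bins inside the fit window")
  if (!is.finite(main$a) || main$a <= 1e-10)
    stop("fitted curvature <= 0: not a minimum at this window scale")
  sens <- range(c(main$loc, unlist(lapply(
    c(half_window - bw, half_window + bw),
    function(hw) {
      r <- tryCatch(fit_at(hw), error = function(e) NULL)
      if (!is.null(r) && r$a > 0) r$loc else NULL
    }))))
  structure(list(location = unname(main$loc), depth = unname(main$depth),
                 curvature = unname(2 * main$a), fit_window = main$window,
                 classification = classification,
                 location_sensitivity = sens),
            class = "minimum_record")
}

#' @export
print.minimum_record <- function(x, ...) {
  cat(sprintf(
    "%s minimum at %.4f (depth %.3f, curvature %.2f, window [%.3f, %.3f])\n",
    x$classification, x$location, x$depth, x$curvature,
    x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' All fitted minima of a PMF
#'
#' Convenience wrapper: detects discrete local minima, fits each with a
#' quadratic, and labels the deepest fitted minimum `"global"`.
#'
#' @inheritParams find_local_minima
#' @inheritParams quadratic_fit_minimum
#' @return List of `minimum_record`s sorted by location (possibly empty).
#' @export
fit_minima <- function(pmf, prominence_threshold = 0.25,
                       half_window = NULL) {
  idx <- find_local_minima(pmf, prominence_threshold)
  recs <- list()
  for (i in idx) {
    r <- tryCatch(quadratic_fit_minimum(pmf, i, half_window),
                  error = function(e) NULL)
    if (!is.null(r)) recs[[length(recs) + 1]] <- r
  }
  if (length(recs)) {
    depths <- vapply(recs, `[[`, numeric(1), "depth")
    recs[[which.min(depths)]]$classification <- "global"
  }
  recs
}

#' Depth of the potential well
#'
#' The value (a negative energy, relative to the profile's declared zero
#' at large separation) of the deepest quadratic-fitted minimum.
#'
#' @param pmf A zero-referenced [pmf_profile()].
#' @param prominence_threshold,half_window Passed to [fit_minima()].
#' @return Scalar well depth.
#' @export
well_depth <- function(pmf, prominence_threshold = 0.25,
                       half_window = NULL) {
  recs <- fit_minima(pmf, prominence_threshold, half_window)
  if (!length(recs)) stop("no minima found in the profile")
  min(vapply(recs, `[[`, numeric(1), "depth"))
}

#' Locate the desolvation-like barrier
#'
#' Highest interior local maximum of the profile within `search_range`
#' (which should lie beyond the outermost minimum); its height is
#' measured relative to the profile's zero reference.  Returns `NULL`
#' (an absent result, not an error) if the profile has no interior
#' maximum there.
#'
#' @param pmf A zero-referenced [pmf_profile()].
#' @param search_range `c(min, max)` separations to search.
#' @return Object of class `barrier_record` (`location`, `height`) or
#'   `NULL`.
#' @export
find_barrier <- function(pmf, search_range) {
  x <- pmf$center; f <- pmf$free_energy
  sel <- which(x >= search_range[1] & x <= search_range[2])
  sel <- sel[sel > 1 & sel < length(x)]
  is_max <- vapply(sel, function(i) {
    all(is.finite(f[(i - 1):(i + 1)])) &&
      f[i] > f[i - 1] && f[i] > f[i + 1]
  }, logical(1))
  sel <- sel[is_max]
  if (!length(sel)) return(NULL)
  i <- sel[which.max(f[sel])]
  structure(list(location = x[i], height = max(f[i], 0)),
            class = "barrier_record")
}

#' @export
print.barrier_record <- function(x, ...) {
  cat(sprintf("barrier at %.3f, height %.3f above the reference\n",
              x$location, x$height))
  invisible(x)
}
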