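#' Transform tracks into step coordinates
#'
#' For each consecutive triplet of positions the current displacement is
#' rotated rigidly so that the previous displacement points along the
#' positive x axis, yielding the components `dx_par` (parallel to the
#' previous step) and `dy_perp` (perpendicular; positive for
#' counter-clockwise turns) plus the signed turning angle in (-pi, pi].
#' A track of m points yields m - 2 step samples; samples whose previous
#' displacement is shorter than `zero_tol` have an undefined rotation and are
#' skipped (counted in the `"n_skipped"` attribute). Steps from multiple
#' tracks are pooled into one dataset.
#'
#' @param tracks A [cell_track()] or a list of them.
#' @param zero_tol Minimum previous-step length (um) for the rotation to be
#'   defined. Default 1e-9.
#' @return A data frame of class `step_data` with columns `cell_id`,
#'   `step_index` (index of the current displacement within its track,
#'   starting at 2), `dx_par`, `dy_perp`, `turn_angle`, and `true_state` when
#'   the tracks carry ground-truth labels. Attributes: `dt` (sampling
#'   interval) and `n_skipped`.
#' @examples
#' tr <- cell_track("c1", 0:3, c(0, 1, 2, 2), c(0, 0, 0, 1))
#' track_to_steps(tr)
#' @export
track_to_steps <- function(tracks, zero_tol = 1e-9) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  if (!length(tracks) || !all(vapply(tracks, inherits, TRUE, "cell_track"))) {
    stop("`tracks` must be a cell_track or list of cell_tracks", call. = FALSE)
  }
  out <- vector("list", length(tracks))
  n_skipped <- 0L
  dts <- vapply(tracks, track_dt, numeric(1))
  if (diff(range(dts)) > 1e-8 * max(dts)) {
    stop("all tracks must share the same sampling interval", call. = FALSE)
  }
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    m <- length(tr$times)
    if (m < 3L) {
      stop(sprintf("track %s has fewer than 3 points; no steps can be formed",
                   tr$cell_id), call. = FALSE)
    }
    dx <- diff(tr$xs)
    dy <- diff(tr$ys)
    nseg <- m - 1L
    j <- 2:nseg                       # current displacement index
    prev_len <- sqrt(dx[j - 1L]^2 + dy[j - 1L]^2)
    ok <- prev_len >= zero_tol
    n_skipped <- n_skipped + sum(!ok)
    j <- j[ok]
    phi <- atan2(dy[j - 1L], dx[j - 1L])
    cp <- cos(phi); sp <- sin(phi)
    dx_par <- cp * dx[j] + sp * dy[j]
    dy_perp <- -sp * dx[j] + cp * dy[j]
    df <- data.frame(
      cell_id = rep(tr$cell_id, length(j)),
      step_index = j,
      dx_par = dx_par,
      dy_perp = dy_perp,
      turn_angle = atan2(dy_perp, dx_par),
      stringsAsFactors = FALSE
    )
    if (!is.null(tr$true_states)) df$true_state <- tr$true_states[j]
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dt") <- dts[1]
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("step_data", "data.frame")
  res
}

#' Persistence statistic
#'
#' The mean cosine of the turning angle pooled over all steps: 1 for
#' straight-line motion, 0 for directionless (diffusive) motion, -1 for
#' systematic reversals.
#'
#' @param steps A `step_data` data frame from [track_to_steps()].
#' @return A value in \[-1, 1\].
#' @export
persistence <- function(steps) {
  if (!is.data.frame(steps) || !nrow(steps)) {
    stop("`steps` must contain at least one step sample", call. = FALSE)
  }
  mean(cos(steps$turn_angle))
}

#' Density histogram of step components
#'
#' Builds a density-normalized histogram (integrating to 1) used as the
#' empirical fitting surface for the sum-of-squared-errors objective.
#' The default binning is Freedman-Diaconis; a fixed bin width or explicit
#' edges may be given instead.
#'
#' @param values Numeric vector (>= 2 finite values with non-zero range).
#' @param breaks Passed to [graphics::hist()] when `width` and `edges` are
#'   NULL; default `"FD"`.
#' @param width Optional fixed bin width (um).
#' @param edges Optional explicit bin edges covering `range(values)`.
#' @return An object of class `step_histogram`: list with `bin_edges`,
#'   `densities` (per um), `counts`, and `n`.
#' @export
build_histogram <- function(values, breaks = "FD", width = NULL, edges = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("all values identical; histogram range is zero", call. = FALSE)
  }
  if (!is.null(edges)) {
    brk <- sort(edges)
  } else if (!is.null(width)) {
    stop_if_not_scalar_num(width, "width", positive = TRUE)
    lo <- floor(min(values) / width) * width
    hi <- ceiling(max(values) / width) * width
    if (hi <= lo) hi <- lo + width
    brk <- seq(lo, hi, by = width)
    if (brk[length(brk)] < max(values)) brk <- c(brk, brk[length(brk)] + width)
  } else {
    brk <- breaks
  }
  h <- graphics::hist(values, breaks = brk, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  out <- structure(
    list(bin_edges = h$breaks, densities = h$density, counts = h$counts,
         n = length(values)),
    class = "step_histogram"
  )
  stopifnot(abs(sum(out$densities * diff(out$bin_edges)) - 1) < 1e-9)
  out
}

#' @export
print.step_histogram <- function(x, ...) {
  cat(sprintf("<step_histogram> %d bins on [%g, %g], n = %d\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges), x$n))
  invisible(x)
}
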