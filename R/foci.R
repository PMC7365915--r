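#' Ratiometric biosensor frame
#'
#' One frame of a ratiometric activity image (e.g., a FRET/donor ratio
#' reporting local GTPase activity) together with its binary cell mask.
#'
#' @param intensities Non-negative numeric matrix of ratiometric activity.
#' @param mask Logical (or 0/1) matrix of the same shape; at least one
#'   foreground pixel.
#' @param frame_index Frame number (0-based by convention).
#' @param cell_id Cell identifier.
#' @return An object of class `ratiometric_frame`.
#' @export
ratiometric_frame <- function(intensities, mask, frame_index = 0L,
                              cell_id = "cell") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("`intensities` must be non-negative", call. = FALSE)
  }
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(intensities))) {
    stop("`mask` and `intensities` must have identical shape", call. = FALSE)
  }
  if (!any(mask)) stop("`mask` has no foreground pixel", call. = FALSE)
  structure(list(intensities = intensities, mask = mask,
                 frame_index = as.integer(frame_index), cell_id = cell_id),
            class = "ratiometric_frame")
}

#' Detection rules for activity foci
#'
#' A focus is a contiguous in-mask region that simultaneously (1) exceeds
#' the cell's mean intensity by the fraction `intensity_excess`, (2) is
#' strictly larger than `min_area_px` pixels, and (3) has at least one pixel
#' within `edge_dist_px` of the cell edge.
#'
#' @param intensity_excess Fractional excess over the in-mask mean intensity
#'   (default 0.60, i.e., pixels more than 60% above the cell mean).
#' @param min_area_px Minimum region area in pixels, strict (default 100).
#' @param edge_dist_px Maximum Euclidean distance (pixels) from the nearest
#'   region pixel to the cell edge (default 5).
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `foci_config`.
#' @export
foci_config <- function(intensity_excess = 0.60, min_area_px = 100L,
                        edge_dist_px = 5, connectivity = 8L) {
  stop_if_not_scalar_num(intensity_excess, "intensity_excess", positive = TRUE)
  stop_if_not_scalar_num(min_area_px, "min_area_px", positive = TRUE)
  stop_if_not_scalar_num(edge_dist_px, "edge_dist_px", positive = TRUE)
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(list(intensity_excess = intensity_excess,
                 min_area_px = as.integer(min_area_px),
                 edge_dist_px = edge_dist_px,
                 connectivity = as.integer(connectivity)),
            class = "foci_config")
}

# Connected-component labeling of a logical matrix at 4- or 8-connectivity,
# via graph components over pixel adjacencies.
label_components <- function(bw, connectivity = 8L) {
  nr <- nrow(bw)
  nc <- ncol(bw)
  idx <- which(bw)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (off in offsets) {
    di <- off[1]; dj <- off[2]
    ra <- seq_len(nr - di)
    if (dj >= 0) { ca <- seq_len(nc - dj) } else { ca <- seq(1 - dj, nc) }
    sub <- bw[ra, ca, drop = FALSE] & bw[ra + di, ca + dj, drop = FALSE]
    kk <- which(sub)
    if (!length(kk)) next
    i <- ra[(kk - 1L) %% length(ra) + 1L]
    j <- ca[(kk - 1L) %/% length(ra) + 1L]
    edges[[length(edges) + 1L]] <- cbind(i + (j - 1L) * nr,
                                         (i + di) + (j + dj - 1L) * nr)
  }
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::make_graph(edges = rbind(match(e[, 1], idx),
                                          match(e[, 2], idx)),
                            n = length(idx), directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# Cell edge: in-mask pixels with at least one out-of-mask 4-neighbor
# (pixels on the image border count as edge).
mask_edge <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

# Euclidean distance of every pixel to the cell-edge pixel set.
edge_distance <- function(mask) {
  em <- mask_edge(mask)
  D <- EBImage::distmap(matrix(as.numeric(!em), nrow(em), ncol(em)))
  matrix(as.numeric(D), nrow(em), ncol(em))
}

#' Normalize a ratiometric frame to its dim-pixel baseline
#'
#' Divides in-mask intensities by the 5th percentile (nearest-rank rule,
#' floor rounding) of the in-mask values, so the dimmest 5% of the cell maps
#' to at most 1. Out-of-mask pixels are untouched. Since the detection
#' criteria are relative to the cell mean, normalization does not change
#' which foci are detected; it standardizes the display scale.
#'
#' @param frame A [ratiometric_frame()].
#' @param prob Percentile used as the baseline. Default 0.05.
#' @return A normalized [ratiometric_frame()].
#' @export
normalize_frame <- function(frame, prob = 0.05) {
  stopifnot(inherits(frame, "ratiometric_frame"))
  v <- frame$intensities[frame$mask]
  k <- max(1L, floor(prob * length(v)))
  p <- sort(v)[k]
  if (p <= 0) {
    stop("baseline percentile of in-mask intensities is not positive",
         call. = FALSE)
  }
  out <- frame
  out$intensities[frame$mask] <- frame$intensities[frame$mask] / p
  out
}

#' Detect high-activity foci in a ratiometric frame
#'
#' Thresholds in-mask pixels at `(1 + intensity_excess)` times the in-mask
#' mean intensity, labels connected components at the configured
#' connectivity, and keeps regions strictly larger than `min_area_px` whose
#' minimum Euclidean distance to the cell edge is at most `edge_dist_px`.
#' All three criteria are relative or geometric, so detection is invariant
#' to rescaling all in-mask intensities by a positive constant.
#'
#' @param frame A [ratiometric_frame()].
#' @param cfg A [foci_config()].
#' @return An object of class `foci_result`: list with `n_foci`, `regions`
#'   (per focus: `pixels` linear indices, `area`, `centroid`,
#'   `min_edge_dist`), and `labels` (matrix labeling accepted foci 1..n).
#' @examples
#' fr <- make_foci_frames(list(list(cx = 100, cy = 30, side = 12,
#'                                  intensity = 2)), seed = 1)$frames[[1]]
#' detect_foci(fr)$n_foci
#' @export
detect_foci <- function(frame, cfg = foci_config()) {
  stopifnot(inherits(frame, "ratiometric_frame"), inherits(cfg, "foci_config"))
  v <- frame$intensities
  mask <- frame$mask
  thr <- (1 + cfg$intensity_excess) * mean(v[mask])
  bw <- mask & (v > thr)
  lab <- label_components(bw, cfg$connectivity)
  D <- edge_distance(mask)
  regions <- list()
  nlab <- max(lab)
  for (l in seq_len(nlab)) {
    pix <- which(lab == l)
    if (length(pix) <= cfg$min_area_px) next
    dmin <- min(D[pix])
    if (dmin > cfg$edge_dist_px) next
    ij <- arrayInd(pix, dim(v))
    regions[[length(regions) + 1L]] <-
      list(pixels = pix, area = length(pix),
           centroid = c(row = mean(ij[, 1]), col = mean(ij[, 2])),
           min_edge_dist = dmin)
  }
  labels <- matrix(0L, nrow(v), ncol(v))
  for (i in seq_along(regions)) labels[regions[[i]]$pixels] <- i
  structure(list(n_foci = length(regions), regions = regions,
                 labels = labels),
            class = "foci_result")
}

#' @export
print.foci_result <- function(x, ...) {
  cat(sprintf("<foci_result> %d focus/foci\n", x$n_foci))
  invisible(x)
}

#' Frame count maximizing total analyzed frames
#'
#' Cells are followed for varying numbers of frames; analyzing `n` frames
#' per cell uses only cells with at least `n` frames. Returns the `n`
#' maximizing `n * m`, where `m` is the number of cells with at least `n`
#' frames; ties are broken toward the larger `n`.
#'
#' @param track_lengths Positive integer vector of per-cell frame counts.
#' @return The selected frame count.
#' @examples
#' select_frame_count(c(10, 8, 5))  # 8 x 2 beats 10 x 1 and 5 x 3
#' @export
select_frame_count <- function(track_lengths) {
  if (!length(track_lengths) || any(track_lengths < 1)) {
    stop("`track_lengths` must be a non-empty vector of positive counts",
         call. = FALSE)
  }
  cand <- sort(unique(as.integer(track_lengths)))
  score <- vapply(cand, function(n) n * sum(track_lengths >= n), numeric(1))
  max(cand[score == max(score)])
}

#' Group per-frame foci counts by predicted migration state
#'
#' @param foci_counts Integer vector of per-frame foci counts.
#' @param state_assignments Aligned vector of per-frame state labels.
#' @return List with `by_state` (named list of count vectors) and `summary`
#'   (data frame with per-state `n_frames`, `mean`, `median`).
#' @export
foci_by_state <- function(foci_counts, state_assignments) {
  if (length(foci_counts) != length(state_assignments)) {
    stop("`foci_counts` and `state_assignments` must be aligned and equal length",
         call. = FALSE)
  }
  by_state <- split(foci_counts, state_assignments)
  summary <- data.frame(
    state = names(by_state),
    n_frames = vapply(by_state, length, integer(1)),
    mean = vapply(by_state, mean, numeric(1)),
    median = vapply(by_state, stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(by_state = by_state, summary = summary)
}
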