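#' Two-state fibroblast-like mixture model
#'
#' The default parameter set emulates the wild-type fibroblast fit used
#' throughout validation: a persistent state with a well-defined
#' characteristic step (`mu_r = 3.2` um, `sigma_theta = 0.7`) occupied 12%
#' of the time, and a meandering state with highly variable step size
#' (`mu_r = 0`, `sigma_theta = 1.3`) occupied the remaining 88%. The step
#' dispersions (`sigma_r1 = 1.0`, `sigma_r2 = 2.0`) are package defaults for
#' quantities that have no single established value; see the methods
#' vignette.
#'
#' @param dt Sampling interval. Default 1.
#' @return A two-state [mixture_model()].
#' @export
mef_like_model <- function(dt = 1) {
  mixture_model(
    list(state_params(3.2, 1.0, 0.7, label = "persistent"),
         state_params(0.0, 2.0, 1.3, label = "meandering")),
    alphas = c(0.12, 0.88), dt = dt
  )
}

simulate_cohort <- function(model, n_tracks, n_steps, seed, prefix) {
  with_seed(seed, function() {
    tracks <- lapply(seq_len(n_tracks), function(i) {
      simulate_track(model, n_steps,
                     start_angle = stats::runif(1, -pi, pi),
                     cell_id = sprintf("%s%03d", prefix, i))
    })
    tracks
  })
}

#' Fibroblast-like two-state synthetic tracks
#'
#' Deterministic generator of two-state tracks from [mef_like_model()],
#' with ground-truth state labels retained. Same seed, same output.
#'
#' @param n_tracks Number of tracks (default 50).
#' @param n_steps Steps per track (default 100).
#' @param seed Integer seed (default 1).
#' @param model Generating model; default [mef_like_model()].
#' @return List with `model`, `tracks` (list of [cell_track()]), `steps`
#'   (pooled `step_data` with `true_state`), and `spec` (echo of the
#'   generating settings).
#' @examples
#' fx <- make_mef_like(n_tracks = 5, n_steps = 50, seed = 7)
#' persistence(fx$steps)
#' @export
make_mef_like <- function(n_tracks = 50L, n_steps = 100L, seed = 1L,
                          model = mef_like_model()) {
  tracks <- simulate_cohort(model, n_tracks, n_steps, seed, "mef")
  list(model = model, tracks = tracks, steps = track_to_steps(tracks),
       spec = list(scenario = "mef_like", n_tracks = n_tracks,
                   n_steps = n_steps, seed = seed))
}

#' Single-state synthetic tracks
#'
#' Deterministic generator of one-state tracks (an epithelial-like cell
#' line showing a single mode of migration).
#'
#' @param state Generating [state_params()]; default a moderately
#'   persistent state `state_params(2.5, 1, 0.5)`.
#' @inheritParams make_mef_like
#' @param dt Sampling interval.
#' @return As [make_mef_like()].
#' @export
make_one_state <- function(state = state_params(2.5, 1, 0.5, "single"),
                           n_tracks = 50L, n_steps = 100L, seed = 1L,
                           dt = 1) {
  model <- mixture_model(state, dt = dt)
  tracks <- simulate_cohort(model, n_tracks, n_steps, seed, "one")
  list(model = model, tracks = tracks, steps = track_to_steps(tracks),
       spec = list(scenario = "one_state", n_tracks = n_tracks,
                   n_steps = n_steps, seed = seed))
}

disk_mask <- function(nrow_px = 200L, ncol_px = 200L,
                      center = c(nrow_px / 2 + 0.5, ncol_px / 2 + 0.5),
                      radius = min(nrow_px, ncol_px) / 2 - 5) {
  ij <- expand.grid(i = seq_len(nrow_px), j = seq_len(ncol_px))
  m <- matrix((ij$i - center[1])^2 + (ij$j - center[2])^2 <= radius^2,
              nrow_px, ncol_px)
  m
}

#' Synthetic ratiometric frames with known foci ground truth
#'
#' Builds disk-masked frames with constant background intensity and
#' injected flat-top blobs (squares or discs) of specified size, intensity
#' and position, then records for each blob whether it satisfies each of
#' the three detection criteria under `cfg` (by brute-force measurement on
#' the constructed image). Optional Gaussian pixel noise.
#'
#' @param blobs List of blob specs: each a list with `cx`, `cy` (center,
#'   pixels; rows = y), `intensity`, and either `side` (square) or `radius`
#'   (disc).
#' @param nrow_px,ncol_px Image size. Default 200 x 200.
#' @param mask_radius Disk mask radius (pixels).
#' @param background In-mask background intensity. Default 1.
#' @param noise_sd Gaussian pixel noise standard deviation. Default 0.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param cfg [foci_config()] used to evaluate the ground truth.
#' @return List with `frames` (length-1 list of [ratiometric_frame()]) and
#'   `truth` (data frame: per blob `area_px`, `min_edge_dist`,
#'   `intensity_ratio`, `meets_intensity`, `meets_area`, `meets_edge`,
#'   `qualifies`).
#' @export
make_foci_frames <- function(blobs, nrow_px = 200L, ncol_px = 200L,
                             mask_radius = min(nrow_px, ncol_px) / 2 - 5,
                             background = 1, noise_sd = 0, seed = 1L,
                             cfg = foci_config()) {
  mask <- disk_mask(nrow_px, ncol_px, radius = mask_radius)
  v <- matrix(0, nrow_px, ncol_px)
  v[mask] <- background
  blob_pix <- vector("list", length(blobs))
  for (b in seq_along(blobs)) {
    bl <- blobs[[b]]
    if (!is.null(bl$side)) {
      i0 <- ceiling(bl$cy - bl$side / 2)
      j0 <- ceiling(bl$cx - bl$side / 2)
      ii <- i0:(i0 + bl$side - 1L)      # exactly `side` rows/cols
      jj <- j0:(j0 + bl$side - 1L)
      pix <- as.matrix(expand.grid(i = ii, j = jj))
    } else if (!is.null(bl$radius)) {
      ij <- expand.grid(i = seq_len(nrow_px), j = seq_len(ncol_px))
      keep <- (ij$i - bl$cy)^2 + (ij$j - bl$cx)^2 <= bl$radius^2
      pix <- as.matrix(ij[keep, ])
    } else {
      stop("each blob needs `side` or `radius`", call. = FALSE)
    }
    inside <- pix[, 1] >= 1 & pix[, 1] <= nrow_px &
      pix[, 2] >= 1 & pix[, 2] <= ncol_px
    pix <- pix[inside, , drop = FALSE]
    lin <- pix[, 1] + (pix[, 2] - 1L) * nrow_px
    lin <- lin[mask[lin]]
    if (!length(lin)) stop("blob lies entirely outside the mask", call. = FALSE)
    v[lin] <- bl$intensity
    blob_pix[[b]] <- lin
  }
  if (noise_sd > 0) {
    v[mask] <- pmax(0, v[mask] +
                      with_seed(seed, function() {
                        stats::rnorm(sum(mask), 0, noise_sd)
                      }))
  }
  frame <- ratiometric_frame(v, mask)
  D <- edge_distance(mask)
  cell_mean <- mean(v[mask])
  truth <- do.call(rbind, lapply(seq_along(blobs), function(b) {
    lin <- blob_pix[[b]]
    ratio <- mean(v[lin]) / cell_mean
    data.frame(
      blob = b,
      area_px = length(lin),
      min_edge_dist = min(D[lin]),
      intensity_ratio = ratio,
      meets_intensity = ratio > 1 + cfg$intensity_excess,
      meets_area = length(lin) > cfg$min_area_px,
      meets_edge = min(D[lin]) <= cfg$edge_dist_px
    )
  }))
  if (!is.null(truth)) {
    truth$qualifies <- truth$meets_intensity & truth$meets_area &
      truth$meets_edge
  } else {
    truth <- data.frame(blob = integer(0))
  }
  list(frames = list(frame), truth = truth)
}
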