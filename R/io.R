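# Readers and writers for the pipeline's file formats: tracks/steps/states
# as CSV (comma-separated, UTF-8, '.' decimal, mandatory header; coordinates
# in um, times in minutes), models/fits as JSON or YAML.

SCHEMA_VERSION <- "1.0"

#' Write and read cell tracks as CSV
#'
#' Columns: `cell_id,frame,time_min,x_um,y_um[,true_state]`, one row per
#' observation, frames 0-based.
#'
#' @param tracks A [cell_track()] or list of them.
#' @param path Output file.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` returns a
#'   list of [cell_track()].
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  dfs <- lapply(tracks, function(tr) {
    df <- data.frame(cell_id = tr$cell_id,
                     frame = seq_along(tr$times) - 1L,
                     time_min = tr$times, x_um = tr$xs, y_um = tr$ys,
                     stringsAsFactors = FALSE)
    if (!is.null(tr$true_states)) df$true_state <- c(tr$true_states, NA)
    df
  })
  has_truth <- vapply(dfs, function(d) "true_state" %in% names(d), TRUE)
  if (any(has_truth) && !all(has_truth)) {
    dfs <- lapply(dfs, function(d) {
      if (!"true_state" %in% names(d)) d$true_state <- NA_integer_
      d
    })
  }
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "time_min", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed tracks CSV `%s`: need columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    ts <- NULL
    if ("true_state" %in% names(d)) {
      ts <- d$true_state[-nrow(d)]
      if (all(is.na(ts))) ts <- NULL
    }
    cell_track(d$cell_id[1], d$time_min, d$x_um, d$y_um, true_states = ts)
  })
}

#' Write and read step datasets as CSV
#'
#' Columns: `cell_id,step_index,dx_par_um,dy_perp_um,turn_angle_rad`
#' (plus `true_state` when present).
#'
#' @param steps A `step_data` data frame.
#' @param path File path.
#' @export
write_steps <- function(steps, path) {
  df <- data.frame(cell_id = steps$cell_id, step_index = steps$step_index,
                   dx_par_um = steps$dx_par, dy_perp_um = steps$dy_perp,
                   turn_angle_rad = steps$turn_angle,
                   stringsAsFactors = FALSE)
  if (!is.null(steps$true_state)) df$true_state <- steps$true_state
  df$dt <- attr(steps, "dt") %||% 1
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "step_index", "dx_par_um", "dy_perp_um",
            "turn_angle_rad")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed steps CSV `%s`: need columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  out <- data.frame(cell_id = df$cell_id, step_index = df$step_index,
                    dx_par = df$dx_par_um, dy_perp = df$dy_perp_um,
                    turn_angle = df$turn_angle_rad, stringsAsFactors = FALSE)
  if ("true_state" %in% names(df)) out$true_state <- df$true_state
  attr(out, "dt") <- if ("dt" %in% names(df)) df$dt[1] else 1
  attr(out, "n_skipped") <- 0L
  class(out) <- c("step_data", "data.frame")
  out
}

model_to_list <- function(model) {
  list(states = lapply(model$states, function(s) {
    list(mu_r = s$mu_r, sigma_r = s$sigma_r, sigma_theta = s$sigma_theta,
         label = s$label)
  }), alphas = model$alphas, dt = model$dt)
}

model_from_list <- function(x) {
  states <- lapply(x$states, function(s) {
    state_params(s$mu_r, s$sigma_r, s$sigma_theta, label = s$label)
  })
  mixture_model(states, unlist(x$alphas), dt = x$dt %||% 1)
}

#' Write and read a mixture model as YAML
#'
#' @param model A [mixture_model()].
#' @param path File path.
#' @export
write_model_yaml <- function(model, path) {
  yaml::write_yaml(model_to_list(model), path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("malformed model YAML `%s`: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  model_from_list(x)
}

#' Write and read a fit result as JSON
#'
#' The JSON carries a `schema_version`, the fitted model, its SSE, and an
#' echo of the seed/configuration used, so a fit is reproducible from its
#' output alone.
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @param seed,config Optional seed and configuration echo to record.
#' @export
write_fit_json <- function(fit, path, seed = NULL, config = NULL) {
  x <- list(schema_version = SCHEMA_VERSION,
            n_states = fit$n_states, sse = fit$sse,
            model = model_to_list(fit$model),
            restart_id = fit$restart_id,
            refined = isTRUE(fit$refined),
            seed = seed, config = config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path), error = function(e) {
    stop(sprintf("malformed fit JSON `%s`: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  structure(list(model = model_from_list(x$model), sse = x$sse,
                 n_states = x$n_states, trace = NULL,
                 restart_id = x$restart_id, refined = isTRUE(x$refined)),
            class = "fit_result")
}
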