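#' Parameters of a single migration state
#'
#' A migration state is characterized by three parameters: the mean signed
#' step magnitude `mu_r` (um per sampling interval), the step-magnitude
#' dispersion `sigma_r`, and the turning-angle dispersion `sigma_theta`.
#' Over a sampling interval `dt` the signed step magnitude is
#' Normal(`mu_r`, `sigma_r^2 * dt`) and the turning-angle increment about the
#' previous direction of motion is Normal(0, `sigma_theta^2 * dt`), so with
#' the default `dt = 1` convention the parameters are per-interval values.
#' Negative step magnitudes are allowed: the cell keeps its orientation but
#' its centroid moves rearward.
#'
#' @param mu_r Mean signed step magnitude (um per interval).
#' @param sigma_r Step-magnitude dispersion (um per square-root interval); > 0.
#' @param sigma_theta Turning-angle dispersion (rad per square-root
#'   interval); > 0. Small values give persistent, nearly straight motion;
#'   large values make the direction uniform and the walk diffusive.
#' @param label Optional state name.
#' @return An object of class `state_params`.
#' @examples
#' state_params(3.2, 1, 0.7, label = "persistent")
#' @export
state_params <- function(mu_r, sigma_r, sigma_theta, label = NULL) {
  stop_if_not_scalar_num(mu_r, "mu_r")
  stop_if_not_scalar_num(sigma_r, "sigma_r", positive = TRUE)
  stop_if_not_scalar_num(sigma_theta, "sigma_theta", positive = TRUE)
  structure(
    list(mu_r = mu_r, sigma_r = sigma_r, sigma_theta = sigma_theta,
         label = label),
    class = "state_params"
  )
}

#' @export
print.state_params <- function(x, ...) {
  cat(sprintf("<state_params%s> mu_r = %g, sigma_r = %g, sigma_theta = %g\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$mu_r, x$sigma_r, x$sigma_theta))
  invisible(x)
}

#' Mixture model of migration states
#'
#' A cell occupies one of `n` migration states at each step; states are drawn
#' independently per step with occupancy probabilities `alphas` (an i.i.d.
#' mixture, the reduced form of a hidden Markov model with i.i.d.
#' transitions). `alphas` must sum to 1.
#'
#' @param states A `state_params` object or list of them (n >= 1), ordered;
#'   by convention state 1 is listed first.
#' @param alphas Occupancy fractions, one per state, each in \[0, 1\],
#'   summing to 1 (within 1e-12). Defaults to equal occupancy.
#' @param dt Sampling interval (time units per step). Default 1, in which
#'   case state parameters are per-interval values.
#' @return An object of class `mixture_model`.
#' @examples
#' m <- mixture_model(list(state_params(3.2, 1, 0.7), state_params(0, 2, 1.3)),
#'                    alphas = c(0.12, 0.88))
#' @export
mixture_model <- function(states, alphas = NULL, dt = 1) {
  if (inherits(states, "state_params")) states <- list(states)
  if (!length(states) || !all(vapply(states, inherits, TRUE, "state_params"))) {
    stop("`states` must be a non-empty list of state_params", call. = FALSE)
  }
  n <- length(states)
  if (is.null(alphas)) alphas <- rep(1 / n, n)
  if (length(alphas) != n || any(!is.finite(alphas)) ||
      any(alphas < 0) || any(alphas > 1)) {
    stop("`alphas` must be probabilities in [0,1], one per state",
         call. = FALSE)
  }
  if (abs(sum(alphas) - 1) > 1e-12) {
    stop("`alphas` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  structure(list(states = states, alphas = as.numeric(alphas), dt = dt),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> %d state(s), dt = %g\n", length(x$states), x$dt))
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat(sprintf("  state %d (alpha = %.4g): mu_r = %g, sigma_r = %g, sigma_theta = %g%s\n",
                i, x$alphas[i], s$mu_r, s$sigma_r, s$sigma_theta,
                if (is.null(s$label)) "" else paste0("  [", s$label, "]")))
  }
  invisible(x)
}

n_states <- function(model) length(model$states)

state_field <- function(model, field) {
  vapply(model$states, `[[`, numeric(1), field)
}

#' Time-ordered centroid track of one cell
#'
#' @param cell_id Identifier.
#' @param times Strictly increasing time stamps (minutes).
#' @param xs,ys Centroid coordinates (um); same length as `times`, >= 2
#'   points.
#' @param true_states Optional per-step ground-truth state indices (length
#'   `length(times) - 1`); retained by the simulator.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(cell_id, times, xs, ys, true_states = NULL) {
  m <- length(times)
  if (m < 2L || length(xs) != m || length(ys) != m) {
    stop("`times`, `xs`, `ys` must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(xs)) || any(!is.finite(ys))) {
    stop("track coordinates and times must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(true_states) && length(true_states) != m - 1L) {
    stop("`true_states` must have length(times) - 1 entries", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, times = as.numeric(times), xs = as.numeric(xs),
         ys = as.numeric(ys),
         true_states = if (is.null(true_states)) NULL else as.integer(true_states)),
    class = "cell_track"
  )
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track %s> %d points over [%g, %g] min%s\n",
              x$cell_id, length(x$times), x$times[1],
              x$times[length(x$times)],
              if (is.null(x$true_states)) "" else " (with true states)"))
  invisible(x)
}

# Uniform sampling interval of a track; error when non-uniform (model
# fitting assumes fixed-interval sampling).
track_dt <- function(track, tol = 1e-8) {
  d <- diff(track$times)
  if (diff(range(d)) > tol * max(d)) {
    stop(sprintf("track %s is not uniformly sampled; model fitting requires a fixed interval",
                 track$cell_id), call. = FALSE)
  }
  mean(d)
}

#' Draw migration states from a mixture model
#'
#' States are drawn independently per call with probabilities given by the
#' model's occupancy fractions.
#'
#' @param model A [mixture_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   untouched.
#' @return Integer vector of state indices in `1:n_states`.
#' @export
sample_state <- function(model, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  with_seed(seed, function() {
    sample.int(n_states(model), size = n, replace = TRUE, prob = model$alphas)
  })
}

#' Simulate a persistent-random-walk cell track
#'
#' At each step a state is drawn from the mixture occupancies, a signed step
#' magnitude `r ~ N(mu_r, sigma_r^2 dt)` and a turning increment
#' `eta ~ N(0, sigma_theta^2 dt)` are drawn, the direction of motion is
#' advanced by `eta` relative to the previous step's displacement direction,
#' and the centroid moves by `r * (cos theta, sin theta)`. Directions are
#' carried unwrapped on the real line. A negative `r` moves the centroid
#' rearward; the next turning increment is referenced to the realized
#' displacement direction, which keeps simulated tracks exactly consistent
#' with the analytic step densities evaluated in the displacement frame (see
#' the methods vignette).
#'
#' @param model A [mixture_model()].
#' @param n_steps Number of steps (>= 1); the track has `n_steps + 1` points.
#' @param start Starting position `c(x, y)` in um.
#' @param start_angle Initial direction of motion (rad).
#' @param seed Optional integer seed.
#' @param cell_id Identifier for the generated track.
#' @param t0 Time of the first point (minutes).
#' @return A [cell_track()] with `true_states` filled in. The attribute
#'   `"draws"` records the drawn signed magnitudes and turning increments
#'   (used by round-trip tests).
#' @examples
#' m <- mixture_model(state_params(1, 0.5, 0.3))
#' tr <- simulate_track(m, 50, seed = 1)
#' @export
simulate_track <- function(model, n_steps, start = c(0, 0), start_angle = 0,
                           seed = NULL, cell_id = "sim1", t0 = 0) {
  stopifnot(inherits(model, "mixture_model"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("`n_steps` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_steps)
  dt <- model$dt
  mu <- state_field(model, "mu_r")
  sr <- state_field(model, "sigma_r")
  sth <- state_field(model, "sigma_theta")
  with_seed(seed, function() {
    st <- sample.int(n_states(model), n, replace = TRUE, prob = model$alphas)
    r <- stats::rnorm(n, mu[st], sr[st] * sqrt(dt))
    eta <- stats::rnorm(n, 0, sth[st] * sqrt(dt))
    # direction of step i: previous displacement direction + eta_i;
    # a negative r flips the realized displacement direction by pi.
    flip <- cumsum(c(0, (r < 0)[-n])) * pi
    theta <- start_angle + cumsum(eta) + flip
    xs <- start[1] + c(0, cumsum(r * cos(theta)))
    ys <- start[2] + c(0, cumsum(r * sin(theta)))
    tr <- cell_track(cell_id, t0 + dt * (0:n), xs, ys, true_states = st)
    attr(tr, "draws") <- data.frame(state = st, r = r, turn = eta)
    tr
  })
}
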