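#' Evaluation settings for the analytic step densities
#'
#' The parallel and perpendicular step densities are integrals over the
#' turning angle of a Gaussian magnitude density divided by |cos(angle)|,
#' weighted by a wrapped-Gaussian angle density. They are evaluated by
#' Gauss-Legendre quadrature after the substitution h = cos(u), which
#' cancels the (1 - h^2)^(-1/2) endpoint singularity of the h-form of the
#' integral.
#'
#' @param k_max Truncation of the 2*pi*k wrap summation. `NULL` (default)
#'   selects `ceiling(6 * sigma_theta * sqrt(dt) / (2*pi)) + 1` per state, so
#'   the neglected wrapped tail mass is below 1e-8.
#' @param n_quad Number of quadrature nodes (even; default 400).
#' @param rel_tol Normalization tolerance used by
#'   [check_pdf_normalization()]. Default 1e-6.
#' @param zero_width Bin width (um) used to return a bin-averaged value at
#'   exactly x = 0, where the pointwise density has an integrable
#'   logarithmic singularity whenever the magnitude density is positive at 0.
#' @return An object of class `pdf_eval_config`.
#' @export
pdf_eval_config <- function(k_max = NULL, n_quad = 400L, rel_tol = 1e-6,
                            zero_width = 1e-2) {
  if (!is.null(k_max)) {
    stopifnot(is.numeric(k_max), length(k_max) == 1L, k_max >= 1)
    k_max <- as.integer(k_max)
  }
  stopifnot(is.numeric(n_quad), length(n_quad) == 1L, n_quad >= 8)
  n_quad <- as.integer(n_quad)
  if (n_quad %% 2L == 1L) n_quad <- n_quad + 1L  # keep nodes off cos(u) = 0
  stop_if_not_scalar_num(rel_tol, "rel_tol", positive = TRUE)
  stop_if_not_scalar_num(zero_width, "zero_width", positive = TRUE)
  structure(list(k_max = k_max, n_quad = n_quad, rel_tol = rel_tol,
                 zero_width = zero_width),
            class = "pdf_eval_config")
}

k_wrap <- function(sigma_eff, cfg) {
  cfg$k_max %||% (ceiling(6 * sigma_eff / (2 * pi)) + 1L)
}

# Beyond this dispersion the wrapped normal is uniform to < 1e-14
# (deviation 2 * exp(-s^2 / 2)), so the closed-form limit is used and the
# wrap summation stays short for any proposal the optimizer visits.
UNIFORM_ANGLE_S <- 8

# Angle-density factor of the parallel integrand at u in (0, pi):
# w(u) + w(-u) where w is the wrapped Normal(0, s^2) density; equals
# 2 * sum_k g(u + 2*pi*k) by evenness of g.
wrap_term_par <- function(u, s, K) {
  if (s >= UNIFORM_ANGLE_S) return(rep(1 / pi, length(u)))
  tot <- 0
  for (k in -K:K) tot <- tot + stats::dnorm(u + 2 * pi * k, 0, s)
  2 * tot
}

# Perpendicular counterpart: w(u + pi/2) + w(-u + pi/2).
wrap_term_perp <- function(u, s, K) {
  if (s >= UNIFORM_ANGLE_S) return(rep(1 / pi, length(u)))
  tot <- 0
  for (k in -K:K) {
    tot <- tot + stats::dnorm(u + pi / 2 + 2 * pi * k, 0, s) +
      stats::dnorm(u - pi / 2 + 2 * pi * k, 0, s)
  }
  tot
}

# Integration interval in u: the angle factor carries essentially all of its
# mass within +-12 s of its center (0 for parallel, pi/2 for perpendicular);
# restricting the Gauss-Legendre rule to that window resolves arbitrarily
# small sigma_theta, which a fixed rule on (0, pi) cannot.
u_interval <- function(component, s) {
  half <- 12 * s
  if (component == "par") {
    c(0, min(pi, half))
  } else {
    c(max(0, pi / 2 - half), min(pi, pi / 2 + half))
  }
}

# Quadrature nodes (u), cos(u), and combined weights (angle term * GL
# weight) for one state/component. The integrand develops a boundary layer
# where cos(u) crosses 0 (normal CDF arguments x/cos(u) sweep through
# +-Inf), so when the interval straddles pi/2 the rule is split there into
# two panels: Gauss-Legendre nodes cluster at panel ends and resolve the
# layer.
quad_setup <- function(state, dt, cfg, component) {
  s <- state$sigma_theta * sqrt(dt)
  K <- k_wrap(s, cfg)
  ab <- u_interval(component, s)
  if (ab[1] < pi / 2 && ab[2] > pi / 2) {
    n1 <- cfg$n_quad %/% 2L
    g1 <- gl_on(n1, ab[1], pi / 2)
    g2 <- gl_on(cfg$n_quad - n1, pi / 2, ab[2])
    g <- list(x = c(g1$x, g2$x), w = c(g1$w, g2$w))
  } else {
    g <- gl_on(cfg$n_quad, ab[1], ab[2])
  }
  term <- if (component == "par") wrap_term_par(g$x, s, K)
          else wrap_term_perp(g$x, s, K)
  list(u = g$x, cu = cos(g$x), W = term * g$w,
       mu = state$mu_r, s_r = state$sigma_r * sqrt(dt))
}

# Pointwise density at x != 0: sum_j W_j * g_r(x / c_j) / |c_j|.
pdf_pointwise_engine <- function(x, q) {
  out <- numeric(length(x))
  nz <- x != 0
  if (any(nz)) {
    ratio <- outer(x[nz], q$cu, "/")
    dens <- stats::dnorm(ratio, q$mu, q$s_r)
    out[nz] <- as.vector(dens %*% (q$W / abs(q$cu)))
  }
  if (any(!nz)) {
    # integrable log singularity at 0: report the bin-averaged value
    zw <- attr(q, "zero_width")
    out[!nz] <- pdf_binned_engine(c(-zw / 2, zw / 2), q)
  }
  out
}

# Exact per-bin averages: (1/width) * sum_j W_j * |G(b/c_j) - G(a/c_j)|
# with G the Normal(mu, s_r^2) CDF. Smooth in x, no singularity at 0.
pdf_binned_engine <- function(edges, q) {
  p <- stats::pnorm(outer(edges, q$cu, "/"), q$mu, q$s_r)
  nb <- length(edges) - 1L
  d <- abs(p[-1L, , drop = FALSE] - p[-(nb + 1L), , drop = FALSE])
  as.vector(d %*% q$W) / diff(edges)
}

state_quad <- function(state, dt, cfg, component) {
  stopifnot(inherits(state, "state_params"), inherits(cfg, "pdf_eval_config"))
  q <- quad_setup(state, dt, cfg, component)
  attr(q, "zero_width") <- cfg$zero_width
  q
}

#' Analytic density of the parallel step component
#'
#' Probability density (per um) of the displacement component parallel to
#' the previous step, for a single migration state. At exactly `x = 0`,
#' where the density has an integrable logarithmic singularity, the value
#' averaged over a bin of width `cfg$zero_width` is returned.
#'
#' @param x Evaluation points (um); vectorized.
#' @param state A [state_params()].
#' @param dt Sampling interval. Default 1.
#' @param cfg A [pdf_eval_config()].
#' @return Densities, same length as `x`.
#' @examples
#' pdf_parallel(c(1, 3, 5), state_params(3, 1, 0.7))
#' @export
pdf_parallel <- function(x, state, dt = 1, cfg = pdf_eval_config()) {
  pdf_pointwise_engine(x, state_quad(state, dt, cfg, "par"))
}

#' Analytic density of the perpendicular step component
#'
#' Probability density (per um) of the displacement component perpendicular
#' to the previous step. Symmetric about zero by construction.
#'
#' @inheritParams pdf_parallel
#' @param y Evaluation points (um); vectorized.
#' @export
pdf_perpendicular <- function(y, state, dt = 1, cfg = pdf_eval_config()) {
  q <- state_quad(state, dt, cfg, "perp")
  # evaluate on |y| so f(y) = f(-y) holds to machine precision
  pdf_pointwise_engine(abs(y), q)
}

#' Bin-averaged analytic densities
#'
#' Average of the analytic density over each bin (integral over the bin
#' divided by its width), computed exactly under the quadrature rule via
#' normal CDF differences. This is the quantity compared against empirical
#' histogram densities in the fitting objective; it is finite and smooth
#' even across a bin containing 0.
#'
#' @inheritParams pdf_parallel
#' @param edges Increasing bin edges (length >= 2).
#' @return Vector of `length(edges) - 1` bin-averaged densities.
#' @export
pdf_parallel_binned <- function(edges, state, dt = 1, cfg = pdf_eval_config()) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  pdf_binned_engine(edges, state_quad(state, dt, cfg, "par"))
}

#' @rdname pdf_parallel_binned
#' @export
pdf_perpendicular_binned <- function(edges, state, dt = 1,
                                     cfg = pdf_eval_config()) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  pdf_binned_engine(edges, state_quad(state, dt, cfg, "perp"))
}

mixture_engine <- function(f, x, model, cfg) {
  out <- 0
  for (i in seq_along(model$states)) {
    if (model$alphas[i] > 0) {
      out <- out + model$alphas[i] * f(x, model$states[[i]], model$dt, cfg)
    }
  }
  out
}

#' Mixture densities over migration states
#'
#' Convex combination `sum_i alpha_i f_i` of the per-state analytic
#' densities.
#'
#' @param x Evaluation points (um) or, for the `_binned` forms, bin edges.
#' @param model A [mixture_model()]; its `dt` is used.
#' @param cfg A [pdf_eval_config()].
#' @export
mixture_pdf_parallel <- function(x, model, cfg = pdf_eval_config()) {
  stopifnot(inherits(model, "mixture_model"))
  mixture_engine(pdf_parallel, x, model, cfg)
}

#' @rdname mixture_pdf_parallel
#' @export
mixture_pdf_perpendicular <- function(x, model, cfg = pdf_eval_config()) {
  stopifnot(inherits(model, "mixture_model"))
  mixture_engine(pdf_perpendicular, x, model, cfg)
}

#' @rdname mixture_pdf_parallel
#' @export
mixture_pdf_parallel_binned <- function(x, model, cfg = pdf_eval_config()) {
  stopifnot(inherits(model, "mixture_model"))
  mixture_engine(pdf_parallel_binned, x, model, cfg)
}

#' @rdname mixture_pdf_parallel
#' @export
mixture_pdf_perpendicular_binned <- function(x, model, cfg = pdf_eval_config()) {
  stopifnot(inherits(model, "mixture_model"))
  mixture_engine(pdf_perpendicular_binned, x, model, cfg)
}

#' Normalization self-check of the analytic densities
#'
#' Integrates the density over a wide grid covering the support and returns
#' the absolute deviation from 1; errors if it exceeds `cfg$rel_tol`.
#'
#' @inheritParams pdf_parallel
#' @param component `"par"` or `"perp"`.
#' @param error Whether to error when the check fails (default TRUE).
#' @return The absolute deviation |integral - 1| (invisibly when `error`).
#' @export
check_pdf_normalization <- function(state, dt = 1, cfg = pdf_eval_config(),
                                    component = c("par", "perp"),
                                    error = TRUE) {
  component <- match.arg(component)
  L <- abs(state$mu_r) + 10 * state$sigma_r * sqrt(dt)
  edges <- seq(-L, L, length.out = 2001L)
  f <- if (component == "par") pdf_parallel_binned else pdf_perpendicular_binned
  dev <- abs(sum(f(edges, state, dt, cfg) * diff(edges)) - 1)
  if (error && dev > cfg$rel_tol) {
    stop(sprintf("pdf normalization check failed for %s component: |integral - 1| = %.3g > %.3g",
                 component, dev, cfg$rel_tol), call. = FALSE)
  }
  if (error) invisible(dev) else dev
}

# Log pointwise parallel/perpendicular density, computed in log space so
# extreme displacements (|x| up to 1e6 um) yield -Inf-safe finite structure
# rather than NaN. Used by the Bayesian state classifier.
log_pdf_component <- function(x, state, dt, cfg, component) {
  q <- state_quad(state, dt, cfg, component)
  if (component == "perp") x <- abs(x)
  lw <- log(q$W) - log(abs(q$cu))        # -Inf where W underflows: harmless
  out <- numeric(length(x))
  nz <- x != 0
  if (any(nz)) {
    lm <- stats::dnorm(outer(x[nz], q$cu, "/"), q$mu, q$s_r, log = TRUE)
    lm <- sweep(lm, 2L, lw, "+")
    out[nz] <- row_log_sum_exp(lm)
  }
  if (any(!nz)) {
    zw <- cfg$zero_width
    out[!nz] <- log(pdf_binned_engine(c(-zw / 2, zw / 2), q))
  }
  out
}
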