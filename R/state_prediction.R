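#' Likelihood of a window of steps under one state
#'
#' Product over the window's steps of the analytic parallel-component
#' density (optionally times the perpendicular-component density). Windows
#' must have odd length so they can be centered on the step being
#' classified.
#'
#' @param window Rows of a `step_data` data frame (odd number of rows).
#' @param state A [state_params()].
#' @param dt Sampling interval. Default 1.
#' @param cfg A [pdf_eval_config()].
#' @param use_perpendicular Also multiply in the perpendicular-component
#'   density. Default FALSE (the parallel component is the fitting surface).
#' @return The window likelihood (strictly positive for finite inputs).
#' @export
window_likelihood <- function(window, state, dt = 1, cfg = pdf_eval_config(),
                              use_perpendicular = FALSE) {
  if (!is.data.frame(window) || !nrow(window)) {
    stop("`window` must contain at least one step", call. = FALSE)
  }
  if (nrow(window) %% 2L == 0L) {
    stop("window length must be odd", call. = FALSE)
  }
  ll <- sum(log_pdf_component(window$dx_par, state, dt, cfg, "par"))
  if (use_perpendicular) {
    ll <- ll + sum(log_pdf_component(window$dy_perp, state, dt, cfg, "perp"))
  }
  exp(ll)
}

assign_with_ties <- function(post, alphas) {
  mx <- max(post)
  cand <- which(post >= mx - 1e-12)
  cand[which.max(alphas[cand])]
}

#' Posterior state probabilities for a window of steps
#'
#' Bayes' rule with the mixture occupancies as priors:
#' `P(s_i | X) = P(X | s_i) alpha_i / sum_j P(X | s_j) alpha_j`, computed in
#' log space so long windows and extreme displacements do not underflow.
#' Ties are broken toward the larger-occupancy state.
#'
#' @param window Rows of a `step_data` data frame (odd number of rows).
#' @param model A [mixture_model()]; a one-state model yields posterior 1
#'   trivially.
#' @param cfg A [pdf_eval_config()].
#' @param use_perpendicular See [window_likelihood()].
#' @return An object of class `state_posterior`: list with `posteriors`
#'   (summing to 1), `assigned_state`, and `window_length`.
#' @export
posterior <- function(window, model, cfg = pdf_eval_config(),
                      use_perpendicular = FALSE) {
  stopifnot(inherits(model, "mixture_model"))
  k <- n_states(model)
  if (nrow(window) %% 2L == 0L) stop("window length must be odd", call. = FALSE)
  if (k == 1L) {
    return(structure(list(posteriors = 1, assigned_state = 1L,
                          window_length = nrow(window)),
                     class = "state_posterior"))
  }
  lp <- vapply(seq_len(k), function(i) {
    if (model$alphas[i] == 0) return(-Inf)
    ll <- sum(log_pdf_component(window$dx_par, model$states[[i]], model$dt,
                                cfg, "par"))
    if (use_perpendicular) {
      ll <- ll + sum(log_pdf_component(window$dy_perp, model$states[[i]],
                                       model$dt, cfg, "perp"))
    }
    ll + log(model$alphas[i])
  }, numeric(1))
  m <- max(lp)
  post <- exp(lp - m)
  post <- post / sum(post)
  structure(list(posteriors = post,
                 assigned_state = assign_with_ties(post, model$alphas),
                 window_length = nrow(window)),
            class = "state_posterior")
}

#' Classify every step of a track into a migration state
#'
#' Windowed Bayesian classification: each step is assigned the state with
#' the highest posterior probability given the steps in a centered window of
#' odd length. Near the track ends the window shrinks to the largest
#' centered odd window that fits (at least 1). The posterior of the
#' non-assigned state(s) is reported per step as `p_other`, a
#' false-positive-rate-like quantity.
#'
#' @param track A [cell_track()] (or a precomputed `step_data` data frame).
#' @param model A fitted or known [mixture_model()].
#' @param window_length Odd window length; 1, 3 and 5 are the intended
#'   values (1 typically performs comparably); others trigger a warning.
#' @param cfg A [pdf_eval_config()].
#' @param use_perpendicular See [window_likelihood()].
#' @return A data frame of class `state_classification` with columns
#'   `cell_id`, `step_index`, one `p_state<i>` column per state,
#'   `assigned_state`, `p_other`, `window_used`, plus `true_state` when the
#'   input carries ground truth.
#' @examples
#' m <- mef_like_model()
#' tr <- simulate_track(m, 200, seed = 1)
#' head(classify_track(tr, m, window_length = 1))
#' @export
classify_track <- function(track, model, window_length = 1L,
                           cfg = pdf_eval_config(),
                           use_perpendicular = FALSE) {
  stopifnot(inherits(model, "mixture_model"))
  wl <- as.integer(window_length)
  if (wl < 1L || wl %% 2L == 0L) {
    stop("`window_length` must be a positive odd integer", call. = FALSE)
  }
  if (!wl %in% c(1L, 3L, 5L)) {
    warning("window lengths 1, 3 and 5 are the intended values")
  }
  steps <- if (inherits(track, "cell_track")) track_to_steps(track) else track
  n <- nrow(steps)
  if (!n) stop("track too short to classify any step", call. = FALSE)
  cells <- unique(steps$cell_id)
  if (length(cells) > 1L) {
    # windows never cross track boundaries
    out <- lapply(cells, function(cid) {
      classify_track(steps[steps$cell_id == cid, , drop = FALSE], model, wl,
                     cfg, use_perpendicular)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out)
  }
  k <- n_states(model)
  dt <- model$dt
  logf <- matrix(0, n, k)
  for (i in seq_len(k)) {
    logf[, i] <- log_pdf_component(steps$dx_par, model$states[[i]], dt, cfg,
                                   "par")
    if (use_perpendicular) {
      logf[, i] <- logf[, i] +
        log_pdf_component(steps$dy_perp, model$states[[i]], dt, cfg, "perp")
    }
  }
  half <- (wl - 1L) %/% 2L
  cs <- rbind(0, apply(logf, 2L, cumsum))
  idx <- seq_len(n)
  w_used <- pmin(idx - 1L, n - idx, half)   # shrunk centered half-width
  lo <- idx - w_used
  hi <- idx + w_used
  lp <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  lp <- sweep(lp, 2L, log(pmax(model$alphas, .Machine$double.xmin)), "+")
  lp[, model$alphas == 0] <- -Inf
  m <- apply(lp, 1L, max)
  post <- exp(lp - m)
  post <- post / rowSums(post)
  assigned <- vapply(seq_len(n), function(i) {
    assign_with_ties(post[i, ], model$alphas)
  }, integer(1))
  out <- data.frame(cell_id = steps$cell_id, step_index = steps$step_index,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) out[[paste0("p_state", i)]] <- post[, i]
  out$assigned_state <- assigned
  out$p_other <- 1 - post[cbind(seq_len(n), assigned)]
  out$window_used <- 2L * w_used + 1L
  if (!is.null(steps$true_state)) out$true_state <- steps$true_state
  class(out) <- c("state_classification", "data.frame")
  out
}
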