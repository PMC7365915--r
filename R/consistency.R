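#' Per-bin sampling-envelope comparison of analytic and empirical densities
#'
#' Compares histogram bin counts against the analytic bin probabilities
#' using exact two-sided binomial quantile bands at a `z`-sigma-equivalent
#' level (default 4). For well-populated bins this coincides with the usual
#' `+- z * sqrt(p(1-p)/N)` envelope on densities; in sparse tail bins,
#' where the Gaussian approximation spuriously rejects single-count
#' observations, the exact band remains valid.
#'
#' @param hist A `step_histogram`.
#' @param analytic Bin-averaged analytic densities on `hist$bin_edges`.
#' @param z Sigma-equivalent level of the band. Default 4.
#' @return List with `ok` (all bins inside the band), `n_violations`, and
#'   per-bin `lower`/`upper` count bounds and `counts`.
#' @export
envelope_check <- function(hist, analytic, z = 4) {
  stopifnot(inherits(hist, "step_histogram"),
            length(analytic) == length(hist$counts))
  p <- pmin(pmax(analytic * diff(hist$bin_edges), 0), 1)
  eps <- 2 * stats::pnorm(-z)
  lo <- stats::qbinom(eps / 2, hist$n, p)
  hi <- stats::qbinom(1 - eps / 2, hist$n, p)
  inside <- hist$counts >= lo & hist$counts <= hi
  list(ok = all(inside), n_violations = sum(!inside),
       lower = lo, upper = hi, counts = hist$counts)
}

#' Consistency check of a parallel-component fit against held-out
#' perpendicular data
#'
#' After fitting on the parallel step component only, the fitted model's
#' analytic perpendicular density is compared against the (held-out)
#' empirical perpendicular histogram. A model that captures the walk should
#' reproduce it within per-bin sampling envelopes; failure indicates the
#' parallel component alone did not pin down the state parameters and the
#' fit should be repeated on both components (see [anneal_fit()]'s
#' `hist_perp` argument).
#'
#' @param model A fitted [mixture_model()].
#' @param steps The `step_data` the fit used (its `dy_perp` column is the
#'   held-out data).
#' @param cfg A [pdf_eval_config()].
#' @param breaks Binning for the perpendicular histogram.
#' @param z Envelope level. Default 4.
#' @return List with `ok`, `n_violations`, and the histogram used.
#' @export
check_perpendicular_consistency <- function(model, steps,
                                            cfg = pdf_eval_config(),
                                            breaks = "FD", z = 4) {
  h <- build_histogram(steps$dy_perp, breaks = breaks)
  ana <- mixture_pdf_perpendicular_binned(h$bin_edges, model, cfg)
  chk <- envelope_check(h, ana, z = z)
  list(ok = chk$ok, n_violations = chk$n_violations, hist = h,
       analytic = ana)
}
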