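# A histogram whose densities are exactly the model's bin-averaged
# densities: the SSE objective must vanish there.
model_exact_hist <- function(model, edges, n = 1000L, cfg = test_pcfg) {
  structure(list(bin_edges = edges,
                 densities = mixture_pdf_parallel_binned(edges, model, cfg),
                 counts = rep(1L, length(edges) - 1L), n = n),
            class = "step_histogram")
}

test_that("SSE is zero at self-match and quadratic in bin perturbations", {
  m <- two_state_model()
  edges <- seq(-8, 10, by = 0.25)
  h <- model_exact_hist(m, edges)
  expect_lt(score_sse(m, h, test_pcfg), 1e-12)
  delta <- 0.017
  h2 <- h
  h2$densities[10] <- h2$densities[10] + delta
  expect_equal(score_sse(m, h2, test_pcfg), delta^2, tolerance = 1e-10)
})

test_that("SSE penalizes a misplaced step-size mean on synthetic data", {
  fx <- make_one_state(state_params(3, 1, 0.7), n_tracks = 50,
                       n_steps = 200, seed = 12)
  h <- build_histogram(fx$steps$dx_par)
  sse_truth <- score_sse(fx$model, h, test_pcfg)
  wrong <- mixture_model(state_params(6, 1, 0.7))  # mu off by 3 sigma_r
  expect_gt(score_sse(wrong, h, test_pcfg), sse_truth)
})

test_that("the Metropolis rule accepts improvements always, else by exp(-ds/T)", {
  accept <- prwmix:::anneal_accept
  expect_true(accept(-1, 0.5, u = 0.999))
  expect_true(accept(0, 0.5, u = 0.999))
  ds <- 0.2; temp <- 0.5
  p <- exp(-ds / temp)
  expect_true(accept(ds, temp, u = p - 1e-9))
  expect_false(accept(ds, temp, u = p + 1e-9))
})

test_that("the cooling schedule is exactly geometric", {
  # temperatures enter only through the acceptance rule; verify the
  # sequence by reconstructing it from the config contract
  acfg <- annealing_config(t0 = 2, cooling_factor = 0.9, n_epochs = 5)
  temps <- acfg$t0 * acfg$cooling_factor^(0:4)
  expect_equal(temps, c(2, 1.8, 1.62, 1.458, 1.3122))
})

test_that("one-state parameters are recovered within 5% on synthetic data", {
  fx <- make_one_state(state_params(3, 1, 0.7), n_tracks = 100,
                       n_steps = 1000, seed = 13)
  h <- build_histogram(fx$steps$dx_par)
  fit <- refine_fit(anneal_fit(h, 1, test_acfg(21), test_pcfg), h, test_pcfg)
  s <- fit$model$states[[1]]
  expect_lt(abs(s$mu_r - 3) / 3, 0.05)
  expect_lt(abs(s$sigma_r - 1) / 1, 0.05)
  expect_lt(abs(s$sigma_theta - 0.7) / 0.7, 0.05)
})

test_that("the best-so-far annealing trace is monotone non-increasing", {
  fx <- make_one_state(state_params(2, 1, 0.8), n_tracks = 20,
                       n_steps = 200, seed = 14)
  h <- build_histogram(fx$steps$dx_par)
  fit <- anneal_fit(h, 1, test_acfg(22), test_pcfg)
  for (r in seq_len(ncol(fit$trace))) {
    expect_true(all(diff(fit$trace[, r]) <= 0))
  }
})

test_that("refinement never worsens the fit and stays feasible", {
  fx <- make_one_state(state_params(3, 1, 0.7), n_tracks = 50,
                       n_steps = 400, seed = 15)
  h <- build_histogram(fx$steps$dx_par)
  # start 10% off truth: refinement must strictly improve
  off <- structure(list(model = mixture_model(state_params(3.3, 1.1, 0.77)),
                        sse = NA, n_states = 1L),
                   class = "fit_result")
  off$sse <- score_sse(off$model, h, test_pcfg)
  ref <- refine_fit(off, h, test_pcfg)
  expect_lt(ref$sse, off$sse)
  expect_gt(ref$model$states[[1]]$sigma_r, 0)

  # starting at the (local) optimum returns it unchanged
  again <- refine_fit(ref, h, test_pcfg)
  expect_lt(abs(again$sse - ref$sse), 1e-10)

  # an occupancy initialized at the boundary stays in [0, 1]
  m2 <- mixture_model(list(state_params(3, 1, 0.7), state_params(0, 2, 1.3)),
                      c(1e-12, 1 - 1e-12))
  b <- structure(list(model = m2, sse = score_sse(m2, h, test_pcfg),
                      n_states = 2L), class = "fit_result")
  rb <- refine_fit(b, h, test_pcfg)
  expect_true(all(rb$model$alphas >= 0 & rb$model$alphas <= 1))
})

test_that("bootstrap threshold behaves as a resampling quantile", {
  fx <- make_one_state(state_params(3, 1, 0.7), n_tracks = 30,
                       n_steps = 300, seed = 16)
  h <- build_histogram(fx$steps$dx_par)
  fit <- structure(list(model = fx$model, sse = score_sse(fx$model, h,
                                                          test_pcfg),
                        n_states = 1L), class = "fit_result")
  thr1 <- bootstrap_sse_threshold(fx$steps, fit, h, n_boot = 1, seed = 31,
                                  pcfg = test_pcfg)
  expect_length(attr(thr1, "sse"), 1)
  expect_equal(as.numeric(thr1), attr(thr1, "sse")[1])
  expect_gte(as.numeric(thr1), 0)

  # on clean data the 95% threshold usually exceeds the model's own SSE
  hits <- vapply(1:10, function(i) {
    thr <- bootstrap_sse_threshold(fx$steps, fit, h, n_boot = 60,
                                   seed = 100 + i, pcfg = test_pcfg)
    as.numeric(thr) > fit$sse
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("profiling brackets the estimate and flags unidentifiable parameters", {
  fx <- make_one_state(state_params(3, 1, 0.7), n_tracks = 50,
                       n_steps = 400, seed = 17)
  h <- build_histogram(fx$steps$dx_par)
  fit <- refine_fit(anneal_fit(h, 1, test_acfg(23), test_pcfg), h, test_pcfg)
  thr <- bootstrap_sse_threshold(fx$steps, fit, h, n_boot = 60, seed = 32,
                                 pcfg = test_pcfg)
  est <- fit$model$states[[1]]$mu_r
  grid <- sort(c(est, seq(2.0, 4.0, length.out = 11)))
  prof <- profile_parameter(fit, h, "mu_r1", grid, thr, pcfg = test_pcfg)
  # profiled SSE at the point estimate itself equals the fit SSE
  expect_lte(min(prof$sse), fit$sse + 1e-9)
  expect_lte(prof$ci_low, prof$estimate)
  expect_gte(prof$ci_high, prof$estimate)
  expect_true(prof$ci_low <= 3 && prof$ci_high >= 3)  # covers the truth
  expect_error(profile_parameter(fit, h, "mu_r1", seq(5, 6, 0.5), thr),
               "outside the grid")

  # a state with vanishing occupancy has an unconstrained sigma_theta
  m2 <- mixture_model(list(state_params(3, 1, 0.7), state_params(0, 2, 1.3)),
                      c(0.999, 0.001))
  f2 <- structure(list(model = m2, sse = score_sse(m2, h, test_pcfg),
                       n_states = 2L), class = "fit_result")
  grid <- seq(0.4, 2.6, length.out = 7)
  prof2 <- profile_parameter(f2, h, "sigma_theta2", grid, thr,
                             pcfg = test_pcfg, maxit = 50)
  expect_equal(prof2$ci_low, grid[1])
  expect_equal(prof2$ci_high, grid[length(grid)])
})

test_that("state-count selection keeps one state when one suffices", {
  light <- annealing_config(n_restarts = 2L, n_epochs = 25L,
                            steps_per_epoch = 50L, seed = 41)
  fx1 <- make_one_state(state_params(2.5, 1, 0.5), n_tracks = 40,
                        n_steps = 250, seed = 42)
  sel1 <- suppressWarnings(select_n_states(fx1$steps, light, test_pcfg,
                                           n_boot = 60))
  expect_identical(sel1$n_states, 1L)
  # degenerate two-state companion fit: alpha at a boundary or twin states
  a <- sel1$fit2$model$alphas[1]
  s1 <- sel1$fit2$model$states[[1]]
  s2 <- sel1$fit2$model$states[[2]]
  rel <- function(x, y) abs(x - y) / pmax(abs(x), abs(y), 1e-6)
  twin <- rel(s1$mu_r, s2$mu_r) < 0.1 && rel(s1$sigma_r, s2$sigma_r) < 0.1 &&
    rel(s1$sigma_theta, s2$sigma_theta) < 0.1
  expect_true(min(a, 1 - a) < 0.05 || twin)

  # strongly bimodal two-state data forces the two-state decision
  m2 <- mixture_model(list(state_params(4, 0.7, 0.4),
                           state_params(0, 1.5, 1.5)), c(0.5, 0.5))
  tracks <- lapply(1:40, function(i) {
    simulate_track(m2, 250, seed = 4200 + i, cell_id = paste0("b", i))
  })
  sel2 <- suppressWarnings(select_n_states(track_to_steps(tracks), light,
                                           test_pcfg, n_boot = 60))
  expect_identical(sel2$n_states, 2L)
})

test_that("the full protocol records its consistency verdict", {
  light <- annealing_config(n_restarts = 2L, n_epochs = 25L,
                            steps_per_epoch = 50L, seed = 43)
  fx <- make_one_state(state_params(2.5, 1, 0.5), n_tracks = 40,
                       n_steps = 250, seed = 44)
  fit <- suppressWarnings(fit_migration_model(fx$steps, 1L, light,
                                              test_pcfg))
  expect_true(is.logical(fit$consistency$ok))
  expect_s3_class(fit$model, "mixture_model")
  # a clean one-state fit should reproduce the perpendicular data
  expect_true(fit$consistency$ok)
})
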