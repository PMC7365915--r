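# Monte Carlo oracle built from raw model draws: x = r cos(theta),
# y = r sin(theta) with r ~ N(mu, sigma_r^2), theta ~ N(0, sigma_theta^2).
# Independent of the simulator and transform code paths. Bin counts are
# compared against exact binomial 4-sigma-equivalent quantile bands (the
# Gaussian +-4 sd approximation spuriously rejects single-count tail bins).
mc_component_ok <- function(state, component, n = 2e5, seed = 1) {
  set.seed(seed)
  r <- rnorm(n, state$mu_r, state$sigma_r)
  th <- rnorm(n, 0, state$sigma_theta)
  v <- if (component == "par") r * cos(th) else r * sin(th)
  h <- build_histogram(v)
  f <- if (component == "par") pdf_parallel_binned else pdf_perpendicular_binned
  ana <- f(h$bin_edges, state, 1, test_pcfg)
  envelope_check(h, ana, z = 4)$ok
}

test_that("densities normalize to 1 across the parameter grid", {
  for (mu in c(0, 1, 3)) {
    for (sr in c(0.5, 2)) {
      for (sth in c(0.3, 0.7, 1.3, 3)) {
        st <- state_params(mu, sr, sth)
        expect_lt(check_pdf_normalization(st, 1, test_pcfg, "par",
                                          error = FALSE), 1e-6)
        expect_lt(check_pdf_normalization(st, 1, test_pcfg, "perp",
                                          error = FALSE), 1e-6)
      }
    }
  }
})

test_that("analytic densities agree with raw-draw Monte Carlo", {
  st <- state_params(3, 1, 0.7)
  expect_true(mc_component_ok(st, "par"))
  expect_true(mc_component_ok(st, "perp"))
  # a diffusive-leaning state too
  st2 <- state_params(0, 2, 1.3)
  expect_true(mc_component_ok(st2, "par", seed = 2))
  expect_true(mc_component_ok(st2, "perp", seed = 2))
})

test_that("perfectly persistent limit collapses to the magnitude density", {
  st <- state_params(3, 1, 1e-4)
  xs <- c(2, 3, 4)  # mu - sigma, mu, mu + sigma
  expect_lt(max(abs(pdf_parallel(xs, st) - dnorm(xs, 3, 1))), 1e-4)
})

test_that("direction-uniform limit is symmetric about zero", {
  st <- state_params(3, 1, 10)
  xs <- c(0.5, 1, 2, 4)
  expect_lt(max(abs(pdf_parallel(xs, st) - pdf_parallel(-xs, st))), 1e-6)
})

test_that("perpendicular density is exactly symmetric", {
  st <- state_params(3, 1, 0.7)
  ys <- c(0.5, 1, 2)
  expect_identical(pdf_perpendicular(ys, st), pdf_perpendicular(-ys, st))
})

test_that("wrap truncation and quadrature order are adequate", {
  st <- state_params(1, 0.5, 1.3)
  xs <- setdiff(seq(-3, 3, by = 0.5), 0)  # x = 0 is the bin-averaged special case
  base <- pdf_parallel(xs, st, cfg = pdf_eval_config(n_quad = 400))
  more_k <- pdf_parallel(xs, st, cfg = pdf_eval_config(k_max = 25,
                                                       n_quad = 400))
  expect_lt(max(abs(base - more_k)), 1e-10)
  more_q <- pdf_parallel(xs, st, cfg = pdf_eval_config(n_quad = 800))
  expect_lt(max(abs(base - more_q)), 1e-8)
  # the x = 0 bin-average converges too, at its own (boundary-layer) rate
  z0 <- pdf_parallel(0, st, cfg = pdf_eval_config(n_quad = 400))
  z1 <- pdf_parallel(0, st, cfg = pdf_eval_config(n_quad = 1600))
  expect_lt(abs(z0 - z1), 1e-4)
})

test_that("mixture densities are convex combinations of their components", {
  s1 <- state_params(3, 1, 0.7)
  s2 <- state_params(0, 2, 1.3)
  x <- 2
  f1 <- pdf_parallel(x, s1, cfg = test_pcfg)
  f2 <- pdf_parallel(x, s2, cfg = test_pcfg)
  m10 <- mixture_model(list(s1, s2), c(1, 0))
  m01 <- mixture_model(list(s1, s2), c(0, 1))
  m37 <- mixture_model(list(s1, s2), c(0.3, 0.7))
  expect_equal(mixture_pdf_parallel(x, m10, test_pcfg), f1, tolerance = 1e-12)
  expect_equal(mixture_pdf_parallel(x, m01, test_pcfg), f2, tolerance = 1e-12)
  expect_equal(mixture_pdf_parallel(x, m37, test_pcfg),
               0.3 * f1 + 0.7 * f2, tolerance = 1e-12)
})

test_that("bin-averaged densities equal the integral of the pointwise pdf", {
  st <- state_params(2, 1, 0.9)
  edges <- c(1.0, 1.5)
  g <- pracma::gaussLegendre(60, edges[1], edges[2])
  quad <- sum(g$w * pdf_parallel(g$x, st)) / diff(edges)
  expect_equal(pdf_parallel_binned(edges, st)[1], quad, tolerance = 1e-8)
})

test_that("the x = 0 evaluation returns a finite bin-averaged value", {
  st <- state_params(0, 1, 0.5)  # magnitude density positive at 0
  v <- pdf_parallel(0, st)
  expect_true(is.finite(v) && v > 0)
})
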