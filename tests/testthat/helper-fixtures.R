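# Shared fixtures and configs for the test suite. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# Small, fast quadrature config for tests that do many density evaluations.
test_pcfg <- pdf_eval_config(n_quad = 200L)

# Light annealing config for tests that need a full fit but not the
# production effort level.
test_acfg <- function(seed) {
  annealing_config(n_restarts = 3L, n_epochs = 30L, steps_per_epoch = 60L,
                   seed = seed)
}

# A well-separated two-state model for recovery tests.
two_state_model <- function() mef_like_model()

# Straight-line track along +x.
straight_track <- function(n = 10L) {
  cell_track("straight", 0:n, 0:n, rep(0, n + 1))
}
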