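# Internal helpers shared across modules.

# Run `fn` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

# Cache of Gauss-Legendre rules on (-1, 1), keyed by node count.
.gl_cache <- new.env(parent = emptyenv())

gl_base <- function(n) {
  key <- as.character(n)
  g <- .gl_cache[[key]]
  if (is.null(g)) {
    g <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- g
  }
  g
}

# Gauss-Legendre nodes/weights rescaled to (a, b).
gl_on <- function(n, a, b) {
  g <- gl_base(n)
  list(x = (a + b) / 2 + (b - a) / 2 * g$x, w = (b - a) / 2 * g$w)
}

# log(sum(exp(x))) by rows of a matrix, safe against -Inf rows.
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
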