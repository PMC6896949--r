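# internal helpers shared across modules

# Scoped RNG: set the seed for the calling frame only, restoring the global
# RNG state on exit, so library calls never clobber a user's random stream.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) {
    return(invisible(NULL))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Dirichlet draws via normalised gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  # guard against all-zero rows when concentrations are tiny
  zero <- rowSums(x) == 0
  if (any(zero)) {
    x[zero, ] <- t(stats::rmultinom(sum(zero), 1L, rep(1 / k, k)))
  }
  x / rowSums(x)
}
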