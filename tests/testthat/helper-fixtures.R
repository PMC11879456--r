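# Shared fixtures: small parameter sets and quick-fit options used across
# the suite. Everything is generated in code; no stored data.

truth_single <- function() default_rtf_truth()

truth_single_vec <- function() {
  p <- default_rtf_truth()
  c(A = p$A, B = p$B, alpha = p$alpha, beta = p$beta, gamma = p$gamma,
    tau = p$tau, b = p$b)
}

truth_sustained_only <- function() {
  rtf_params(A = 1, B = 0, alpha = 1, beta = 2, gamma = 0.5, tau = 0.5, b = 0.2)
}

# a fast fitting configuration for tests that exercise plumbing, not accuracy
quick_fit <- function(data, ...) {
  rtf_fit(data, n_starts = 6, seed = 1, sign_sus = 1, sign_trans = 1, ...)
}

# random feasible natural-scale parameter draws inside the problem's bounds
random_feasible <- function(problem, n, seed) {
  free <- setdiff(problem$param_names, names(problem$fixed))
  set.seed(seed)
  lo <- problem$lb[free]; hi <- problem$ub[free]
  lg <- problem$take_log10[free]
  draws <- matrix(NA_real_, n, length(free), dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    if (lg[j]) {
      draws[, j] <- 10^stats::runif(n, log10(lo[j]), log10(hi[j]))
    } else {
      # stay a little inside so finite differences remain feasible
      pad <- 0.05 * (hi[j] - lo[j])
      draws[, j] <- stats::runif(n, lo[j] + pad, hi[j] - pad)
    }
  }
  draws
}

# central finite difference of a scalar function
fd_scalar <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
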