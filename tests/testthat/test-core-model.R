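# Core RTF evaluation: time transform, model, components, analytic gradients.

test_that("time transform matches its closed form and limits", {
  # frozen value from 50-digit evaluation of the defining expression
  expect_equal(time_transform(5, 1, 10), 3.9586507421186376, tolerance = 1e-14)
  expect_equal(time_transform(3, -0.5, 7), 4.1663903508719265, tolerance = 1e-14)

  # exact zero at treal = 0 for any tau
  for (tau in c(-30, -2, 0, 0.7, 5, 40)) {
    expect_identical(time_transform(0, tau, 10), 0)
  }

  # tau -> -Inf limit: linear rescaling treal * 10 / T
  tr <- seq(0, 7, length.out = 25)
  expect_lt(max(abs(time_transform(tr, -20, 7) - tr * 10 / 7)), 1e-6)

  # strictly increasing in treal for a spread of tau
  tr <- seq(0, 10, length.out = 400)
  for (tau in c(-10, -1, 0, 1, 3)) {
    expect_true(all(diff(time_transform(tr, tau, 10)) > 0))
  }

  # no overflow for large arguments
  expect_true(is.finite(time_transform(1e4, 5, 10)))

  expect_error(time_transform(1, 0, -1), "positive")
  expect_error(time_transform(NA_real_, 0, 1), "finite")
  expect_error(time_transform(1, Inf, 1), "finite")
})

test_that("RTF evaluation honours closed-form special cases", {
  base <- list(alpha = 1.3, beta = 2.2, gamma = 0.4, tau = 0.3)

  # zero amplitudes: response is the offset everywhere
  p0 <- rtf_params(A = 0, B = 0, alpha = base$alpha, beta = base$beta,
                   gamma = base$gamma, tau = base$tau, b = 0.7)
  expect_equal(rtf_evaluate(p0, c(0, 2, 5, 9), 10), rep(0.7, 4))

  # treal = 0 always returns b
  p <- truth_single()
  expect_equal(rtf_evaluate(p, 0, 10), p$b)

  # tau -> -Inf, pure sustained at treal = T: A (1 - e^-10)
  p1 <- rtf_params(A = 2, B = 0, alpha = 1, beta = 1, gamma = 1,
                   tau = -20, b = 0)
  expect_equal(rtf_evaluate(p1, 10, 10), 1.999909200140475, tolerance = 1e-8)

  # large-time asymptote: transient decays, leaving sign_sus * A + b
  p2 <- rtf_params(A = 1.4, B = 2, alpha = 1, beta = 2, gamma = 0.8,
                   tau = 0.2, b = 0.3)
  expect_equal(rtf_evaluate(p2, 1e3, 10), 1.4 + 0.3, tolerance = 1e-6)

  expect_error(rtf_params(A = -1, B = 0, alpha = 1, beta = 1, gamma = 1,
                          tau = 0, b = 0), ">= 0")
  expect_error(rtf_params(A = 1, B = 0, alpha = 0, beta = 1, gamma = 1,
                          tau = 0, b = 0), "> 0")
  expect_error(rtf_params(A = 1, B = 0, alpha = 1, beta = 1, gamma = 1,
                          tau = 0, b = 0, sign_sus = 2), "sign")
})

test_that("component decomposition sums exactly to the full model", {
  tr <- seq(0, 12, length.out = 37)
  set.seed(11)
  for (i in 1:10) {
    p <- rtf_params(A = runif(1, 0, 2), B = runif(1, 0, 2),
                    alpha = 10^runif(1, -1, 1), beta = 10^runif(1, -1, 1),
                    gamma = 10^runif(1, -1, 1), tau = runif(1, -1, 2),
                    b = runif(1, -1, 1),
                    sign_sus = sample(c(-1, 1), 1),
                    sign_trans = sample(c(-1, 1), 1))
    cmp <- rtf_components(p, tr, 12)
    expect_identical(cmp$sustained + cmp$transient + cmp$offset,
                     rtf_evaluate(p, tr, 12))
  }
  pB0 <- rtf_params(A = 1, B = 0, alpha = 1, beta = 2, gamma = 1, tau = 0, b = 0)
  expect_equal(rtf_components(pB0, tr, 12)$transient, rep(0, length(tr)))
  pA0 <- rtf_params(A = 0, B = 1, alpha = 1, beta = 2, gamma = 1, tau = 0, b = 0)
  expect_equal(rtf_components(pA0, tr, 12)$sustained, rep(0, length(tr)))
})

test_that("sustained-only RTF is monotone in time", {
  p <- rtf_params(A = 1.5, B = 0, alpha = 0.8, beta = 1, gamma = 1,
                  tau = 0.4, b = 0.1)
  tr <- seq(0, 10, length.out = 300)
  expect_true(all(diff(rtf_evaluate(p, tr, 10)) >= 0))
})

test_that("analytic RTF gradient agrees with central finite differences", {
  tr <- seq(0, 10, length.out = 15)
  set.seed(202)
  for (i in 1:20) {
    v <- c(A = runif(1, 0.2, 2), B = runif(1, 0.2, 2),
           alpha = 10^runif(1, -0.7, 0.7), beta = 10^runif(1, -0.7, 0.7),
           gamma = 10^runif(1, -0.7, 0.7), tau = runif(1, -1, 2),
           b = runif(1, -0.5, 0.5))
    p <- rtf_params(A = v[["A"]], B = v[["B"]], alpha = v[["alpha"]],
                    beta = v[["beta"]], gamma = v[["gamma"]], tau = v[["tau"]],
                    b = v[["b"]])
    G <- rtf_gradient(p, tr, 10)
    expect_identical(G[, "b"], rep(1, length(tr)))
    for (nm in names(v)) {
      h <- 1e-6 * max(1, abs(v[[nm]]))
      fdv <- vapply(tr, function(t1) {
        fd_scalar(function(x) {
          q <- p; q[[nm]] <- x
          rtf_evaluate(q, t1, 10)
        }, v[[nm]], h)
      }, numeric(1))
      expect_lt(max(abs(G[, nm] - fdv)) / max(1, max(abs(G[, nm]))), 1e-5)
    }
  }
  # dR/dA vanishes at treal = 0 since transformed time is 0 there
  p <- truth_single()
  expect_equal(unname(rtf_gradient(p, 0, 10)[, "A"]), 0)
})

test_that("Hill curve has its defining properties", {
  expect_identical(hill(0, M = 4, h = 2, K = 3), 0)
  expect_equal(hill(3, M = 4, h = 2, K = 3), 2)  # half-maximum at d = K
  dd <- seq(0, 500, length.out = 2000)
  hv <- hill(dd, M = 4, h = 2, K = 3)
  expect_true(all(diff(hv) >= 0))
  expect_true(all(hv >= 0 & hv < 4))
  expect_gt(hill(1e6, M = 4, h = 2, K = 3), 4 - 1e-4)
  expect_error(hill(-1, 1, 1, 1), ">= 0")
  expect_error(hill(1, 1, -1, 1), "Hill")
})

test_that("dose expansion matches single-dose evaluation and its limits", {
  dp <- default_dose_truth()

  # d = 0: amplitudes vanish, response is flat at b
  p0 <- dose_expand(dp, 0)
  expect_identical(p0$A, 0)
  expect_identical(p0$B, 0)
  expect_equal(rtf_evaluate(p0, c(0, 3, 8), 10), rep(dp$b, 3))

  # d = K: every increasing parameter at M/2, tau at M_tau/2
  pK <- dose_expand(dp, 5)
  expect_equal(pK$A, 1 / 2)
  expect_equal(pK$B, 1.5 / 2)
  expect_equal(pK$alpha, 1 / 2)
  expect_equal(pK$tau, 0.5 / 2)

  # tau(d) decreasing, others non-decreasing over a dose ladder
  dd <- c(0, 0.5, 1.25, 2.5, 5, 10, 20, 80)
  ex <- lapply(dd, function(d) dose_expand(dp, d))
  expect_true(all(diff(vapply(ex, `[[`, numeric(1), "tau")) <= 0))
  for (nm in c("A", "B", "alpha", "beta", "gamma")) {
    expect_true(all(diff(vapply(ex, `[[`, numeric(1), nm)) >= 0))
  }

  # equivalence: expand-then-evaluate == vectorized dose evaluation
  tr <- seq(0, 10, length.out = 11)
  for (d in c(1.25, 5, 20)) {
    expect_equal(rtf_evaluate(dose_expand(dp, d), tr, 10),
                 dose_rtf_evaluate(dp, tr, rep(d, length(tr)), 10),
                 tolerance = 1e-12)
  }
  expect_error(dose_expand(dp, -1), ">= 0")
})

test_that("dose-dependent gradient agrees with finite differences", {
  tr <- rep(seq(0, 10, length.out = 7), times = 3)
  dd <- rep(c(1.25, 5, 20), each = 7)
  set.seed(303)
  for (i in 1:20) {
    dp <- dose_rtf_params(
      hill_A = c(runif(1, 0.3, 2), 10^runif(1, -0.3, 0.6), runif(1, 2, 10)),
      hill_B = c(runif(1, 0.3, 2), 10^runif(1, -0.3, 0.6), runif(1, 2, 10)),
      hill_alpha = c(runif(1, 0.3, 2), 10^runif(1, -0.3, 0.6), runif(1, 2, 10)),
      hill_beta = c(runif(1, 0.5, 3), 10^runif(1, -0.3, 0.6), runif(1, 2, 10)),
      hill_gamma = c(runif(1, 0.2, 1), 10^runif(1, -0.3, 0.6), runif(1, 2, 10)),
      hill_tau = c(runif(1, 0.1, 1), 10^runif(1, -0.3, 0.6), runif(1, 2, 10)),
      b = runif(1, -0.5, 0.5)
    )
    th <- rtfmod:::.dose_params_to_theta(dp)
    G <- dose_gradient(dp, tr, dd, 10)
    expect_identical(G[, "b"], rep(1, length(tr)))
    for (nm in names(th)) {
      h <- 1e-6 * max(1, abs(th[[nm]]))
      fdv <- vapply(seq_along(tr), function(k) {
        fd_scalar(function(x) {
          t2 <- th; t2[[nm]] <- x
          rtfmod:::.dose_rtf_values(t2, tr[k], dd[k], 1, 1, 10)
        }, th[[nm]], h)
      }, numeric(1))
      expect_lt(max(abs(G[, nm] - fdv)) / max(1, max(abs(G[, nm]))), 1e-5)
    }
  }
  # at d = 0 the M_A sensitivity vanishes (Hill(0) = 0 with zero slope in M)
  dp <- default_dose_truth()
  expect_equal(dose_gradient(dp, c(0, 5), c(0, 0), 10)[, "M_A"], c(0, 0))
})
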