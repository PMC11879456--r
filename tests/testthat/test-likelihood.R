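# Objective, problem construction, initial guesses, fitting and prediction.

test_that("objective matches the Gaussian closed forms", {
  # zero residuals, sigma = 1, n = 10: objective is 10 * ln(2*pi)
  p <- truth_single()
  tt <- seq(0, 10, length.out = 10)
  d <- data.frame(t = tt, y = rtf_evaluate(p, tt, 10))
  prob <- rtf_problem(d, sign_sus = 1, sign_trans = 1)
  theta <- c(truth_single_vec(), sigma = 1)
  expect_equal(neg2_log_likelihood(theta, prob), 18.37877066409345,
               tolerance = 1e-12)

  # single residual of 2 at sigma = 1: ln(2*pi) + 4 per point
  d2 <- d
  d2$y <- d2$y + 2
  prob2 <- rtf_problem(d2, sign_sus = 1, sign_trans = 1)
  expect_equal(neg2_log_likelihood(theta, prob2),
               10 * 5.837877066409345, tolerance = 1e-12)

  # doubling known sigmaExp changes the objective by n ln4 - (3/4) sum(r^2/s^2)
  set.seed(5)
  d3 <- d
  d3$y <- d3$y + rnorm(10, 0, 0.3)
  d3$sigmaExp <- runif(10, 0.2, 0.5)
  pr3 <- rtf_problem(d3, sign_sus = 1, sign_trans = 1)
  th3 <- truth_single_vec()
  v1 <- neg2_log_likelihood(th3, pr3)
  r <- d3$y - rtf_evaluate(p, tt, 10)
  d4 <- d3
  d4$sigmaExp <- 2 * d3$sigmaExp
  pr4 <- rtf_problem(d4, sign_sus = 1, sign_trans = 1)
  v2 <- neg2_log_likelihood(th3, pr4)
  expect_equal(v2 - v1, 10 * log(4) - 0.75 * sum((r / d3$sigmaExp)^2),
               tolerance = 1e-10)

  expect_error(neg2_log_likelihood(c(th3, sigma = -1), prob), "sigma")
})

test_that("problem construction resolves sigma, bounds and modes correctly", {
  d <- sim_timecourse(seed = 2)

  # sigma free without sigmaExp, absent with it
  pr <- rtf_problem(d)
  expect_true("sigma" %in% pr$param_names)
  expect_true(pr$sigma_free)
  d2 <- d
  d2$sigmaExp <- rep(0.02, nrow(d))
  pr2 <- rtf_problem(d2)
  expect_false("sigma" %in% pr2$param_names)
  expect_false(pr2$sigma_free)

  # default guess inside bounds across many simulated datasets
  for (s in 1:50) {
    ds <- sim_timecourse(seed = s, noise_sd = runif(1, 0.005, 0.2))
    ps <- rtf_problem(ds)
    expect_true(all(ps$initial_guess >= ps$lb & ps$initial_guess <= ps$ub))
  }

  # dose mode requires d with at least two distinct doses
  expect_error(rtf_problem(d, mode = "doseDependent"), "dose")
  dd <- sim_timecourse("doseDependent", seed = 1)
  prd <- rtf_problem(dd, mode = "doseDependent")
  expect_length(prd$param_names, 20)  # 18 Hill + b + sigma
  dd1 <- dd[dd$d == dd$d[1], ]
  expect_error(rtf_problem(dd1, mode = "doseDependent"), "2 distinct doses")

  # degenerate (constant) data: warning, still a valid problem
  dc <- data.frame(t = 0:5, y = rep(1, 6))
  expect_warning(pc <- rtf_problem(dc), "identical")
  expect_true(all(pc$initial_guess >= pc$lb & pc$initial_guess <= pc$ub))

  expect_error(rtf_problem(d, fixed = c(nonsense = 1)), "unknown parameter")
})

test_that("initial guesses are deterministic, feasible, default-first", {
  pr <- rtf_problem(sim_timecourse(seed = 3), sign_sus = 1, sign_trans = 1)
  g1 <- initial_guesses(pr, 1, seed = 9)
  expect_identical(nrow(g1), 1L)
  expect_equal(g1[1, ], pr$initial_guess)

  ga <- initial_guesses(pr, 200, seed = 42)
  gb <- initial_guesses(pr, 200, seed = 42)
  expect_identical(ga, gb)
  gc <- initial_guesses(pr, 200, seed = 43)
  expect_false(identical(ga, gc))
  expect_true(all(is.finite(ga)))
  expect_true(all(t(ga) >= pr$lb[colnames(ga)] & t(ga) <= pr$ub[colnames(ga)]))
})

test_that("analytic objective gradient matches finite differences", {
  # differentiate on the optimizer (log10-transformed) scale, where every
  # coordinate is O(1) and central differences are well conditioned
  for (mode in c("singleDose", "doseDependent")) {
    d <- sim_timecourse(mode, seed = 4)
    pr <- rtf_problem(d, mode = mode, sign_sus = 1, sign_trans = 1)
    free <- setdiff(pr$param_names, names(pr$fixed))
    lg <- pr$take_log10[free]
    draws <- random_feasible(pr, 20, seed = 77)
    obj_at <- function(x) {
      th <- x
      th[lg] <- 10^x[lg]
      names(th) <- free
      neg2_log_likelihood(th, pr)
    }
    for (i in seq_len(nrow(draws))) {
      theta <- draws[i, ]
      x0 <- theta
      x0[lg] <- log10(theta[lg])
      g <- objective_gradient(theta, pr, transformed = TRUE)
      expect_identical(names(g), free)
      fd <- vapply(seq_along(free), function(k) {
        h <- 1e-6 * max(1, abs(x0[k]))
        fd_scalar(function(v) {
          x2 <- x0; x2[k] <- v
          obj_at(x2)
        }, x0[k], h)
      }, numeric(1))
      # relative to the gradient norm: coordinates much smaller than the
      # norm carry only finite-difference roundoff at this objective scale
      expect_lt(max(abs(g - fd)) / max(1, max(abs(fd))), 1e-5)
    }
  }
})

test_that("log10 reparameterization applies the chain factor", {
  pr <- rtf_problem(sim_timecourse(seed = 6), sign_sus = 1, sign_trans = 1)
  theta <- random_feasible(pr, 1, seed = 8)[1, ]
  g_nat <- objective_gradient(theta, pr, transformed = FALSE)
  g_tr <- objective_gradient(theta, pr, transformed = TRUE)
  lg <- pr$take_log10[names(g_nat)]
  expect_equal(g_tr[lg], g_nat[lg] * theta[names(g_nat)[lg]] * log(10))
  expect_equal(g_tr[!lg], g_nat[!lg])
})

test_that("fixed parameters are excluded from the optimization vector", {
  pr <- rtf_problem(sim_timecourse(seed = 6), sign_sus = 1, sign_trans = 1,
                    fixed = c(B = 0, beta = 1, gamma = 1))
  theta <- c(truth_single_vec(), sigma = 0.05)
  theta[c("B", "beta", "gamma")] <- c(0, 1, 1)
  g <- objective_gradient(theta, pr)
  expect_identical(names(g), c("A", "alpha", "tau", "b", "sigma"))
})

test_that("fitting attains the noise-free likelihood floor and is reproducible", {
  d <- sim_timecourse(seed = 10, noise_sd = 1e-9)
  d$sigmaExp <- rep(1e-6, nrow(d))
  f <- rtf_fit(d, n_starts = 30, seed = 1, sign_sus = 1, sign_trans = 1)
  floor <- nrow(d) * log(2 * pi * 1e-12)
  expect_lt(f$value - floor, 1e-3)
  expect_equal(f$value, neg2_log_likelihood(f$best, f$problem))
  expect_true(all(f$best >= f$problem$lb & f$best <= f$problem$ub))

  # bit-identical reproducibility
  f2 <- rtf_fit(d, n_starts = 30, seed = 1, sign_sus = 1, sign_trans = 1)
  expect_identical(f$best, f2$best)
  expect_identical(f$value, f2$value)
})

test_that("sigma stationarity holds at the optimum when sigma is free", {
  for (s in 1:5) {
    d <- sim_timecourse(seed = s)
    f <- rtf_fit(d, n_starts = 10, seed = s)
    expect_equal(f$best[["sigma"]]^2, mean(f$residuals^2), tolerance = 1e-4)
  }
})

test_that("continuation via res_old never worsens the result", {
  d <- sim_timecourse(seed = 12)
  f1 <- rtf_fit(d, n_starts = 4, seed = 1)
  f2 <- rtf_fit(d, n_starts = 0, seed = 2, res_old = f1)
  expect_lte(f2$value, f1$value)
  f3 <- rtf_fit(d, n_starts = 10, seed = 2, res_old = f1)
  expect_lte(f3$value, f1$value)
  expect_error(rtf_fit(d, n_starts = 0), "res_old")
})

test_that("multi-start waterfall shows a plateau on an easy fitting task", {
  # sustained-only model (transient fixed out): 5 free parameters
  p <- truth_sustained_only()
  d <- sim_timecourse(params = p, seed = 5, noise_sd = 0.01)
  f <- rtf_fit(d, n_starts = 50, seed = 5, sign_sus = 1, sign_trans = 1,
               fixed = c(B = 0, beta = 1, gamma = 1))
  w <- waterfall_values(f)
  expect_gte(mean(w <= min(w) + 1e-3), 0.3)
  expect_true(all(diff(w) >= 0))
})

test_that("prediction is consistent with the training fit", {
  d <- sim_timecourse(seed = 13)
  f <- quick_fit(d)
  expect_equal(predict(f, d$t), f$fitted)
  expect_equal(predict(f, 0), f$best[["b"]])
  expect_error(predict(f, 1, doses = 2), "singleDose")

  dd <- sim_timecourse("doseDependent", seed = 13)
  fd <- rtf_fit(dd, mode = "doseDependent", n_starts = 4, seed = 1,
                sign_sus = 1, sign_trans = 1)
  expect_error(predict(fd, 1), "doses")
  pred <- predict(fd, c(0, 5), doses = c(2.5, 10))
  expect_identical(nrow(pred), 4L)
  # matches single-dose evaluation of the expanded parameters
  dp <- dose_rtf_params(hill_A = fd$best[c("M_A", "h_A", "K_A")],
                        hill_B = fd$best[c("M_B", "h_B", "K_B")],
                        hill_alpha = fd$best[c("M_alpha", "h_alpha", "K_alpha")],
                        hill_beta = fd$best[c("M_beta", "h_beta", "K_beta")],
                        hill_gamma = fd$best[c("M_gamma", "h_gamma", "K_gamma")],
                        hill_tau = fd$best[c("M_tau", "h_tau", "K_tau")],
                        b = fd$best[["b"]],
                        sign_sus = fd$sign_sus, sign_trans = fd$sign_trans)
  ex <- dose_expand(dp, 10)
  expect_equal(pred$y[pred$d == 10],
               rtf_evaluate(ex, c(0, 5), fd$problem$T), tolerance = 1e-10)
})
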