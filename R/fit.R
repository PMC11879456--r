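# Multi-start bounded maximum-likelihood fitting of the RTF.

#' Fit the RTF to time-course data by multi-start maximum likelihood
#'
#' Runs bounded quasi-Newton (`L-BFGS-B`) local optimization of the
#' [neg2_log_likelihood] objective from many initial guesses (the
#' data-derived default plus a seeded Latin-hypercube sample, see
#' [initial_guesses]) and keeps the best converged result. When the
#' component signs are `"auto"` (the default) all sign combinations are
#' enumerated and the start budget is split equally between them. When
#' `sigma` is estimated, the best fit receives a final profile update
#' `sigma^2 = mean(residuals^2)` (the exact conditional optimum of the
#' objective) followed by a polishing optimization.
#'
#' A previous [rtf_fit] result can be supplied via `res_old`; its recorded
#' starts are merged with the new ones and the overall best is returned, so
#' the objective can only improve.
#'
#' @param x A data.frame (columns `t`, `y`, optional `d`, `sigmaExp`) or an
#'   [rtf_problem].
#' @param mode,sign_sus,sign_trans,fixed,lb,ub Passed to [rtf_problem] when
#'   `x` is a data.frame; ignored otherwise.
#' @param n_starts Total number of optimization starts (default 50). May be
#'   0 when continuing from `res_old`.
#' @param seed Integer seed controlling all random draws.
#' @param res_old Optional previous [rtf_fit] on the same problem.
#' @param warm_start Optional named natural-scale parameter vector inserted
#'   as an additional first start (used by the model-reduction refits).
#' @param basin_hops Number of seeded basin-hopping rounds applied to the
#'   incumbent best fit after the multi-start stage: the optimizer-space
#'   parameter vector is perturbed (Gaussian, with an amplitude cycling
#'   through 10/25/50% of each box width) and re-optimized, keeping
#'   improvements. This escapes the narrow near-equal-likelihood side
#'   basins typical of sums of exponentials. Set to 0 to disable.
#' @param optim_control Extra `control` entries for [stats::optim]
#'   (defaults: `maxit = 1000`, `factr = 1e7`).
#' @return An object of class `rtf_fit`: the resolved problem, all starts
#'   (`starts`), the best natural-scale parameter vector (`best`), the best
#'   objective (`value`), fitted values and residuals.
#' @examples
#' d <- sim_timecourse(seed = 1)
#' fit <- rtf_fit(d, n_starts = 8, seed = 1)
#' coef(fit)
#' @export
rtf_fit <- function(x, mode = c("singleDose", "doseDependent"),
                    n_starts = 50, seed = 1, res_old = NULL,
                    sign_sus = "auto", sign_trans = "auto",
                    fixed = NULL, lb = NULL, ub = NULL,
                    warm_start = NULL, basin_hops = 15, optim_control = list()) {
  problem <- if (inherits(x, "rtf_problem")) {
    x
  } else {
    rtf_problem(x, mode = mode, sign_sus = sign_sus, sign_trans = sign_trans,
                fixed = fixed, lb = lb, ub = ub)
  }
  if (n_starts < 0) stop("`n_starts` must be >= 0", call. = FALSE)
  if (n_starts == 0 && is.null(res_old)) {
    stop("`n_starts = 0` requires a previous result in `res_old`", call. = FALSE)
  }
  if (!is.null(res_old)) {
    if (!inherits(res_old, "rtf_fit")) stop("`res_old` must be an rtf_fit", call. = FALSE)
    if (!identical(res_old$problem$param_names, problem$param_names) ||
        !identical(dim(res_old$problem$data), dim(problem$data))) {
      stop("`res_old` was fitted on an incompatible problem", call. = FALSE)
    }
  }

  ss_opts <- if (identical(problem$sign_sus, "auto")) c(1, -1) else problem$sign_sus
  st_opts <- if (identical(problem$sign_trans, "auto")) c(1, -1) else problem$sign_trans
  combos <- expand.grid(ss = ss_opts, st = st_opts, KEEP.OUT.ATTRS = FALSE)
  n_combo <- nrow(combos)
  budget <- rep(n_starts %/% n_combo, n_combo)
  extra <- n_starts %% n_combo
  if (extra > 0) budget[seq_len(extra)] <- budget[seq_len(extra)] + 1L

  control <- utils::modifyList(list(maxit = 1000, factr = 1e7), optim_control)
  starts <- list()
  for (ci in seq_len(n_combo)) {
    if (budget[ci] == 0 && is.null(warm_start)) next
    prob_c <- problem
    prob_c$sign_sus <- combos$ss[ci]
    prob_c$sign_trans <- combos$st[ci]
    free <- .free_names(prob_c)
    guesses <- if (budget[ci] > 0) {
      initial_guesses(prob_c, budget[ci], seed = .derive_seed(seed, ci))
    } else {
      matrix(numeric(0), 0, length(free), dimnames = list(NULL, free))
    }
    if (!is.null(warm_start)) {
      w <- pmin(pmax(warm_start[free], prob_c$lb[free]), prob_c$ub[free])
      guesses <- rbind(matrix(w, 1, dimnames = list(NULL, free)), guesses)
    }
    starts <- c(starts, .run_starts(prob_c, guesses, control))
  }
  if (!is.null(res_old)) starts <- c(res_old$starts, starts)

  ok <- vapply(starts, function(s) is.finite(s$value), logical(1))
  if (!any(ok)) {
    diag <- vapply(starts, function(s) s$message %||% "non-finite objective", character(1))
    stop("all optimization starts failed:\n  ", paste(unique(diag), collapse = "\n  "),
         call. = FALSE)
  }
  best_i <- which(ok)[which.min(vapply(starts[ok], `[[`, numeric(1), "value"))]
  best_s <- starts[[best_i]]

  prob_best <- problem
  prob_best$sign_sus <- best_s$sign_sus
  prob_best$sign_trans <- best_s$sign_trans

  # seeded basin hopping around the incumbent best
  if (basin_hops > 0) {
    hopped <- .basin_hop(prob_best, best_s, basin_hops,
                         .derive_seed(seed, 7L), control)
    if (length(hopped)) {
      starts <- c(starts, hopped)
      vals <- vapply(hopped, `[[`, numeric(1), "value")
      if (min(vals) < best_s$value) best_s <- hopped[[which.min(vals)]]
    }
  }

  # profile update of sigma at the best fit, then one polishing run
  if (problem$sigma_free && !"sigma" %in% names(problem$fixed)) {
    polished <- .polish_sigma(prob_best, best_s, control)
    if (!is.null(polished)) {
      starts <- c(starts, list(polished))
      if (polished$value < best_s$value) best_s <- polished
    }
  }

  best <- .full_theta(best_s$par, prob_best)
  fitted_vals <- .model_values(best, prob_best, prob_best$sign_sus, prob_best$sign_trans)
  res <- structure(list(
    problem = prob_best,
    best = best,
    value = neg2_log_likelihood(best, prob_best),
    fitted = fitted_vals,
    residuals = prob_best$data$y - fitted_vals,
    starts = starts,
    sign_sus = prob_best$sign_sus,
    sign_trans = prob_best$sign_trans,
    n_starts = length(starts),
    seed = seed
  ), class = "rtf_fit")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_starts <- function(problem, guesses, control) {
  free <- colnames(guesses)
  lo <- .to_x(problem$lb[free], problem)
  hi <- .to_x(problem$ub[free], problem)
  funs <- .make_optim_funs(problem)
  fn <- funs$fn
  gr <- funs$gr
  lapply(seq_len(nrow(guesses)), function(i) {
    x0 <- .to_x(guesses[i, ], problem)
    o <- tryCatch(
      stats::optim(x0, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = control),
      error = function(e) NULL
    )
    if (is.null(o)) {
      list(x0 = guesses[i, ], par = guesses[i, ], value = Inf,
           converged = FALSE, message = "optim error",
           sign_sus = problem$sign_sus, sign_trans = problem$sign_trans)
    } else {
      list(x0 = guesses[i, ], par = .from_x(o$par, problem, free),
           value = o$value, converged = o$convergence == 0,
           message = o$message,
           sign_sus = problem$sign_sus, sign_trans = problem$sign_trans)
    }
  })
}

.basin_hop <- function(problem, best_s, n_hops, seed, control) {
  free <- names(best_s$par)
  lo <- .to_x(problem$lb[free], problem)
  hi <- .to_x(problem$ub[free], problem)
  out <- list()
  incumbent <- best_s
  set.seed(seed)
  amps <- rep(c(0.1, 0.25, 0.5), length.out = n_hops)
  for (r in seq_len(n_hops)) {
    x <- .to_x(incumbent$par, problem)
    if (r %% 2L == 1L || length(x) < 2L) {
      # local hop: Gaussian perturbation of every coordinate
      x2 <- pmin(pmax(x + stats::rnorm(length(x), 0, amps[r] * (hi - lo)), lo), hi)
    } else {
      # exploratory hop: re-draw a few coordinates uniformly in their box
      x2 <- x
      k <- sample(2:min(4L, length(x)), 1)
      idx <- sample(length(x), k)
      x2[idx] <- stats::runif(k, lo[idx], hi[idx])
    }
    g <- matrix(.from_x(x2, problem, free), 1, dimnames = list(NULL, free))
    o <- .run_starts(problem, g, control)[[1]]
    out[[length(out) + 1L]] <- o
    if (is.finite(o$value) && o$value < incumbent$value) incumbent <- o
  }
  out
}

.polish_sigma <- function(problem, best_s, control) {
  theta <- .full_theta(best_s$par, problem)
  r <- problem$data$y - .model_values(theta, problem, problem$sign_sus, problem$sign_trans)
  s_hat <- sqrt(mean(r^2))
  s_hat <- min(max(s_hat, problem$lb[["sigma"]] * 1.000001), problem$ub[["sigma"]])
  theta[["sigma"]] <- s_hat
  free <- .free_names(problem)
  guesses <- matrix(theta[free], 1, dimnames = list(NULL, free))
  out <- .run_starts(problem, guesses, control)[[1]]
  if (!is.finite(out$value)) return(NULL)
  # the profile point itself may already beat the polished end point
  v0 <- neg2_log_likelihood(theta, problem)
  if (v0 < out$value) {
    out$par <- theta[free]
    out$value <- v0
    out$converged <- TRUE
  }
  out
}

#' @export
print.rtf_fit <- function(x, ...) {
  cat(sprintf("RTF fit (%s), -2 ln L = %.6g, %d starts (%d converged)\n",
              x$problem$mode, x$value, length(x$starts),
              sum(vapply(x$starts, `[[`, logical(1), "converged"))))
  cat(sprintf("  signs: sustained %+d, transient %+d\n", x$sign_sus, x$sign_trans))
  print(round(x$best, 5))
  invisible(x)
}

#' @export
coef.rtf_fit <- function(object, ...) object$best

#' @export
residuals.rtf_fit <- function(object, ...) object$residuals

#' @export
fitted.rtf_fit <- function(object, ...) object$fitted

#' Sorted multi-start objective values (waterfall)
#'
#' @param fit An [rtf_fit].
#' @return Numeric vector of final objective values, sorted increasingly;
#'   a plateau at the minimum indicates the global optimum was found
#'   repeatedly.
#' @export
waterfall_values <- function(fit) {
  stopifnot(inherits(fit, "rtf_fit"))
  sort(vapply(fit$starts, `[[`, numeric(1), "value"))
}

#' Predict from a fitted RTF
#'
#' Evaluates the fitted model at new time points, and in dose-dependent
#' mode at the cartesian product of `times` and `doses`, using the time
#' range `T` of the training data.
#'
#' @param object An [rtf_fit].
#' @param times Numeric vector of real times.
#' @param doses Doses (required in `doseDependent` mode, disallowed in
#'   `singleDose` mode).
#' @param ... Unused.
#' @return `singleDose`: numeric vector along `times`. `doseDependent`: a
#'   data.frame with columns `t`, `d`, `y`.
#' @export
predict.rtf_fit <- function(object, times, doses = NULL, ...) {
  problem <- object$problem
  if (problem$mode == "singleDose") {
    if (!is.null(doses)) {
      stop("`doses` supplied but the fit is singleDose", call. = FALSE)
    }
    fake <- problem
    fake$data <- data.frame(t = times, y = numeric(length(times)))
    .model_values(object$best, fake, object$sign_sus, object$sign_trans)
  } else {
    if (is.null(doses)) {
      stop("`doses` is required for a doseDependent fit", call. = FALSE)
    }
    grid <- expand.grid(t = times, d = doses, KEEP.OUT.ATTRS = FALSE)
    y <- .dose_rtf_values(object$best, grid$t, grid$d,
                          object$sign_sus, object$sign_trans, problem$T)
    data.frame(t = grid$t, d = grid$d, y = y)
  }
}
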