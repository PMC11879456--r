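# Maximum-likelihood objective and optimization problem setup.
#
# The central structure is the `rtf_problem`, mirroring how bounded
# ML fitting problems are usually carried around: the data, the ordered
# parameter names, data-derived default initial guess, lower/upper bounds, a
# set of fixed parameters, a log10 mask for parameters that optimize better
# on log scale, the mode (singleDose / doseDependent) and the component
# signs (+1, -1, or "auto").

SINGLE_PARAM_NAMES <- c("A", "B", "alpha", "beta", "gamma", "tau", "b")

.derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 1009 + a * 97 + b * 13) %% 2147483629) + 1L
}

.validate_timecourse <- function(data, mode) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  for (nm in c("t", "y")) {
    if (!nm %in% names(data)) {
      stop("data must contain a column named `", nm, "`", call. = FALSE)
    }
    if (!is.numeric(data[[nm]]) || anyNA(data[[nm]])) {
      stop("column `", nm, "` must be numeric with no missing values", call. = FALSE)
    }
  }
  if (nrow(data) < 3L) stop("need at least 3 data points", call. = FALSE)
  if (length(unique(data$t)) < 2L) {
    stop("need at least 2 distinct time points (time range must be > 0)", call. = FALSE)
  }
  if ("sigmaExp" %in% names(data)) {
    if (!is.numeric(data$sigmaExp) || anyNA(data$sigmaExp) || any(data$sigmaExp <= 0)) {
      stop("`sigmaExp` must be numeric and > 0 for every point", call. = FALSE)
    }
  }
  if (mode == "doseDependent") {
    if (!"d" %in% names(data)) {
      stop("mode 'doseDependent' requires a dose column `d`", call. = FALSE)
    }
    if (!is.numeric(data$d) || anyNA(data$d) || any(data$d < 0)) {
      stop("column `d` must be numeric and >= 0", call. = FALSE)
    }
    if (length(unique(data$d)) < 2L) {
      stop("mode 'doseDependent' requires at least 2 distinct doses", call. = FALSE)
    }
  }
  invisible(data)
}

# Data-derived default initial guess (natural scale, all parameters).
# b starts at min(y) for an upward sustained component, at the median when
# the sustained sign is known to be negative.
.default_guess <- function(problem, sign_sus = 1) {
  data <- problem$data
  y <- data$y[order(data$t)]
  ry <- max(diff(range(y)), .Machine$double.eps)
  b0 <- if (identical(sign_sus, -1)) stats::median(y) else min(y)
  A0 <- abs(y[length(y)] - y[1])
  B0 <- max(abs(y - y[1]))
  g <- c(A = A0, B = B0, alpha = 1, beta = 1, gamma = 1, tau = 0, b = b0,
         sigma = 0.1 * ry)
  if (problem$mode == "doseDependent") {
    dpos <- data$d[data$d > 0]
    K0 <- if (length(dpos)) stats::median(unique(dpos)) else 1
    g <- c(M_A = A0, h_A = 1, K_A = K0,
           M_B = B0, h_B = 1, K_B = K0,
           M_alpha = 1, h_alpha = 1, K_alpha = K0,
           M_beta = 1, h_beta = 1, K_beta = K0,
           M_gamma = 1, h_gamma = 1, K_gamma = K0,
           M_tau = 1, h_tau = 1, K_tau = K0,
           b = b0, sigma = 0.1 * ry)
  }
  g <- g[problem$param_names]
  # clamp into bounds, keeping log10 parameters strictly positive
  lo <- problem$lb + ifelse(problem$take_log10, abs(problem$lb) * 1e-6, 0)
  pmin(pmax(g, lo), problem$ub)
}

#' Set up an RTF optimization problem
#'
#' Builds the container holding everything a fit needs: validated data,
#' ordered parameter names, data-derived default initial guess, lower and
#' upper bounds, fixed parameters, the log10 mask, and component signs.
#' When the data carry a `sigmaExp` column the measurement error is treated
#' as known and no `sigma` parameter is created; otherwise `sigma` is
#' estimated jointly with the kinetic parameters.
#'
#' Default bounds are scale-free in the data's units (`ry = max(y) - min(y)`,
#' transformed time spans about 10): amplitudes in `[0, 2 ry]`, rates in
#' `[1e-2, 1e2]` (log10), `tau` in `[-2, max(t) * 10 / T]`, offset in
#' `[min(y) - ry, max(y) + ry]`, `sigma` in `[1e-4 ry, ry]` (log10), Hill
#' `h` in `[0.1, 10]` (log10), Hill `K` spanning the observed dose range
#' (log10). All are overridable via `lb` / `ub`.
#'
#' @param data A data.frame with numeric columns `t` and `y`, optionally `d`
#'   (dose) and `sigmaExp` (known per-point standard error).
#' @param mode `"singleDose"` or `"doseDependent"`.
#' @param sign_sus,sign_trans Component signs: `+1`, `-1`, or `"auto"`
#'   (enumerated during fitting).
#' @param fixed Optional named numeric vector of parameters to hold fixed.
#' @param lb,ub Optional named numeric vectors overriding individual default
#'   bounds.
#' @return An object of class `rtf_problem`.
#' @examples
#' d <- sim_timecourse(seed = 1)
#' rtf_problem(d)
#' @export
rtf_problem <- function(data, mode = c("singleDose", "doseDependent"),
                        sign_sus = "auto", sign_trans = "auto",
                        fixed = NULL, lb = NULL, ub = NULL) {
  mode <- match.arg(mode)
  .validate_timecourse(data, mode)
  for (s in list(sign_sus, sign_trans)) {
    if (!(identical(s, "auto") || (is.numeric(s) && s %in% c(-1, 1)))) {
      stop("signs must be +1, -1 or \"auto\"", call. = FALSE)
    }
  }
  y <- data$y
  ry <- diff(range(y))
  if (ry == 0) {
    warning("all y values are identical; expect A and B near 0", call. = FALSE)
    ry <- max(abs(y[1]), 1)
  }
  T <- diff(range(data$t))
  tau_ub <- max(max(data$t) * 10 / T, 2)
  sigma_free <- !("sigmaExp" %in% names(data))

  if (mode == "singleDose") {
    pn <- SINGLE_PARAM_NAMES
    lbv <- c(A = 0, B = 0, alpha = 1e-2, beta = 1e-2, gamma = 1e-2,
             tau = -2, b = min(y) - ry)
    ubv <- c(A = 2 * ry, B = 2 * ry, alpha = 1e2, beta = 1e2, gamma = 1e2,
             tau = tau_ub, b = max(y) + ry)
    lg <- c(A = FALSE, B = FALSE, alpha = TRUE, beta = TRUE, gamma = TRUE,
            tau = FALSE, b = FALSE)
  } else {
    pn <- c(DOSE_HILL_NAMES, "b")
    dpos <- data$d[data$d > 0]
    if (!length(dpos)) stop("doseDependent mode needs at least one positive dose", call. = FALSE)
    k_lb <- min(dpos) / 10
    k_ub <- 10 * max(data$d)
    lbv <- ubv <- numeric(0)
    lg <- logical(0)
    amp <- c(A = TRUE, B = TRUE, alpha = FALSE, beta = FALSE, gamma = FALSE, tau = TRUE)
    for (nm in c("A", "B", "alpha", "beta", "gamma", "tau")) {
      if (nm == "tau") {
        mlb <- 0; mub <- tau_ub; mlog <- FALSE
      } else if (amp[[nm]]) {
        mlb <- 0; mub <- 2 * ry; mlog <- FALSE
      } else {
        mlb <- 1e-2; mub <- 1e2; mlog <- TRUE
      }
      lbv <- c(lbv, stats::setNames(c(mlb, 0.1, k_lb), paste(c("M", "h", "K"), nm, sep = "_")))
      ubv <- c(ubv, stats::setNames(c(mub, 10, k_ub), paste(c("M", "h", "K"), nm, sep = "_")))
      lg <- c(lg, stats::setNames(c(mlog, TRUE, TRUE), paste(c("M", "h", "K"), nm, sep = "_")))
    }
    lbv <- c(lbv, b = min(y) - ry)
    ubv <- c(ubv, b = max(y) + ry)
    lg <- c(lg, b = FALSE)
  }
  if (sigma_free) {
    pn <- c(pn, "sigma")
    lbv <- c(lbv, sigma = 1e-4 * ry)
    ubv <- c(ubv, sigma = ry)
    lg <- c(lg, sigma = TRUE)
  }
  lbv <- lbv[pn]; ubv <- ubv[pn]; lg <- lg[pn]

  if (!is.null(lb)) {
    bad <- setdiff(names(lb), pn)
    if (length(bad)) stop("unknown parameter(s) in `lb`: ", paste(bad, collapse = ", "), call. = FALSE)
    lbv[names(lb)] <- lb
  }
  if (!is.null(ub)) {
    bad <- setdiff(names(ub), pn)
    if (length(bad)) stop("unknown parameter(s) in `ub`: ", paste(bad, collapse = ", "), call. = FALSE)
    ubv[names(ub)] <- ub
  }
  fixedv <- numeric(0)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), pn)
    if (length(bad)) stop("unknown parameter(s) in `fixed`: ", paste(bad, collapse = ", "), call. = FALSE)
    fixedv <- unlist(fixed)
  }
  free <- setdiff(pn, names(fixedv))
  if (any(lbv[free] >= ubv[free])) {
    stop("lower bounds must be strictly below upper bounds for free parameters", call. = FALSE)
  }
  if (any(lg[free] & lbv[free] <= 0)) {
    stop("log10-scaled free parameters need a positive lower bound", call. = FALSE)
  }

  problem <- structure(list(
    data = data, mode = mode, param_names = pn,
    lb = lbv, ub = ubv, take_log10 = lg, fixed = fixedv,
    sign_sus = sign_sus, sign_trans = sign_trans,
    sigma_free = sigma_free, T = T
  ), class = "rtf_problem")
  problem$initial_guess <- .default_guess(problem,
                                          if (identical(sign_sus, -1)) -1 else 1)
  problem
}

#' @export
print.rtf_problem <- function(x, ...) {
  cat(sprintf("RTF optimization problem (%s), %d data points\n",
              x$mode, nrow(x$data)))
  cat(sprintf("  time range T = %.4g; sigma %s\n", x$T,
              if (x$sigma_free) "estimated jointly" else "from sigmaExp"))
  free <- setdiff(x$param_names, names(x$fixed))
  cat(sprintf("  free parameters (%d): %s\n", length(free), paste(free, collapse = ", ")))
  if (length(x$fixed)) {
    cat("  fixed:", paste(sprintf("%s=%.4g", names(x$fixed), x$fixed), collapse = ", "), "\n")
  }
  invisible(x)
}

.free_names <- function(problem) setdiff(problem$param_names, names(problem$fixed))

.resolve_signs <- function(problem) {
  ss <- problem$sign_sus; st <- problem$sign_trans
  if (identical(ss, "auto") || identical(st, "auto")) {
    stop("component signs are \"auto\"; resolve them (e.g. via rtf_fit) before ",
         "evaluating the objective", call. = FALSE)
  }
  c(ss, st)
}

# model values at a full natural-scale named parameter vector
.model_values <- function(theta, problem, sign_sus, sign_trans) {
  if (problem$mode == "singleDose") {
    t <- time_transform(problem$data$t, theta[["tau"]], problem$T)
    sign_sus * theta[["A"]] * (1 - exp(-theta[["alpha"]] * t)) +
      sign_trans * theta[["B"]] * (1 - exp(-theta[["beta"]] * t)) *
        exp(-theta[["gamma"]] * t) +
      theta[["b"]]
  } else {
    .dose_rtf_values(theta, problem$data$t, problem$data$d,
                     sign_sus, sign_trans, problem$T)
  }
}

.model_gradient <- function(theta, problem, sign_sus, sign_trans) {
  if (problem$mode == "singleDose") {
    p <- structure(list(A = theta[["A"]], B = theta[["B"]],
                        alpha = theta[["alpha"]], beta = theta[["beta"]],
                        gamma = theta[["gamma"]], tau = theta[["tau"]],
                        b = theta[["b"]], sign_sus = sign_sus,
                        sign_trans = sign_trans, sigma = NULL),
                   class = "rtf_params")
    rtf_gradient(p, problem$data$t, problem$T)
  } else {
    .dose_rtf_gradient(theta, problem$data$t, problem$data$d,
                       sign_sus, sign_trans, problem$T)
  }
}

.sigma_vector <- function(theta, problem) {
  if (problem$sigma_free) {
    s <- theta[["sigma"]]
    if (!is.finite(s) || s <= 0) stop("sigma must be > 0", call. = FALSE)
    rep(s, nrow(problem$data))
  } else {
    problem$data$sigmaExp
  }
}

#' Twice the negative Gaussian log-likelihood of an RTF parameter vector
#'
#' The minimized objective is
#' \deqn{-2 \ln L = \sum_i \left[ \ln(2\pi\sigma_i^2) +
#'   \Delta_i^2/\sigma_i^2 \right]}
#' where \eqn{\Delta_i} is the residual of point `i` and \eqn{\sigma_i}
#' comes from the `sigmaExp` column when present, otherwise from the free
#' `sigma` parameter in `theta`.
#'
#' @param theta Full named parameter vector on the natural scale (all of
#'   `problem$param_names`, including any fixed entries).
#' @param problem An [rtf_problem] with resolved (non-"auto") signs.
#' @return The scalar objective value.
#' @export
neg2_log_likelihood <- function(theta, problem) {
  stopifnot(inherits(problem, "rtf_problem"))
  sg <- .resolve_signs(problem)
  theta <- theta[problem$param_names]
  r <- problem$data$y - .model_values(theta, problem, sg[1], sg[2])
  s <- .sigma_vector(theta, problem)
  sum(log(2 * pi * s^2) + (r / s)^2)
}

#' Analytic gradient of the fitting objective
#'
#' Gradient of [neg2_log_likelihood] with respect to the free parameters,
#' obtained through the analytic model gradients ([rtf_gradient] /
#' [dose_gradient]) rather than finite differences. With `transformed =
#' TRUE` (the scale the optimizer works on) the chain factor
#' \eqn{\theta \ln 10} is applied to log10-scaled parameters.
#'
#' @inheritParams neg2_log_likelihood
#' @param transformed Return the gradient on the optimizer scale (log10 for
#'   masked parameters)?
#' @return Named numeric vector over the free parameters.
#' @export
objective_gradient <- function(theta, problem, transformed = TRUE) {
  stopifnot(inherits(problem, "rtf_problem"))
  sg <- .resolve_signs(problem)
  theta <- theta[problem$param_names]
  r <- problem$data$y - .model_values(theta, problem, sg[1], sg[2])
  s <- .sigma_vector(theta, problem)
  G <- .model_gradient(theta, problem, sg[1], sg[2])
  g <- colSums((-2 * r / s^2) * G)
  if (problem$sigma_free) {
    n <- length(r)
    g <- c(g, sigma = 2 * n / s[1] - 2 * sum(r^2) / s[1]^3)
  }
  g <- g[.free_names(problem)]
  if (transformed) {
    lg <- problem$take_log10[.free_names(problem)]
    g[lg] <- g[lg] * theta[names(g)[lg]] * LN10
  }
  g
}

# optimizer-space packing: x holds free parameters, log10 where masked
.to_x <- function(theta_free, problem) {
  lg <- problem$take_log10[names(theta_free)]
  x <- theta_free
  x[lg] <- log10(theta_free[lg])
  x
}

.from_x <- function(x, problem, free) {
  lg <- problem$take_log10[free]
  th <- x
  th[lg] <- 10^x[lg]
  names(th) <- free
  th
}

.full_theta <- function(theta_free, problem) {
  th <- stats::setNames(numeric(length(problem$param_names)), problem$param_names)
  th[names(problem$fixed)] <- problem$fixed
  th[names(theta_free)] <- theta_free
  th
}

# Fused objective/gradient closures for the optimizer hot path: one
# time-transform evaluation shared between model values and gradient, no
# name-based lookups per call, no condition handling (the arithmetic is
# total on the feasible box).
.make_optim_funs <- function(problem) {
  data <- problem$data
  y <- data$y
  n <- length(y)
  Tt <- problem$T
  u <- data$t * 10 / Tt
  sS <- problem$sign_sus
  sT <- problem$sign_trans
  pn <- problem$param_names
  free <- setdiff(pn, names(problem$fixed))
  template <- stats::setNames(numeric(length(pn)), pn)
  template[names(problem$fixed)] <- problem$fixed
  fidx <- match(free, pn)
  lg <- unname(problem$take_log10[free])
  sigma_free <- problem$sigma_free
  sigmaExp <- if (!sigma_free) data$sigmaExp
  si <- match("sigma", pn)
  single <- problem$mode == "singleDose"
  if (single) {
    ii <- match(c("A", "B", "alpha", "beta", "gamma", "tau", "b"), pn)
  } else {
    dvec <- data$d
    gcols <- c(DOSE_HILL_NAMES, "b")
    gidx <- match(gcols, pn)
  }
  L <- function(z) pmax(z, 0) + log1p(10^(-abs(z))) / LN10

  expand <- function(x) {
    th <- x
    th[lg] <- 10^x[lg]
    full <- template
    full[fidx] <- th
    full
  }
  single_model <- function(full) {
    tv <- u + L(full[ii[6]] - u) - L(full[ii[6]])
    eA <- exp(-full[ii[3]] * tv)
    eB <- exp(-full[ii[4]] * tv)
    eG <- exp(-full[ii[5]] * tv)
    list(m = sS * full[ii[1]] * (1 - eA) + sT * full[ii[2]] * (1 - eB) * eG +
           full[ii[7]],
         tv = tv, eA = eA, eB = eB, eG = eG)
  }
  fn <- function(x) {
    full <- expand(x)
    m <- if (single) single_model(full)$m else {
      .dose_rtf_values(full, data$t, dvec, sS, sT, Tt)
    }
    r <- y - m
    s <- if (sigma_free) full[si] else sigmaExp
    v <- sum(log(2 * pi * s^2) + (r / s)^2)
    if (is.finite(v)) v else 1e12
  }
  gr <- function(x) {
    full <- expand(x)
    if (single) {
      sm <- single_model(full)
      A <- full[ii[1]]; B <- full[ii[2]]
      al <- full[ii[3]]; be <- full[ii[4]]; ga <- full[ii[5]]
      tau <- full[ii[6]]
      dt_dtau <- stats::plogis(LN10 * (tau - u)) - stats::plogis(LN10 * tau)
      dR_dt <- sS * A * al * sm$eA +
        sT * B * (be * sm$eB - ga * (1 - sm$eB)) * sm$eG
      G <- cbind(sS * (1 - sm$eA),
                 sT * (1 - sm$eB) * sm$eG,
                 sS * A * sm$tv * sm$eA,
                 sT * B * sm$tv * sm$eB * sm$eG,
                 -sT * B * (1 - sm$eB) * sm$tv * sm$eG,
                 dR_dt * dt_dtau,
                 rep(1, n))
      m <- sm$m
      gidx_use <- ii
    } else {
      m <- .dose_rtf_values(full, data$t, dvec, sS, sT, Tt)
      G <- .dose_rtf_gradient(full, data$t, dvec, sS, sT, Tt)
      gidx_use <- gidx
    }
    r <- y - m
    s <- if (sigma_free) full[si] else sigmaExp
    gfull <- stats::setNames(numeric(length(pn)), pn)
    gfull[gidx_use] <- colSums((-2 * r / s^2) * G)
    if (sigma_free) gfull[si] <- 2 * n / s[1] - 2 * sum(r^2) / s[1]^3
    g <- gfull[fidx]
    g[lg] <- g[lg] * full[fidx][lg] * LN10
    g[!is.finite(g)] <- 0
    g
  }
  list(fn = fn, gr = gr, free = free)
}

#' Generate multi-start initial guesses
#'
#' The first guess is the data-derived default; the remainder are a seeded
#' Latin-hypercube sample of the free-parameter box, drawn log10-uniformly
#' for log10-masked parameters.
#'
#' @param problem An [rtf_problem].
#' @param n_starts Number of guesses (>= 1).
#' @param seed Integer seed; the same seed reproduces the same guesses.
#' @return Matrix `n_starts x n_free` of natural-scale guesses (columns are
#'   the free parameters).
#' @export
initial_guesses <- function(problem, n_starts, seed = 1) {
  stopifnot(inherits(problem, "rtf_problem"), n_starts >= 1)
  free <- .free_names(problem)
  sign_sus <- if (identical(problem$sign_sus, -1)) -1 else 1
  g0 <- .default_guess(problem, sign_sus)[free]
  out <- matrix(NA_real_, n_starts, length(free), dimnames = list(NULL, free))
  out[1, ] <- g0
  if (n_starts > 1L) {
    lo <- .to_x(problem$lb[free], problem)
    hi <- .to_x(problem$ub[free], problem)
    set.seed(seed)
    u <- lhs::randomLHS(n_starts - 1L, length(free))
    xs <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
    for (i in seq_len(n_starts - 1L)) {
      out[i + 1L, ] <- .from_x(xs[i, ], problem, free)
    }
  }
  out
}
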