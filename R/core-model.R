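# Core evaluation of the retarded transient function (RTF) and its analytic
# partial derivatives. Everything here is pure: no data handling, no fitting.

LN10 <- log(10)

# log10(1 + 10^z), overflow-safe for any finite z
.log10_1p_pow10 <- function(z) {
  pmax(z, 0) + log1p(10^(-abs(z))) / LN10
}

#' Retarded time transform
#'
#' Maps real (experimental) time onto the transformed time axis on which the
#' RTF rate constants act. The transform
#' \deqn{t(t_{real}, \tau) = \log_{10}(10^{t_{real} \cdot 10/T} + 10^\tau) -
#'   \log_{10}(1 + 10^\tau)}
#' compresses early times by an amount controlled by the time-shift parameter
#' \eqn{\tau}, producing the delayed ("retarded") onset typical of signalling
#' responses. For \eqn{\tau \to -\infty} it approaches the linear rescaling
#' \eqn{t_{real} \cdot 10 / T}; larger \eqn{\tau} delays the response further.
#'
#' @param treal Numeric vector of real measurement times.
#' @param tau Time-shift parameter (scalar or vector recycled against
#'   `treal`); dimensionless, any finite real.
#' @param T Range of the experimental measurement times,
#'   `max(treal) - min(treal)` of the fitted dataset; must be > 0.
#' @return Numeric vector of transformed times; `0` at `treal = 0` exactly,
#'   strictly increasing in `treal`.
#' @examples
#' time_transform(c(0, 5, 10), tau = 1, T = 10)
#' @export
time_transform <- function(treal, tau, T) {
  if (!is.numeric(treal) || !all(is.finite(treal))) {
    stop("`treal` must be a finite numeric vector", call. = FALSE)
  }
  if (!is.numeric(tau) || !all(is.finite(tau))) {
    stop("`tau` must be finite", call. = FALSE)
  }
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("`T` (time range) must be a single positive number", call. = FALSE)
  }
  u <- treal * 10 / T
  u + .log10_1p_pow10(tau - u) - .log10_1p_pow10(tau)
}

# d t / d tau, same recycling rules as time_transform
.time_transform_dtau <- function(treal, tau, T) {
  u <- treal * 10 / T
  stats::plogis(LN10 * (tau - u)) - stats::plogis(LN10 * tau)
}

#' Construct a single-dose RTF parameter set
#'
#' Bundles the parameters of the single-dose RTF: sustained amplitude `A` and
#' rate `alpha`, transient amplitude `B` with rise rate `beta` and decay rate
#' `gamma`, time-shift `tau`, offset `b`, component signs, and optionally the
#' noise standard deviation `sigma` (present when the measurement error is
#' estimated from the data rather than supplied).
#'
#' Rates act on the transformed time axis (range about \[0, 10\]), so they are
#' expressed per transformed-time unit.
#'
#' @param A,B Non-negative amplitudes (signal units).
#' @param alpha,beta,gamma Positive rate constants (1/transformed time).
#' @param tau Time-shift parameter (dimensionless).
#' @param b Offset (signal units).
#' @param sign_sus,sign_trans Signs of the sustained and transient component,
#'   each `+1` or `-1`.
#' @param sigma Optional noise standard deviation (> 0).
#' @return An object of class `rtf_params`.
#' @examples
#' rtf_params(A = 1, B = 1, alpha = 1, beta = 2, gamma = 0.5, tau = 0.5, b = 0.2)
#' @export
rtf_params <- function(A, B, alpha, beta, gamma, tau, b,
                       sign_sus = 1, sign_trans = 1, sigma = NULL) {
  p <- list(A = A, B = B, alpha = alpha, beta = beta, gamma = gamma,
            tau = tau, b = b, sign_sus = sign_sus, sign_trans = sign_trans,
            sigma = sigma)
  validate_rtf_params(p)
  class(p) <- "rtf_params"
  p
}

validate_rtf_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("A", "B", "alpha", "beta", "gamma", "tau", "b")) {
    if (!num1(p[[nm]])) stop("parameter `", nm, "` must be a finite scalar", call. = FALSE)
  }
  if (p$A < 0 || p$B < 0) stop("amplitudes A and B must be >= 0", call. = FALSE)
  if (p$alpha <= 0 || p$beta <= 0 || p$gamma <= 0) {
    stop("rates alpha, beta, gamma must be > 0", call. = FALSE)
  }
  if (!p$sign_sus %in% c(-1, 1) || !p$sign_trans %in% c(-1, 1)) {
    stop("sign_sus and sign_trans must be exactly +1 or -1", call. = FALSE)
  }
  if (!is.null(p$sigma) && (!num1(p$sigma) || p$sigma <= 0)) {
    stop("sigma must be > 0 when present", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.rtf_params <- function(x, ...) {
  cat("Single-dose RTF parameters\n")
  cat(sprintf("  sustained: %+d * %.4g (1 - exp(-%.4g t))\n", x$sign_sus, x$A, x$alpha))
  cat(sprintf("  transient: %+d * %.4g (1 - exp(-%.4g t)) exp(-%.4g t)\n",
              x$sign_trans, x$B, x$beta, x$gamma))
  cat(sprintf("  tau = %.4g, offset b = %.4g", x$tau, x$b))
  if (!is.null(x$sigma)) cat(sprintf(", sigma = %.4g", x$sigma))
  cat("\n")
  invisible(x)
}

#' Evaluate the RTF at real times
#'
#' Computes
#' \deqn{R(t) = sign_{sus} A (1 - e^{-\alpha t}) +
#'   sign_{trans} B (1 - e^{-\beta t}) e^{-\gamma t} + b}
#' with \eqn{t = } [time_transform]`(treal, tau, T)`.
#'
#' @param params An [rtf_params] object.
#' @param treal Numeric vector of real times.
#' @param T Time range used for the transform (see [time_transform]).
#' @return Numeric vector of model responses.
#' @examples
#' p <- rtf_params(A = 1, B = 1, alpha = 1, beta = 2, gamma = 0.5,
#'                 tau = 0.5, b = 0.2)
#' rtf_evaluate(p, seq(0, 10, length.out = 5), T = 10)
#' @export
rtf_evaluate <- function(params, treal, T) {
  validate_rtf_params(params)
  cmp <- rtf_components(params, treal, T)
  cmp$sustained + cmp$transient + cmp$offset
}

#' Decompose the RTF into sustained and transient parts
#'
#' @inheritParams rtf_evaluate
#' @return A list with elements `sustained`, `transient` (vectors matching
#'   `treal`) and the scalar `offset`; their sum reproduces [rtf_evaluate]
#'   exactly.
#' @export
rtf_components <- function(params, treal, T) {
  validate_rtf_params(params)
  t <- time_transform(treal, params$tau, T)
  sus <- params$sign_sus * params$A * (1 - exp(-params$alpha * t))
  trans <- params$sign_trans * params$B * (1 - exp(-params$beta * t)) *
    exp(-params$gamma * t)
  list(sustained = sus, transient = trans, offset = params$b)
}

#' Analytic gradient of the RTF
#'
#' Partial derivatives of the model response with respect to
#' `A, B, alpha, beta, gamma, tau, b`, derived in closed form (the tau column
#' goes through the chain rule of the time transform). Used by the optimizer
#' instead of finite differences.
#'
#' @inheritParams rtf_evaluate
#' @return Numeric matrix `length(treal) x 7` with columns named
#'   `A, B, alpha, beta, gamma, tau, b`.
#' @export
rtf_gradient <- function(params, treal, T) {
  validate_rtf_params(params)
  sS <- params$sign_sus; sT <- params$sign_trans
  t <- time_transform(treal, params$tau, T)
  eA <- exp(-params$alpha * t)
  eB <- exp(-params$beta * t)
  eG <- exp(-params$gamma * t)
  dt_dtau <- .time_transform_dtau(treal, params$tau, T)
  # dR/dt for the tau chain rule
  dR_dt <- sS * params$A * params$alpha * eA +
    sT * params$B * (params$beta * eB - params$gamma * (1 - eB)) * eG
  g <- cbind(
    A     = sS * (1 - eA),
    B     = sT * (1 - eB) * eG,
    alpha = sS * params$A * t * eA,
    beta  = sT * params$B * t * eB * eG,
    gamma = -sT * params$B * (1 - eB) * t * eG,
    tau   = dR_dt * dt_dtau,
    b     = rep(1, length(t))
  )
  g
}
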