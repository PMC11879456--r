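# Hill dose-response parameterization of the RTF: each kinetic parameter of
# the single-dose model becomes a function of dose through an (M, h, K)
# triple. Amplitudes and rates increase with dose via the standard Hill
# curve; the time shift tau decreases via the reversed Hill curve
# tau(d) = M K^h / (K^h + d^h), so tau(0) = M and tau(Inf) = 0.

RATE_FLOOR <- 1e-10

#' Hill dose-response curve
#'
#' \deqn{H(d) = M d^h / (K^h + d^h)}
#' with maximum `M`, Hill coefficient `h` (sigmoidality) and half-maximal
#' dose `K` (the EC50).
#'
#' @param d Dose(s), >= 0.
#' @param M Maximum value (> 0 in a free fit; 0 is allowed and gives a
#'   constant zero curve, used when a dose dependence has been eliminated).
#' @param h Hill coefficient (> 0).
#' @param K Half-maximal dose (> 0).
#' @return `H(d)`, in `[0, M)`, non-decreasing in `d`; `H(K) = M/2`.
#' @examples
#' hill(c(0, 3, 30), M = 4, h = 2, K = 3)
#' @export
hill <- function(d, M, h, K) {
  if (any(d < 0)) stop("doses must be >= 0", call. = FALSE)
  if (M < 0 || h <= 0 || K <= 0) {
    stop("Hill triple must satisfy M >= 0, h > 0, K > 0", call. = FALSE)
  }
  dh <- d^h
  M * dh / (K^h + dh)
}

#' Construct a dose-dependent RTF parameter set
#'
#' The dose-dependent RTF replaces each of `A, B, alpha, beta, gamma, tau`
#' by a Hill curve in dose: `A, B, alpha, beta, gamma` by [hill] (increasing
#' in dose) and `tau` by the reversed Hill curve `M K^h/(K^h + d^h)`
#' (decreasing in dose), for 18 dose parameters plus the offset.
#'
#' @param hill_A,hill_B,hill_alpha,hill_beta,hill_gamma,hill_tau Numeric
#'   vectors `c(M, h, K)` (names optional, order fixed).
#' @param b Offset (signal units).
#' @param sign_sus,sign_trans Component signs, `+1` or `-1`.
#' @param sigma Optional noise standard deviation (> 0).
#' @return An object of class `dose_rtf_params`.
#' @examples
#' dose_rtf_params(hill_A = c(1, 2, 5), hill_B = c(1, 2, 5),
#'                 hill_alpha = c(1, 2, 5), hill_beta = c(2, 2, 5),
#'                 hill_gamma = c(0.5, 2, 5), hill_tau = c(0.5, 2, 5), b = 0.2)
#' @export
dose_rtf_params <- function(hill_A, hill_B, hill_alpha, hill_beta,
                            hill_gamma, hill_tau, b,
                            sign_sus = 1, sign_trans = 1, sigma = NULL) {
  triples <- list(A = hill_A, B = hill_B, alpha = hill_alpha,
                  beta = hill_beta, gamma = hill_gamma, tau = hill_tau)
  for (nm in names(triples)) {
    tr <- as.numeric(triples[[nm]])
    if (length(tr) != 3L || !all(is.finite(tr))) {
      stop("hill_", nm, " must be a finite numeric triple c(M, h, K)", call. = FALSE)
    }
    if (tr[1] < 0 || tr[2] <= 0 || tr[3] <= 0) {
      stop("hill_", nm, ": need M >= 0, h > 0, K > 0", call. = FALSE)
    }
    names(tr) <- c("M", "h", "K")
    triples[[nm]] <- tr
  }
  if (!sign_sus %in% c(-1, 1) || !sign_trans %in% c(-1, 1)) {
    stop("sign_sus and sign_trans must be exactly +1 or -1", call. = FALSE)
  }
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0 when present", call. = FALSE)
  structure(list(hill = triples, b = b, sign_sus = sign_sus,
                 sign_trans = sign_trans, sigma = sigma),
            class = "dose_rtf_params")
}

#' @export
print.dose_rtf_params <- function(x, ...) {
  cat("Dose-dependent RTF parameters (Hill triples M, h, K):\n")
  for (nm in names(x$hill)) {
    tr <- x$hill[[nm]]
    dir <- if (nm == "tau") "decreasing" else "increasing"
    cat(sprintf("  %-5s M = %.4g, h = %.4g, K = %.4g  (%s in dose)\n",
                nm, tr["M"], tr["h"], tr["K"], dir))
  }
  cat(sprintf("  offset b = %.4g, signs (%+d, %+d)\n", x$b, x$sign_sus, x$sign_trans))
  invisible(x)
}

#' Expand a dose-dependent parameter set at a single dose
#'
#' Evaluates all six Hill curves at dose `d` and returns the corresponding
#' single-dose [rtf_params]. At `d = 0` the amplitudes and rates are all 0;
#' rates are clamped to a small floor (`1e-10`) so that the single-dose
#' invariants hold — the response is unaffected because the amplitudes
#' vanish there.
#'
#' @param params A [dose_rtf_params] object.
#' @param d A single dose, >= 0.
#' @return An [rtf_params] object usable with [rtf_evaluate].
#' @export
dose_expand <- function(params, d) {
  stopifnot(inherits(params, "dose_rtf_params"))
  if (length(d) != 1L || !is.finite(d) || d < 0) {
    stop("`d` must be a single dose >= 0", call. = FALSE)
  }
  hv <- function(nm) hill(d, params$hill[[nm]]["M"], params$hill[[nm]]["h"],
                          params$hill[[nm]]["K"])
  tr <- params$hill$tau
  tau_d <- tr["M"] - hill(d, tr["M"], tr["h"], tr["K"])  # reversed Hill
  rtf_params(
    A = unname(hv("A")), B = unname(hv("B")),
    alpha = max(unname(hv("alpha")), RATE_FLOOR),
    beta  = max(unname(hv("beta")), RATE_FLOOR),
    gamma = max(unname(hv("gamma")), RATE_FLOOR),
    tau = unname(tau_d), b = params$b,
    sign_sus = params$sign_sus, sign_trans = params$sign_trans,
    sigma = params$sigma
  )
}

# --- internal vectorized machinery over per-point doses -------------------

# Order of the 18 Hill parameters in flattened vectors/matrices
DOSE_HILL_NAMES <- as.vector(t(outer(c("A", "B", "alpha", "beta", "gamma", "tau"),
                                     c("M", "h", "K"),
                                     function(a, b) paste(b, a, sep = "_"))))

# theta: named vector with M_A, h_A, K_A, ..., M_tau, h_tau, K_tau
# returns list of per-point parameter vectors (same length as d)
.dose_expand_vec <- function(theta, d) {
  out <- list()
  for (nm in c("A", "B", "alpha", "beta", "gamma")) {
    M <- theta[[paste0("M_", nm)]]; h <- theta[[paste0("h_", nm)]]
    K <- theta[[paste0("K_", nm)]]
    dh <- d^h
    v <- M * dh / (K^h + dh)
    if (nm %in% c("alpha", "beta", "gamma")) v <- pmax(v, RATE_FLOOR)
    out[[nm]] <- v
  }
  M <- theta[["M_tau"]]; h <- theta[["h_tau"]]; K <- theta[["K_tau"]]
  Kh <- K^h
  out$tau <- M * Kh / (Kh + d^h)
  out
}

# model values for the dose-dependent RTF at per-point (treal, d)
.dose_rtf_values <- function(theta, treal, d, sign_sus, sign_trans, T) {
  ex <- .dose_expand_vec(theta, d)
  t <- time_transform(treal, ex$tau, T)
  sign_sus * ex$A * (1 - exp(-ex$alpha * t)) +
    sign_trans * ex$B * (1 - exp(-ex$beta * t)) * exp(-ex$gamma * t) +
    theta[["b"]]
}

# gradient of the dose-dependent RTF w.r.t. the 18 Hill parameters + b;
# chain rule: (dR/dA, dR/dB, dR/dalpha, dR/dbeta, dR/dgamma, dR/dtau) at the
# per-point expanded parameters, times the Hill partials d(param)/d(M,h,K).
.dose_rtf_gradient <- function(theta, treal, d, sign_sus, sign_trans, T) {
  n <- length(treal)
  ex <- .dose_expand_vec(theta, d)
  t <- time_transform(treal, ex$tau, T)
  eA <- exp(-ex$alpha * t); eB <- exp(-ex$beta * t); eG <- exp(-ex$gamma * t)
  inner <- list(
    A     = sign_sus * (1 - eA),
    B     = sign_trans * (1 - eB) * eG,
    alpha = sign_sus * ex$A * t * eA,
    beta  = sign_trans * ex$B * t * eB * eG,
    gamma = -sign_trans * ex$B * (1 - eB) * t * eG,
    tau   = (sign_sus * ex$A * ex$alpha * eA +
               sign_trans * ex$B * (ex$beta * eB - ex$gamma * (1 - eB)) * eG) *
      .time_transform_dtau(treal, ex$tau, T)
  )
  g <- matrix(0, n, 19L, dimnames = list(NULL, c(DOSE_HILL_NAMES, "b")))
  logd <- ifelse(d > 0, log(d), 0)
  for (nm in c("A", "B", "alpha", "beta", "gamma", "tau")) {
    M <- theta[[paste0("M_", nm)]]; h <- theta[[paste0("h_", nm)]]
    K <- theta[[paste0("K_", nm)]]
    p <- d^h; q <- K^h; s <- p + q
    dH_dM <- p / s
    dH_dh <- ifelse(d > 0, M * p * q * (logd - log(K)) / s^2, 0)
    dH_dK <- -M * p * h * K^(h - 1) / s^2
    if (nm == "tau") {
      # tau(d) = M q / s = M - H(d): flip M column to q/s, negate h and K
      dH_dM <- q / s
      dH_dh <- -dH_dh
      dH_dK <- -dH_dK
    }
    g[, paste0("M_", nm)] <- inner[[nm]] * dH_dM
    g[, paste0("h_", nm)] <- inner[[nm]] * dH_dh
    g[, paste0("K_", nm)] <- inner[[nm]] * dH_dK
  }
  g[, "b"] <- 1
  g
}

#' Analytic gradient of the dose-dependent RTF
#'
#' Partial derivatives of the dose-dependent model response with respect to
#' the 18 Hill parameters (`M, h, K` for each of `A, B, alpha, beta, gamma,
#' tau`) and the offset `b`, obtained by the chain rule through the Hill
#' curves and the time transform.
#'
#' @param params A [dose_rtf_params] object.
#' @param treal Numeric vector of real times.
#' @param d Numeric vector of doses, one per time point (recycled if scalar).
#' @param T Time range for the transform.
#' @return Matrix `length(treal) x 19` with named columns (`M_A`, `h_A`,
#'   `K_A`, ..., `K_tau`, `b`).
#' @export
dose_gradient <- function(params, treal, d, T) {
  stopifnot(inherits(params, "dose_rtf_params"))
  if (any(d < 0)) stop("doses must be >= 0", call. = FALSE)
  d <- rep_len(d, length(treal))
  theta <- .dose_params_to_theta(params)
  .dose_rtf_gradient(theta, treal, d, params$sign_sus, params$sign_trans, T)
}

#' Evaluate the dose-dependent RTF
#'
#' @inheritParams dose_gradient
#' @return Numeric vector of responses, one per `(treal, d)` pair.
#' @export
dose_rtf_evaluate <- function(params, treal, d, T) {
  stopifnot(inherits(params, "dose_rtf_params"))
  if (any(d < 0)) stop("doses must be >= 0", call. = FALSE)
  d <- rep_len(d, length(treal))
  theta <- .dose_params_to_theta(params)
  .dose_rtf_values(theta, treal, d, params$sign_sus, params$sign_trans, T)
}

.dose_params_to_theta <- function(params) {
  th <- numeric(0)
  for (nm in c("A", "B", "alpha", "beta", "gamma", "tau")) {
    tr <- params$hill[[nm]]
    v <- c(tr[["M"]], tr[["h"]], tr[["K"]])
    names(v) <- paste(c("M", "h", "K"), nm, sep = "_")
    th <- c(th, v)
  }
  c(th, b = params$b)
}
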