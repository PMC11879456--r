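# Synthetic time-course generation: single-dose and dose-dependent RTF
# courses with i.i.d. Gaussian noise, and labelled multi-course collections
# with distinct dynamic classes and paired conditions.

#' Default single-dose simulation truth
#'
#' A parameter set with clearly visible sustained and transient structure:
#' both signs positive, `A = 1`, `B = 1.5`, `alpha = 1`, `beta = 2`,
#' `gamma = 0.5`, `tau = 0.5`, `b = 0.2`. The amplitudes are deliberately
#' unequal: when `A = B` the RTF is exactly non-identifiable (exchanging
#' `alpha` with `beta + gamma` leaves the curve unchanged), so equal
#' amplitudes would make a meaningless truth for recovery checks.
#'
#' @return An [rtf_params] object.
#' @export
default_rtf_truth <- function() {
  rtf_params(A = 1, B = 1.5, alpha = 1, beta = 2, gamma = 0.5, tau = 0.5, b = 0.2)
}

#' Default dose-dependent simulation truth
#'
#' Hill maxima equal to the single-dose defaults, Hill coefficient 2
#' everywhere, and EC50 `K = 5` — the midpoint of the default dose ladder
#' `c(1.25, 2.5, 5, 10, 20)`.
#'
#' @return A [dose_rtf_params] object.
#' @export
default_dose_truth <- function() {
  dose_rtf_params(
    hill_A = c(1, 2, 5), hill_B = c(1.5, 2, 5), hill_alpha = c(1, 2, 5),
    hill_beta = c(2, 2, 5), hill_gamma = c(0.5, 2, 5), hill_tau = c(0.5, 2, 5),
    b = 0.2
  )
}

.resolve_noise_sd <- function(noise_sd, y_true) {
  if (is.character(noise_sd)) {
    if (!grepl("^relative:", noise_sd)) {
      stop("character `noise_sd` must look like \"relative:0.01\"", call. = FALSE)
    }
    frac <- as.numeric(sub("^relative:", "", noise_sd))
    if (!is.finite(frac) || frac <= 0) stop("invalid relative noise fraction", call. = FALSE)
    rng <- diff(range(y_true))
    return(frac * if (rng > 0) rng else 1)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop("`noise_sd` must be a positive scalar or \"relative:<fraction>\"", call. = FALSE)
  }
  noise_sd
}

#' Simulate an RTF time course
#'
#' Evaluates the (dose-expanded) RTF on a time grid and adds i.i.d.
#' Gaussian noise. The generating truth is attached to the result so
#' recovery can be checked.
#'
#' @param mode `"singleDose"` or `"doseDependent"`.
#' @param params The generating truth: an [rtf_params]
#'   (default [default_rtf_truth]) or [dose_rtf_params]
#'   (default [default_dose_truth]).
#' @param times Time grid (default 21 equally spaced points on
#'   `[0, 10]`; in dose-dependent mode the grid is repeated per dose,
#'   defaulting to 11 points).
#' @param doses Dose ladder for `doseDependent` mode.
#' @param noise_sd Noise standard deviation: a positive scalar, or
#'   `"relative:<fraction>"` of the noise-free response range.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A data.frame with columns `t`, `y` (and `d` in dose-dependent
#'   mode) carrying attributes `truth` (the generating parameters),
#'   `y_true` (noise-free values), `noise_sd` and `mode`.
#' @examples
#' head(sim_timecourse(seed = 7))
#' @export
sim_timecourse <- function(mode = c("singleDose", "doseDependent"),
                           params = NULL, times = NULL, doses = NULL,
                           noise_sd = 0.02, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "singleDose") {
    if (is.null(params)) params <- default_rtf_truth()
    stopifnot(inherits(params, "rtf_params"))
    if (is.null(times)) times <- seq(0, 10, length.out = 21)
    if (length(times) < 3L) stop("need at least 3 time points", call. = FALSE)
    T <- diff(range(times))
    y_true <- rtf_evaluate(params, times, T)
    out <- data.frame(t = times, y = NA_real_)
  } else {
    if (is.null(params)) params <- default_dose_truth()
    stopifnot(inherits(params, "dose_rtf_params"))
    if (is.null(times)) times <- seq(0, 10, length.out = 11)
    if (is.null(doses)) doses <- c(1.25, 2.5, 5, 10, 20)
    if (length(doses) < 2L) stop("need at least 2 doses", call. = FALSE)
    grid <- expand.grid(t = times, d = doses, KEEP.OUT.ATTRS = FALSE)
    T <- diff(range(times))
    y_true <- dose_rtf_evaluate(params, grid$t, grid$d, T)
    out <- data.frame(t = grid$t, y = NA_real_, d = grid$d)
  }
  sd_use <- .resolve_noise_sd(noise_sd, y_true)
  set.seed(seed)
  out$y <- y_true + stats::rnorm(length(y_true), 0, sd_use)
  attr(out, "truth") <- params
  attr(out, "y_true") <- y_true
  attr(out, "noise_sd") <- sd_use
  attr(out, "mode") <- mode
  out
}

#' Simulate a labelled collection of time courses
#'
#' Generates `n_per_class` courses per dynamic class, and optionally a
#' paired second condition in which a perturbation is applied to the class
#' truths. The defaults emulate the main use case of the embedding: a
#' collection of trajectories extracted from a simulated (ODE) pathway
#' model — densely sampled (41 points) and nearly noise-free (sd `1e-4`,
#' the scale of a solver tolerance). The default classes contrast a
#' sustained-dominant responder (`A = 1, B = 0.3`) with a
#' transient-dominant one (`A = 0.2, B = 1.5`); both truths keep the two
#' amplitudes distinct, since amplitude ties put the RTF on an exactly
#' non-identifiable manifold (see [default_rtf_truth]) and a strictly
#' sustained-only truth (`B = 0`) can be represented exactly by several
#' parameter sets, which makes fitted parameters — and hence any clustering
#' of them — unstable.
#'
#' @param class_specs Named list of [rtf_params] truths, one per class.
#' @param n_per_class Courses per class (scalar or one value per class).
#' @param condition_effect Optional `function(params, class)` returning the
#'   perturbed truth for condition 2 (return the input unchanged for an
#'   unaffected class). When supplied, every course is generated under both
#'   conditions with a shared `pair_id`.
#' @param times,noise_sd As in [sim_timecourse].
#' @param seed Integer master seed; per-course seeds are derived from it.
#' @return An object of class `rtf_collection`: a list with `courses`
#'   (each `id`, `class`, `condition`, `pair_id`, `table`) and a
#'   `metadata` data.frame.
#' @export
sim_collection <- function(class_specs = NULL, n_per_class = 10,
                           condition_effect = NULL,
                           times = seq(0, 10, length.out = 41),
                           noise_sd = 1e-4, seed = 1) {
  if (is.null(class_specs)) {
    class_specs <- list(
      sustained = rtf_params(A = 1, B = 0.3, alpha = 1, beta = 2, gamma = 0.5,
                             tau = 0.5, b = 0.2),
      transient = rtf_params(A = 0.2, B = 1.5, alpha = 1, beta = 2, gamma = 0.8,
                             tau = 0.5, b = 0.2)
    )
  }
  if (is.null(names(class_specs)) || any(names(class_specs) == "")) {
    stop("`class_specs` must be a named list of rtf_params", call. = FALSE)
  }
  n_per_class <- rep_len(n_per_class, length(class_specs))
  if (any(n_per_class < 1)) stop("counts must be >= 1", call. = FALSE)
  conditions <- if (is.null(condition_effect)) "1" else c("1", "2")

  courses <- list()
  idx <- 0L
  for (ci in seq_along(class_specs)) {
    cls <- names(class_specs)[ci]
    for (i in seq_len(n_per_class[ci])) {
      pair_id <- sprintf("%s_%02d", cls, i)
      for (cond in conditions) {
        idx <- idx + 1L
        truth <- class_specs[[ci]]
        if (cond == "2") truth <- condition_effect(truth, cls)
        tab <- sim_timecourse("singleDose", params = truth, times = times,
                              noise_sd = noise_sd,
                              seed = .derive_seed(seed, idx))
        id <- if (length(conditions) > 1) paste0(pair_id, "_c", cond) else pair_id
        courses[[idx]] <- list(id = id, class = cls, condition = cond,
                               pair_id = pair_id, table = tab)
      }
    }
  }
  metadata <- data.frame(
    id = vapply(courses, `[[`, character(1), "id"),
    class = vapply(courses, `[[`, character(1), "class"),
    condition = vapply(courses, `[[`, character(1), "condition"),
    pair_id = vapply(courses, `[[`, character(1), "pair_id")
  )
  structure(list(courses = courses, metadata = metadata),
            class = "rtf_collection")
}

#' @export
print.rtf_collection <- function(x, ...) {
  cat(sprintf("RTF course collection: %d courses\n", length(x$courses)))
  print(table(class = x$metadata$class, condition = x$metadata$condition))
  invisible(x)
}
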