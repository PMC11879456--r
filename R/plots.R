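# Static ggplot2 graphics: data, fit with component decomposition,
# waterfall of multi-start objectives, start histograms, dose-parameter
# curves, and embedding displays.

#' Plot a time-course table
#'
#' Points over time; dose-dependent tables are colour-coded by dose, and
#' error bars are drawn when `sigmaExp` is present.
#'
#' @param data Data.frame with columns `t`, `y`, optional `d`, `sigmaExp`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(data) {
  p <- if ("d" %in% names(data)) {
    ggplot2::ggplot(data, ggplot2::aes(x = .data$t, y = .data$y,
                                       colour = factor(.data$d))) +
      ggplot2::labs(colour = "dose")
  } else {
    ggplot2::ggplot(data, ggplot2::aes(x = .data$t, y = .data$y))
  }
  if ("sigmaExp" %in% names(data)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sigmaExp,
                   ymax = .data$y + .data$sigmaExp), width = 0)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = "time", y = "signal") +
    ggplot2::theme_bw()
}

#' Plot a fitted RTF with its component decomposition
#'
#' The best fit curve is drawn through the data together with the
#' sustained and transient components (single-dose mode); dose-dependent
#' fits are shown as one total curve per dose.
#'
#' @param fit An [rtf_fit].
#' @param n_grid Curve resolution.
#' @return A ggplot object.
#' @export
plot_rtf_fit <- function(fit, n_grid = 101) {
  stopifnot(inherits(fit, "rtf_fit"))
  data <- fit$problem$data
  tt <- seq(min(data$t), max(data$t), length.out = n_grid)
  if (fit$problem$mode == "singleDose") {
    pars <- rtf_params(A = fit$best[["A"]], B = fit$best[["B"]],
                       alpha = fit$best[["alpha"]], beta = fit$best[["beta"]],
                       gamma = fit$best[["gamma"]], tau = fit$best[["tau"]],
                       b = fit$best[["b"]], sign_sus = fit$sign_sus,
                       sign_trans = fit$sign_trans)
    cmp <- rtf_components(pars, tt, fit$problem$T)
    curves <- rbind(
      data.frame(t = tt, y = cmp$sustained + cmp$transient + cmp$offset,
                 component = "total"),
      data.frame(t = tt, y = cmp$sustained + cmp$offset, component = "sustained"),
      data.frame(t = tt, y = cmp$transient + cmp$offset, component = "transient")
    )
    ggplot2::ggplot() +
      ggplot2::geom_line(data = curves,
                         ggplot2::aes(x = .data$t, y = .data$y,
                                      colour = .data$component,
                                      linetype = .data$component)) +
      ggplot2::geom_point(data = data, ggplot2::aes(x = .data$t, y = .data$y)) +
      ggplot2::labs(x = "time", y = "signal") +
      ggplot2::theme_bw()
  } else {
    doses <- sort(unique(data$d))
    curves <- predict(fit, tt, doses = doses)
    ggplot2::ggplot() +
      ggplot2::geom_line(data = curves,
                         ggplot2::aes(x = .data$t, y = .data$y,
                                      colour = factor(.data$d))) +
      ggplot2::geom_point(data = data,
                          ggplot2::aes(x = .data$t, y = .data$y,
                                       colour = factor(.data$d))) +
      ggplot2::labs(x = "time", y = "signal", colour = "dose") +
      ggplot2::theme_bw()
  }
}

#' Waterfall plot of sorted multi-start objectives
#'
#' A plateau at the lowest value across many starts indicates that the
#' global optimum was found repeatedly.
#'
#' @param fit An [rtf_fit].
#' @return A ggplot object.
#' @export
plot_waterfall <- function(fit) {
  v <- waterfall_values(fit)
  df <- data.frame(start = seq_along(v), value = v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "start (sorted)", y = "-2 ln L") +
    ggplot2::theme_bw()
}

#' Histograms of final parameter values across all starts
#'
#' @param fit An [rtf_fit].
#' @return A ggplot object, one facet per free parameter.
#' @export
plot_start_histograms <- function(fit) {
  stopifnot(inherits(fit, "rtf_fit"))
  rows <- lapply(fit$starts, function(s) {
    data.frame(parameter = names(s$par), value = unname(s$par))
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::theme_bw()
}

#' Dose dependence of the expanded RTF parameters
#'
#' For a dose-dependent fit, shows how each of `A, B, alpha, beta, gamma,
#' tau` varies with dose through its fitted Hill curve (6 panels), with
#' the training doses marked.
#'
#' @param fit A dose-dependent [rtf_fit].
#' @param n_grid Dose-axis resolution.
#' @return A ggplot object.
#' @export
plot_dose_parameters <- function(fit, n_grid = 101) {
  stopifnot(inherits(fit, "rtf_fit"))
  if (fit$problem$mode != "doseDependent") {
    stop("dose-parameter curves require a doseDependent fit", call. = FALSE)
  }
  dmax <- max(fit$problem$data$d)
  dd <- seq(0, dmax, length.out = n_grid)
  ex <- .dose_expand_vec(fit$best, dd)
  df <- do.call(rbind, lapply(c("A", "B", "alpha", "beta", "gamma", "tau"),
                              function(nm) {
                                data.frame(d = dd, value = ex[[nm]], parameter = nm)
                              }))
  pts <- do.call(rbind, lapply(c("A", "B", "alpha", "beta", "gamma", "tau"),
                               function(nm) {
                                 du <- sort(unique(fit$problem$data$d))
                                 data.frame(d = du,
                                            value = .dose_expand_vec(fit$best, du)[[nm]],
                                            parameter = nm)
                               }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", nrow = 2) +
    ggplot2::labs(x = "dose", y = "parameter value") +
    ggplot2::theme_bw()
}

#' @export
plot.rtf_fit <- function(x, which = c("fit", "waterfall", "histograms",
                                      "dose_parameters"), ...) {
  which <- match.arg(which)
  switch(which,
         fit = plot_rtf_fit(x, ...),
         waterfall = plot_waterfall(x),
         histograms = plot_start_histograms(x),
         dose_parameters = plot_dose_parameters(x, ...))
}

#' Plot a low-dimensional representation
#'
#' Embedding coordinates coloured by cluster (default) or by any metadata
#' column; pairs sharing a `pair_id` across conditions are connected by a
#' line so condition shifts are visible.
#'
#' @param x An [low_dim_rtf] result.
#' @param colour `"cluster"` or the name of a metadata column.
#' @param connect_pairs Draw lines between paired courses?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.rtf_embedding <- function(x, colour = "cluster", connect_pairs = TRUE, ...) {
  df <- data.frame(id = rownames(x$coords), dim1 = x$coords[, 1],
                   dim2 = x$coords[, 2], cluster = factor(x$labels))
  if (!is.null(x$metadata)) {
    df <- merge(df, x$metadata, by = "id", sort = FALSE)
  }
  if (!colour %in% names(df)) {
    stop("unknown colour variable `", colour, "`", call. = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (connect_pairs && "pair_id" %in% names(df) &&
      anyDuplicated(df$pair_id) > 0) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$pair_id),
                                colour = "grey60")
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]])) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_bw()
}

#' Per-cluster parameter quantile plot
#'
#' Median with 25th-75th percentile bars for each fitted parameter within
#' each cluster.
#'
#' @param embedding An [low_dim_rtf] result.
#' @return A ggplot object.
#' @export
plot_cluster_quantiles <- function(embedding) {
  df <- embedding$summaries
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$median)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                           width = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(y = "parameter (median, q25-q75)") +
    ggplot2::theme_bw()
}

#' Per-cluster dynamics plot
#'
#' Fitted time courses drawn per cluster, unscaled or min-max scaled (the
#' scaled view compares shapes regardless of amplitude).
#'
#' @param embedding An [low_dim_rtf] result.
#' @param scaled Use the min-max scaled curves?
#' @return A ggplot object.
#' @export
plot_cluster_dynamics <- function(embedding, scaled = TRUE) {
  df <- embedding$dynamics
  df$yy <- if (scaled) df$y_scaled else df$y
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$yy,
                                   group = .data$id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time", y = if (scaled) "scaled signal" else "signal") +
    ggplot2::theme_bw()
}
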