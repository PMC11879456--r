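# Reading time-course tables and serializing fits.
#
# Fits are stored as a documented JSON schema (full double precision, so a
# write/read round-trip reproduces the fit bit-exactly) instead of
# generated source code; predictions from a re-read fit go through the
# ordinary predict() method.

FIT_SCHEMA_VERSION <- "1.0"

#' Read a time-course table from delimited text
#'
#' Expects a header with columns `t` and `y`; `d` (dose) and `sigmaExp`
#' (known per-point standard error) are picked up by name when present.
#' The delimiter (comma or tab) is auto-detected from the header unless
#' given.
#'
#' @param path Path to the file.
#' @param delimiter `","`, `"\t"`, or `NULL` to auto-detect.
#' @return A validated data.frame with the canonical columns.
#' @export
read_timecourse <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  for (nm in c("t", "y")) {
    if (!nm %in% names(raw)) {
      stop("input file is missing required column `", nm, "`", call. = FALSE)
    }
  }
  cols <- intersect(c("t", "y", "d", "sigmaExp"), names(raw))
  out <- list()
  for (nm in cols) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("column `", nm, "` has non-numeric or missing entries in row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    out[[nm]] <- v
  }
  out <- as.data.frame(out)
  .validate_timecourse(out, if ("d" %in% cols) "doseDependent" else "singleDose")
  out
}

#' Write a time-course table as delimited text
#'
#' @param data Data.frame with columns `t`, `y` and optionally `d`,
#'   `sigmaExp`.
#' @param path Output path.
#' @param delimiter Field separator (default comma).
#' @export
write_timecourse <- function(data, path, delimiter = ",") {
  utils::write.table(data, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a fitted RTF to JSON
#'
#' Writes the complete fit — mode, parameter names, best parameters,
#' objective, bounds, fixed set, log10 mask, signs, time range, training
#' data, and every start's initial/final vectors — at full double
#' precision, so [read_rtf_fit] reproduces the fit bit-exactly. A
#' reduction result ([reduce_model]) is written as its final fit plus the
#' elimination trail.
#'
#' @param fit An [rtf_fit] or [reduce_model] result.
#' @param path Output path (`.json`).
#' @export
write_rtf_fit <- function(fit, path) {
  trail <- NULL
  if (inherits(fit, "rtf_reduction")) {
    trail <- fit$trail
    fit <- fit$final
  }
  stopifnot(inherits(fit, "rtf_fit"))
  p <- fit$problem
  obj <- list(
    schema_version = FIT_SCHEMA_VERSION,
    mode = p$mode,
    param_names = p$param_names,
    best = as.list(fit$best),
    value = fit$value,
    lb = as.list(p$lb), ub = as.list(p$ub),
    fixed = as.list(p$fixed),
    take_log10 = as.list(p$take_log10),
    sign_sus = fit$sign_sus, sign_trans = fit$sign_trans,
    T = p$T, sigma_free = p$sigma_free,
    n_starts = fit$n_starts, seed = fit$seed,
    data = as.list(p$data),
    starts = lapply(fit$starts, function(s) {
      list(x0 = as.list(s$x0), x = as.list(s$par), value = s$value,
           converged = s$converged, sign_sus = s$sign_sus,
           sign_trans = s$sign_trans)
    })
  )
  if (!is.null(trail)) obj$reduction_trail <- trail
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a fitted RTF back from JSON
#'
#' @param path Path written by [write_rtf_fit].
#' @return An [rtf_fit]; if the file carries a reduction trail it is
#'   attached as attribute `reduction_trail`.
#' @export
read_rtf_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version)) {
    stop("not an RTF fit file: missing schema_version", call. = FALSE)
  }
  if (!identical(obj$schema_version, FIT_SCHEMA_VERSION)) {
    stop("unsupported fit file schema version: ", obj$schema_version, call. = FALSE)
  }
  unl <- function(x) {
    if (is.null(x) || !length(x)) return(stats::setNames(numeric(0), character(0)))
    v <- unlist(x)
    # JSON readers return whole numbers as integers; fits are all doubles
    if (is.integer(v)) storage.mode(v) <- "double"
    v
  }
  num <- function(x) as.numeric(x)
  data <- as.data.frame(lapply(obj$data, unlist))
  problem <- structure(list(
    data = data, mode = obj$mode,
    param_names = unlist(obj$param_names),
    lb = unl(obj$lb), ub = unl(obj$ub),
    take_log10 = vapply(obj$take_log10, isTRUE, logical(1)),
    fixed = unl(obj$fixed),
    sign_sus = num(obj$sign_sus), sign_trans = num(obj$sign_trans),
    sigma_free = isTRUE(obj$sigma_free), T = num(obj$T)
  ), class = "rtf_problem")
  problem$initial_guess <- .default_guess(problem,
                                          if (identical(problem$sign_sus, -1)) -1 else 1)
  best <- unl(obj$best)[problem$param_names]
  fitted_vals <- .model_values(best, problem, problem$sign_sus, problem$sign_trans)
  starts <- lapply(obj$starts, function(s) {
    list(x0 = unl(s$x0), par = unl(s$x), value = num(s$value),
         converged = isTRUE(s$converged), message = NULL,
         sign_sus = num(s$sign_sus), sign_trans = num(s$sign_trans))
  })
  fit <- structure(list(
    problem = problem, best = best, value = num(obj$value),
    fitted = fitted_vals, residuals = data$y - fitted_vals,
    starts = starts, sign_sus = problem$sign_sus, sign_trans = problem$sign_trans,
    n_starts = obj$n_starts, seed = obj$seed
  ), class = "rtf_fit")
  if (!is.null(obj$reduction_trail)) {
    attr(fit, "reduction_trail") <-
      do.call(rbind, lapply(obj$reduction_trail, as.data.frame))
  }
  fit
}

#' Read a collection of time courses
#'
#' Two layouts are supported. A *long-format* file: one delimited table
#' with an `id` column plus the usual `t`, `y` (and optional `d`,
#' `sigmaExp`) columns; any further columns (e.g. `class`, `condition`,
#' `pair_id`) are treated as per-course metadata. Or a *manifest*: a
#' delimited table with columns `id` and `file` (paths resolved relative
#' to the manifest) plus optional metadata columns, each `file` holding
#' one course in [read_timecourse] format.
#'
#' @param path Path to the long-format file, or to the manifest when
#'   `manifest = TRUE`.
#' @param manifest Is `path` a manifest table?
#' @param delimiter Field separator; `NULL` auto-detects comma/tab.
#' @return An `rtf_collection` list (`courses`, `metadata`) as produced by
#'   [sim_collection], usable with [fit_collection] / [low_dim_rtf].
#' @export
read_collection <- function(path, manifest = FALSE, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delimiter)) delimiter <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  courses <- list()
  meta <- list()
  if (manifest) {
    for (nm in c("id", "file")) {
      if (!nm %in% names(tab)) {
        stop("manifest is missing required column `", nm, "`", call. = FALSE)
      }
    }
    if (anyDuplicated(tab$id)) stop("course ids must be unique", call. = FALSE)
    for (i in seq_len(nrow(tab))) {
      f <- tab$file[i]
      if (!file.exists(f)) f <- file.path(dirname(path), tab$file[i])
      courses[[i]] <- list(id = as.character(tab$id[i]),
                           table = read_timecourse(f, delimiter = delimiter))
      meta[[i]] <- tab[i, setdiff(names(tab), "file"), drop = FALSE]
    }
  } else {
    if (!"id" %in% names(tab)) {
      stop("long-format input is missing required column `id`", call. = FALSE)
    }
    mcols <- setdiff(names(tab), c("id", "t", "y", "d", "sigmaExp"))
    ids <- unique(as.character(tab$id))
    for (i in seq_along(ids)) {
      sub <- tab[tab$id == ids[i], , drop = FALSE]
      course <- sub[, intersect(c("t", "y", "d", "sigmaExp"), names(sub)),
                    drop = FALSE]
      .validate_timecourse(course,
                           if ("d" %in% names(course)) "doseDependent" else "singleDose")
      courses[[i]] <- list(id = ids[i], table = course)
      meta[[i]] <- cbind(data.frame(id = ids[i]),
                         sub[1, mcols, drop = FALSE])
    }
  }
  for (i in seq_along(courses)) {
    extra <- meta[[i]][setdiff(names(meta[[i]]), "id")]
    courses[[i]] <- c(courses[[i]], as.list(extra))
  }
  structure(list(courses = courses,
                 metadata = do.call(rbind, meta)),
            class = "rtf_collection")
}
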