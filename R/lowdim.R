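# Low-dimensional representation of many fitted RTFs: fit each course,
# assemble the parameter matrix, standardize, embed in 2-D, cluster, and
# summarize per-cluster dynamics. Shifts of paired points between
# conditions rank the entities whose dynamics changed most.

LOWDIM_PARAMS <- c("A", "B", "alpha", "beta", "gamma", "tau", "b")

#' Fit every course of a collection
#'
#' Independent single-dose fits (shared options, per-course time range)
#' for each course, assembled into the parameter matrix used by the
#' embedding: columns `A, B, alpha, beta, gamma, tau, b` plus the resolved
#' signs as two +/-1 columns (so direction changes contribute to
#' condition shifts). The noise parameter `sigma` is excluded — it
#' describes measurement error, not dynamics. Courses whose fit fails are
#' dropped with a warning.
#'
#' @param collection An [sim_collection] result, or any list with a
#'   `courses` element of `(id, table)` entries.
#' @param n_starts Multi-starts per course fit.
#' @param seed Integer seed, shared by every course fit (so identical
#'   courses yield identical rows).
#' @param sign_sus,sign_trans Component signs, usually `"auto"`.
#' @param refine Run a cross-course refinement pass? Courses whose best
#'   objective lies far above the collection median (the courses share one
#'   sampling design, so their optimal objectives concentrate) are refitted
#'   warm-started from the solutions of the best-fitting other courses.
#'   This repairs the occasional multi-start miss that would otherwise
#'   place a course in a spurious likelihood basin.
#' @param refine_margin Objective excess over the collection median that
#'   flags a course for refinement.
#' @return An object of class `rtf_collection_fit`: `param_matrix`
#'   (courses x parameters), `fits` (named list of [rtf_fit]s) and the
#'   collection `metadata` restricted to fitted courses.
#' @export
fit_collection <- function(collection, n_starts = 10, seed = 1,
                           sign_sus = "auto", sign_trans = "auto",
                           refine = TRUE, refine_margin = 30) {
  courses <- collection$courses
  if (!length(courses)) stop("empty collection", call. = FALSE)
  ids <- vapply(courses, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("course ids must be unique", call. = FALSE)
  fits <- vector("list", length(courses))
  failed <- character(0)
  for (i in seq_along(courses)) {
    fits[[i]] <- tryCatch(
      rtf_fit(courses[[i]]$table, mode = "singleDose", n_starts = n_starts,
              seed = seed, sign_sus = sign_sus, sign_trans = sign_trans),
      error = function(e) {
        failed <<- c(failed, ids[i])
        NULL
      }
    )
  }
  if (refine && sum(!vapply(fits, is.null, logical(1))) >= 4L) {
    fitted_idx <- which(!vapply(fits, is.null, logical(1)))
    vals <- vapply(fits[fitted_idx], `[[`, numeric(1), "value")
    med <- stats::median(vals)
    flagged <- fitted_idx[vals > med + refine_margin]
    if (length(flagged)) {
      donors_idx <- fitted_idx[order(vals)]
      donors_idx <- utils::head(setdiff(donors_idx, flagged), 5L)
      for (i in flagged) {
        best_fit <- fits[[i]]
        for (j in donors_idx) {
          cand <- tryCatch(
            rtf_fit(courses[[i]]$table, mode = "singleDose", n_starts = 1,
                    seed = seed, sign_sus = fits[[j]]$sign_sus,
                    sign_trans = fits[[j]]$sign_trans,
                    warm_start = fits[[j]]$best, basin_hops = 5),
            error = function(e) NULL
          )
          if (!is.null(cand) && cand$value < best_fit$value) best_fit <- cand
        }
        fits[[i]] <- best_fit
      }
    }
  }
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("all course fits failed", call. = FALSE)
  if (length(failed)) {
    warning("dropped ", length(failed), " course(s) with failed fits: ",
            paste(failed, collapse = ", "), call. = FALSE)
  }
  fits <- fits[keep]
  names(fits) <- ids[keep]
  pm <- t(vapply(fits, function(f) {
    c(f$best[LOWDIM_PARAMS], sign_sus = f$sign_sus, sign_trans = f$sign_trans)
  }, numeric(length(LOWDIM_PARAMS) + 2)))
  colnames(pm) <- c(LOWDIM_PARAMS, "sign_sus", "sign_trans")
  rownames(pm) <- ids[keep]
  metadata <- collection$metadata
  if (!is.null(metadata)) metadata <- metadata[metadata$id %in% ids[keep], , drop = FALSE]
  structure(list(param_matrix = pm, fits = fits, metadata = metadata,
                 failed = failed),
            class = "rtf_collection_fit")
}

#' Standardize a fitted-parameter matrix
#'
#' Per-parameter z-score across courses; the rate parameters (`alpha`,
#' `beta`, `gamma`), which span orders of magnitude, are standardized on
#' log10 scale. The divisor is floored at 10% of the column's typical
#' magnitude (`median(|x|)`, or 0.1 for columns centred on zero): a column
#' whose spread across courses is far below its own scale varies only by
#' fitting noise, and plain unit-variance scaling would amplify that noise
#' into order-one coordinates that drown the informative parameters.
#' Constant columns (e.g. signs that never flip) become 0.
#'
#' @param param_matrix Courses x parameters matrix as produced by
#'   [fit_collection].
#' @return Matrix of the same shape, standardized.
#' @export
scale_param_matrix <- function(param_matrix) {
  m <- param_matrix
  for (nm in intersect(c("alpha", "beta", "gamma"), colnames(m))) {
    m[, nm] <- log10(pmax(m[, nm], 1e-12))
  }
  ctr <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  sds[!is.finite(sds)] <- 0
  floors <- 0.1 * pmax(apply(abs(m), 2, stats::median), 0.1)
  div <- pmax(sds, floors)
  scaled <- sweep(sweep(m, 2, ctr, "-"), 2, div, "/")
  # exactly constant columns carry no information at all
  scaled[, sds == 0] <- 0
  scaled
}

#' Embed the standardized parameter matrix in two dimensions
#'
#' The default method is PCA of the standardized matrix: the embedding
#' feeds displacement-magnitude comparisons ([condition_shift]), and a
#' metric projection keeps those magnitudes meaningful. `"nmds"` selects
#' non-metric multidimensional scaling ([vegan::monoMDS], initialized from
#' classical MDS so the result is deterministic), which preserves
#' neighbourhood ranks rather than distances and can unfold nonlinear
#' structure for display. Identical rows map to coincident points under
#' both.
#'
#' @param scaled_matrix Standardized matrix (see [scale_param_matrix]),
#'   >= 4 rows.
#' @param seed Integer seed (kept for interface stability; both methods
#'   are deterministic).
#' @param method `"pca"` (default) or `"nmds"`.
#' @return Numeric matrix `rows x 2` with columns `dim1`, `dim2`.
#' @export
embed_params <- function(scaled_matrix, seed = 1, method = c("pca", "nmds")) {
  method <- match.arg(method)
  n <- nrow(scaled_matrix)
  if (is.null(n) || n < 4L) {
    stop("embedding needs at least 4 courses; plot the parameter matrix directly ",
         "for smaller collections", call. = FALSE)
  }
  coords <- if (method == "pca") {
    pc <- stats::prcomp(scaled_matrix, center = FALSE, scale. = FALSE)
    sc <- pc$x
    if (ncol(sc) < 2L) sc <- cbind(sc, 0)
    sc[, 1:2, drop = FALSE]
  } else {
    d <- stats::dist(scaled_matrix)
    if (all(d < .Machine$double.eps)) {
      matrix(0, n, 2)  # all courses identical: a single point
    } else {
      init <- stats::cmdscale(d, k = 2)
      if (ncol(init) < 2L) init <- cbind(init, 0)
      set.seed(seed)
      fit <- vegan::monoMDS(d, y = init, k = 2)
      fit$points
    }
  }
  dimnames(coords) <- list(rownames(scaled_matrix), c("dim1", "dim2"))
  coords
}

#' k-means clustering of the standardized parameter matrix
#'
#' Clusters operate on the standardized parameters (not the 2-D
#' coordinates), so clusters reflect the fitted kinetics and the embedding
#' stays display-only. When `k` is not given it is chosen in
#' `2..min(10, rows - 1)` by maximizing the mean silhouette width.
#'
#' @param scaled_matrix Standardized matrix (>= 2 rows).
#' @param k Cluster count; `NULL` to select by silhouette; `1` for a
#'   single cluster.
#' @param seed Integer seed for the k-means restarts (10 per k).
#' @return A list with `labels` (integers in `1..k`), `k`, and
#'   `silhouette` (mean width, `NA` when `k = 1` or `k` was given).
#' @export
cluster_params <- function(scaled_matrix, k = NULL, seed = 1) {
  n <- nrow(scaled_matrix)
  if (is.null(n) || n < 2L) stop("clustering needs at least 2 rows", call. = FALSE)
  if (!is.null(k) && k == 1L) {
    return(list(labels = rep(1L, n), k = 1L, silhouette = NA_real_))
  }
  km_at <- function(kk) {
    set.seed(.derive_seed(seed, kk))
    stats::kmeans(scaled_matrix, centers = kk, nstart = 10, iter.max = 50)
  }
  if (!is.null(k)) {
    if (k >= n) stop("`k` must be smaller than the number of rows", call. = FALSE)
    km <- km_at(k)
    return(list(labels = as.integer(km$cluster), k = as.integer(k),
                silhouette = NA_real_))
  }
  ks <- 2:min(10L, n - 1L)
  d <- stats::dist(scaled_matrix)
  best <- NULL
  for (kk in ks) {
    km <- km_at(kk)
    if (length(unique(km$cluster)) < kk) next
    sw <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    if (is.null(best) || sw > best$silhouette) {
      best <- list(labels = as.integer(km$cluster), k = as.integer(kk),
                   silhouette = sw)
    }
  }
  if (is.null(best)) stop("clustering failed for every candidate k", call. = FALSE)
  best
}

#' Per-cluster quantile summaries of fitted parameters
#'
#' 25th, 50th and 75th percentiles (type-7, linear interpolation) of each
#' fitted parameter within each cluster.
#'
#' @param param_matrix Courses x parameters matrix (natural scale).
#' @param labels Integer cluster labels, one per row.
#' @return Long data.frame with columns `cluster`, `parameter`, `q25`,
#'   `median`, `q75`.
#' @export
summarize_clusters <- function(param_matrix, labels) {
  stopifnot(nrow(param_matrix) == length(labels))
  out <- list()
  for (cl in sort(unique(labels))) {
    sub <- param_matrix[labels == cl, , drop = FALSE]
    q <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), type = 7)
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, parameter = colnames(sub),
      q25 = q[1, ], median = q[2, ], q75 = q[3, ], row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Fitted per-cluster dynamics, unscaled and min-max scaled
#'
#' Evaluates each course's fitted RTF on a fine grid over its own time
#' range and attaches a min-max scaled version (`(y - min)/(max - min)`,
#' constant curves mapped to 0.5) so dynamics can be compared
#' qualitatively within a cluster regardless of amplitude.
#'
#' @param cfit An [fit_collection] result.
#' @param labels Integer cluster labels, one per fitted course.
#' @param n_grid Grid points per course.
#' @return Long data.frame with columns `id`, `cluster`, `t`, `y`,
#'   `y_scaled`.
#' @export
cluster_dynamics <- function(cfit, labels, n_grid = 50) {
  stopifnot(inherits(cfit, "rtf_collection_fit"),
            length(labels) == length(cfit$fits))
  out <- vector("list", length(cfit$fits))
  for (i in seq_along(cfit$fits)) {
    f <- cfit$fits[[i]]
    tr <- range(f$problem$data$t)
    tt <- seq(tr[1], tr[2], length.out = n_grid)
    y <- predict(f, tt)
    rng <- diff(range(y))
    y_scaled <- if (rng > 0) (y - min(y)) / rng else rep(0.5, length(y))
    out[[i]] <- data.frame(id = names(cfit$fits)[i], cluster = labels[i],
                           t = tt, y = y, y_scaled = y_scaled)
  }
  do.call(rbind, out)
}

#' Low-dimensional representation of a collection of time courses
#'
#' The full pipeline: fit every course ([fit_collection]), standardize the
#' parameter matrix ([scale_param_matrix]), embed it in 2-D
#' ([embed_params]), cluster the standardized parameters
#' ([cluster_params]) and summarize each cluster ([summarize_clusters],
#' [cluster_dynamics]).
#'
#' @inheritParams fit_collection
#' @param k Cluster count (`NULL`: silhouette selection).
#' @param method Embedding method, see [embed_params].
#' @return An object of class `rtf_embedding` with elements
#'   `param_matrix`, `scaled_matrix`, `coords`, `labels`, `k`,
#'   `summaries`, `dynamics`, `metadata` and the underlying
#'   `collection_fit`.
#' @export
low_dim_rtf <- function(collection, n_starts = 10, k = NULL, seed = 1,
                        method = c("pca", "nmds"), sign_sus = "auto",
                        sign_trans = "auto") {
  method <- match.arg(method)
  cfit <- fit_collection(collection, n_starts = n_starts, seed = seed,
                         sign_sus = sign_sus, sign_trans = sign_trans)
  scaled <- scale_param_matrix(cfit$param_matrix)
  coords <- embed_params(scaled, seed = .derive_seed(seed, 2L), method = method)
  cl <- cluster_params(scaled, k = k, seed = .derive_seed(seed, 3L))
  structure(list(
    param_matrix = cfit$param_matrix, scaled_matrix = scaled,
    coords = coords, labels = cl$labels, k = cl$k,
    silhouette = cl$silhouette,
    summaries = summarize_clusters(cfit$param_matrix, cl$labels),
    dynamics = cluster_dynamics(cfit, cl$labels),
    metadata = cfit$metadata, collection_fit = cfit,
    seed = seed, method = method
  ), class = "rtf_embedding")
}

#' @export
print.rtf_embedding <- function(x, ...) {
  cat(sprintf("RTF low-dimensional representation: %d courses, %d clusters (%s)\n",
              nrow(x$coords), x$k, x$method))
  if (is.finite(x$silhouette %||% NA)) {
    cat(sprintf("  mean silhouette at chosen k: %.3f\n", x$silhouette))
  }
  invisible(x)
}

#' Rank condition-induced shifts of paired courses in the embedding
#'
#' For each pair of course ids (the same molecular entity under two
#' conditions) the 2-D displacement between their embedded points is
#' computed; pairs are returned sorted by decreasing displacement length,
#' ranking the entities whose dynamics changed most under the
#' perturbation. Ids absent from the embedding are reported in the
#' `unmatched` attribute rather than raising an error.
#'
#' @param embedding An [low_dim_rtf] result (or anything with a `coords`
#'   matrix rownamed by course id).
#' @param pairing Data.frame with columns `id1`, `id2`.
#' @return Data.frame `id1, id2, dx, dy, distance`, sorted by decreasing
#'   `distance`, with attribute `unmatched` (character vector of missing
#'   ids).
#' @export
condition_shift <- function(embedding, pairing) {
  coords <- embedding$coords
  stopifnot(is.matrix(coords), !is.null(rownames(coords)))
  if (!all(c("id1", "id2") %in% names(pairing))) {
    stop("`pairing` needs columns `id1` and `id2`", call. = FALSE)
  }
  pairing$id1 <- as.character(pairing$id1)
  pairing$id2 <- as.character(pairing$id2)
  present <- rownames(coords)
  ok <- pairing$id1 %in% present & pairing$id2 %in% present
  unmatched <- unique(c(pairing$id1[!pairing$id1 %in% present],
                        pairing$id2[!pairing$id2 %in% present]))
  p <- pairing[ok, , drop = FALSE]
  if (nrow(p)) {
    dx <- coords[p$id2, 1] - coords[p$id1, 1]
    dy <- coords[p$id2, 2] - coords[p$id1, 2]
    out <- data.frame(id1 = p$id1, id2 = p$id2, dx = dx, dy = dy,
                      distance = sqrt(dx^2 + dy^2), row.names = NULL)
    out <- out[order(-out$distance), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(id1 = character(), id2 = character(), dx = numeric(),
                      dy = numeric(), distance = numeric())
  }
  attr(out, "unmatched") <- unmatched
  out
}
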