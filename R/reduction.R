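# Stepwise (backward) model reduction via likelihood-ratio tests.
#
# Candidates remove a whole model feature at a time. Removing an amplitude
# leaves its associated rate(s) unidentifiable, so those are fixed jointly
# with it and the chi-square degrees of freedom count every parameter
# removed — each tested nested model stays identifiable and the test honest.

#' Enumerate candidate parameter eliminations
#'
#' Single-dose candidates: drop the transient component (`B = 0`, with
#' `beta`, `gamma` fixed; df 3), drop the sustained component (`A = 0` with
#' `alpha` fixed; df 2), drop the retardation (`tau = 0`; df 1), drop the
#' offset (`b = 0`; df 1). Dose-dependent candidates: the same component
#' removals acting on whole Hill triples (`M = 0` with the dependent
#' triples fixed; df 3 per removed triple), plus fixing each Hill
#' coefficient at 1 (df 1 each). Parameters already fixed in the problem
#' are not candidates; `sigma` never is.
#'
#' @param problem An [rtf_problem].
#' @param best Optional named vector supplying the values at which
#'   unidentifiable co-fixed parameters are frozen (defaults to the
#'   problem's initial guess).
#' @return A list of candidates, each a list with `name`, `fix` (named
#'   values to impose) and `df`.
#' @export
candidate_eliminations <- function(problem, best = NULL) {
  stopifnot(inherits(problem, "rtf_problem"))
  if (is.null(best)) best <- problem$initial_guess
  at <- function(nms) stats::setNames(best[nms], nms)
  cands <- if (problem$mode == "singleDose") {
    list(
      list(name = "transient",   fix = c(c(B = 0), at(c("beta", "gamma"))), df = 3L),
      list(name = "sustained",   fix = c(c(A = 0), at("alpha")), df = 2L),
      list(name = "retardation", fix = c(tau = 0), df = 1L),
      list(name = "offset",      fix = c(b = 0), df = 1L)
    )
  } else {
    comp <- list(
      list(name = "transient",
           fix = c(c(M_B = 0), at(c("h_B", "K_B", "M_beta", "h_beta", "K_beta",
                                    "M_gamma", "h_gamma", "K_gamma"))), df = 9L),
      list(name = "sustained",
           fix = c(c(M_A = 0), at(c("h_A", "K_A", "M_alpha", "h_alpha", "K_alpha"))),
           df = 6L),
      list(name = "retardation",
           fix = c(c(M_tau = 0), at(c("h_tau", "K_tau"))), df = 3L),
      list(name = "offset", fix = c(b = 0), df = 1L)
    )
    hills <- lapply(c("A", "B", "alpha", "beta", "gamma", "tau"), function(nm) {
      list(name = paste0("hill_coefficient_", nm),
           fix = stats::setNames(1, paste0("h_", nm)), df = 1L)
    })
    c(comp, hills)
  }
  already <- names(problem$fixed)
  Filter(function(cand) !any(names(cand$fix) %in% already), cands)
}

#' Likelihood-ratio test p-value for nested RTF models
#'
#' The statistic is the increase in `-2 ln L` of the reduced (nested) model
#' over the full model, referred to a chi-square distribution with `df`
#' equal to the number of parameters removed. Small negative statistics
#' (numerical noise when both fits are at their optimum) are clamped to 0.
#'
#' @param neg2ll_reduced,neg2ll_full Objective values of the reduced and
#'   full model.
#' @param df Number of parameters removed (>= 1).
#' @return The upper-tail chi-square p-value.
#' @examples
#' lrt_pvalue(10 + 3.841459, 10, df = 1)  # ~0.05
#' @export
lrt_pvalue <- function(neg2ll_reduced, neg2ll_full, df) {
  if (length(df) != 1L || !is.finite(df) || df < 1) {
    stop("`df` must be >= 1", call. = FALSE)
  }
  stat <- max(0, neg2ll_reduced - neg2ll_full)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Stepwise model reduction of a fitted RTF
#'
#' Backward elimination: each remaining candidate (see
#' [candidate_eliminations]) is refitted with its parameters fixed, a
#' likelihood-ratio test compares it against the current model, and per
#' round the candidate with the largest p-value is accepted if
#' `p >= alpha` (ties broken by fewer df, then candidate order). The
#' procedure stops when every remaining candidate is rejected, yielding a
#' minimal model that the data do not distinguish from the full one.
#' `alpha = 1` is the limiting convention "always eliminate": every
#' eligible candidate is removed in turn, down to the offset-only model.
#'
#' Refits warm-start from the surviving best fit (with the candidate's
#' constraint imposed) plus fresh multi-starts, and keep the signs resolved
#' by the original fit so all models are nested. `sigma` stays free (or
#' `sigmaExp`-fixed) throughout.
#'
#' @param fit An [rtf_fit].
#' @param alpha Significance level for the likelihood-ratio tests.
#' @param n_starts Multi-starts per candidate refit.
#' @param seed Integer seed for the refits.
#' @return An object of class `rtf_reduction`: `final` (the reduced
#'   [rtf_fit]), `initial`, `trail` (one row per tested round winner:
#'   eliminated feature, df, objectives, p-value, accepted flag) and
#'   `alpha`.
#' @export
reduce_model <- function(fit, alpha = 0.05, n_starts = 20, seed = 1) {
  stopifnot(inherits(fit, "rtf_fit"))
  current <- fit
  trail <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    cands <- candidate_eliminations(current$problem, current$best)
    if (!length(cands)) break
    evals <- vector("list", length(cands))
    for (j in seq_along(cands)) {
      cand <- cands[[j]]
      prob_r <- current$problem
      prob_r$fixed <- c(prob_r$fixed, cand$fix)
      refit <- tryCatch(
        rtf_fit(prob_r, n_starts = n_starts,
                seed = .derive_seed(seed, round_i, j),
                warm_start = current$best),
        error = function(e) e
      )
      if (inherits(refit, "error")) {
        warning("candidate '", cand$name, "' skipped: ", conditionMessage(refit),
                call. = FALSE)
        next
      }
      evals[[j]] <- list(cand = cand, fit = refit,
                         p = lrt_pvalue(refit$value, current$value, cand$df))
    }
    evals <- Filter(Negate(is.null), evals)
    if (!length(evals)) break
    ps <- vapply(evals, `[[`, numeric(1), "p")
    dfs <- vapply(evals, function(e) e$cand$df, integer(1))
    best_j <- order(-ps, dfs, seq_along(evals))[1]
    e <- evals[[best_j]]
    accepted <- e$p >= alpha || alpha >= 1
    trail[[length(trail) + 1L]] <- data.frame(
      round = round_i, eliminated = e$cand$name, df = e$cand$df,
      neg2ll_before = current$value, neg2ll_after = e$fit$value,
      statistic = max(0, e$fit$value - current$value),
      p_value = e$p, accepted = accepted
    )
    if (!accepted) break
    current <- e$fit
  }
  structure(list(final = current, initial = fit,
                 trail = do.call(rbind, trail) %||%
                   data.frame(round = integer(), eliminated = character(),
                              df = integer(), neg2ll_before = numeric(),
                              neg2ll_after = numeric(), statistic = numeric(),
                              p_value = numeric(), accepted = logical()),
                 alpha = alpha, n_starts = n_starts, seed = seed),
            class = "rtf_reduction")
}

#' @export
print.rtf_reduction <- function(x, ...) {
  n_acc <- sum(x$trail$accepted)
  cat(sprintf("RTF model reduction (alpha = %g): %d feature(s) eliminated\n",
              x$alpha, n_acc))
  if (nrow(x$trail)) {
    tr <- x$trail
    tr$p_value <- signif(tr$p_value, 4)
    print(tr, row.names = FALSE)
  }
  cat(sprintf("final -2 ln L = %.6g (initial %.6g), free parameters: %d\n",
              x$final$value, x$initial$value,
              length(.free_names(x$final$problem))))
  invisible(x)
}
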