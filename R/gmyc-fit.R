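#' Fit the GMYC model with a single threshold
#'
#' Scans all candidate threshold ages — the midpoints between successive
#' distinct branching ages, plus one beyond the root — re-optimizing the
#' four mixed-model parameters at each, and returns the maximum-likelihood
#' threshold. Ties in log-likelihood are broken toward the *oldest*
#' threshold (most inclusive clusters). A likelihood-ratio test against the
#' single-population null uses 3 degrees of freedom (threshold + extra
#' scale + extra exponent), and the confidence set collects the entity
#' counts of every candidate within 2 log-likelihood units of the maximum.
#'
#' @param tree Binary ultrametric `phylo` with at least 4 tips.
#' @param tol Ultrametricity tolerance.
#' @return An object of class `gmyc_fit`. Key fields: `params`,
#'   `threshold` (age, also printed as negative time), `clusters`,
#'   `singletons`, `n_entities`, `logL`, `null` (null fit), `LRT`,
#'   `conf_entities`, and `candidates` (a tibble of the whole profile).
#' @seealso [fit_multiple_threshold()], [fit_gmyc()]
#' @export
fit_single_threshold <- function(tree, tol = 1e-6) {
  pre <- if (inherits(tree, "coaldelim_gmyc_pre")) tree else {
    p <- gmyc_preprocess(tree, tol); class(p) <- "coaldelim_gmyc_pre"; p
  }
  if (pre$ntip < 4) {
    stop_coaldelim("single-threshold fitting needs >= 4 tips",
                   "coaldelim_degenerate_error")
  }
  if (length(pre$d) < 3) {
    stop_coaldelim("fewer than 3 distinct branching ages",
                   "coaldelim_degenerate_error")
  }
  null_fit <- fit_null(pre)
  null_start <- matrix(c(log(null_fit$lambda), null_fit$p,
                         log(null_fit$lambda), null_fit$p), 1)

  ages_desc <- pre$d  # distinct branching ages, oldest first
  mids <- (ages_desc[-length(ages_desc)] + ages_desc[-1]) / 2
  cand_T <- c(pre$root_age * 1.05, mids)  # oldest first; beyond-root first

  best <- NULL
  warm <- NULL
  rows <- vector("list", length(cand_T))
  for (i in seq_along(cand_T)) {
    Tc <- cand_T[i]
    roots <- cluster_roots_at_threshold(pre, Tc)
    cnt <- gmyc_interval_counts(pre, roots)
    # the scan warm-starts each candidate from its neighbour's optimum and
    # refreshes the full start grid periodically; the winner is re-polished
    # from the full grid below
    opt <- optimize_gmyc_params(cnt, extra_starts = rbind(warm, null_start),
                                grid = (i == 1L || i %% 8L == 0L))
    warm <- matrix(opt$raw, 1)
    rows[[i]] <- tibble(threshold = Tc, logL = opt$logL,
                        n_entities = cnt$n_entities,
                        n_clusters = length(roots),
                        n_singletons = length(cnt$singletons))
    if (is.null(best) || opt$logL > best$logL + 1e-9) {
      best <- list(T = Tc, roots = roots, opt = opt, logL = opt$logL,
                   n_entities = cnt$n_entities)
    }
  }
  # polish the winning threshold from the full start grid
  repolish <- optimize_gmyc_params(gmyc_interval_counts(pre, best$roots),
                                   extra_starts = matrix(best$opt$raw, 1))
  if (repolish$logL > best$logL) best$opt <- repolish
  best$logL <- best$opt$logL
  candidates <- dplyr::bind_rows(rows)
  candidates$logL[candidates$threshold == best$T] <- best$logL
  conf <- sort(unique(candidates$n_entities[candidates$logL >=
                                              max(candidates$logL) - 2]))
  ent <- gmyc_entities(pre, best$roots)
  test <- lrt(best$logL, null_fit$logL, df = 3)
  structure(list(
    method = "single",
    tree = pre$tree,
    params = best$opt$par,
    threshold = best$T,
    thresholds = best$T,
    cluster_roots = best$roots,
    clusters = ent$clusters,
    singletons = ent$singletons,
    n_entities = best$n_entities,
    logL = best$logL,
    null = null_fit,
    LRT = c(test, df = 3),
    conf_entities = conf,
    candidates = candidates,
    converged = best$opt$converged
  ), class = "gmyc_fit")
}

#' Fit the GMYC model with multiple thresholds
#'
#' Deterministic hill climb over subtree-local threshold configurations,
#' started from a single-threshold fit. The model state is the antichain of
#' cluster-root nodes; the proposal neighbourhood splits one cluster into
#' its child clusters or merges sibling clusters/singletons into their
#' parent (moving a local threshold is a split followed by a merge, so the
#' neighbourhood is complete). Each proposal re-optimizes all four
#' parameters; the best strictly-improving proposal is accepted until none
#' improves by more than `tol_improve`. The default gain of 2 log-likelihood
#' units per accepted switch is the profile-likelihood support convention
#' (the same band used for the confidence set): it keeps the climb from
#' accumulating switches on marginal likelihood wiggles, and can be lowered
#' to make the search a pure hill climb.
#'
#' @param tree Binary ultrametric `phylo` with at least 4 tips.
#' @param init A `gmyc_fit` from [fit_single_threshold()]; fitted here when
#'   omitted.
#' @param tol_improve Minimum log-likelihood gain to accept a move.
#' @param tol Ultrametricity tolerance.
#' @return An object of class `gmyc_fit` whose `logL` is >= `init$logL`.
#'   `thresholds` holds the sorted distinct local threshold ages (each the
#'   midpoint between a cluster root and its parent).
#' @export
fit_multiple_threshold <- function(tree, init = NULL, tol_improve = 2,
                                   tol = 1e-6) {
  pre <- if (inherits(tree, "coaldelim_gmyc_pre")) tree else {
    p <- gmyc_preprocess(tree, tol); class(p) <- "coaldelim_gmyc_pre"; p
  }
  if (is.null(init)) init <- fit_single_threshold(pre)
  state <- sort(init$cluster_roots)
  cur_opt <- optimize_gmyc_params(gmyc_interval_counts(pre, state))
  cur_logL <- max(cur_opt$logL, init$logL)

  neighbor_states <- function(roots) {
    out <- list()
    # split: replace a cluster root by its internal children
    for (r in roots) {
      kids <- pre$children[[r]]
      internal_kids <- kids[kids > pre$ntip]
      out[[length(out) + 1L]] <- sort(c(setdiff(roots, r), internal_kids))
    }
    # merge: a node all of whose children are tips or current roots, and
    # which is not itself inside a cluster, becomes a cluster root
    in_cluster <- integer(0)
    for (r in roots) in_cluster <- c(in_cluster, pre$desc_internal[[r]])
    for (v in pre$internals) {
      if (v %in% in_cluster) next
      kids <- pre$children[[v]]
      ok <- all(kids <= pre$ntip | kids %in% roots)
      if (ok) {
        out[[length(out) + 1L]] <- sort(c(setdiff(roots, kids), v))
      }
    }
    unique(out)
  }

  max_iter <- 10L * pre$ntip
  for (iter in seq_len(max_iter)) {
    nbrs <- neighbor_states(state)
    nbrs <- nbrs[!vapply(nbrs, identical, logical(1), y = state)]
    if (length(nbrs) == 0) break
    best_nb <- NULL
    for (nb in nbrs) {
      cnt <- gmyc_interval_counts(pre, nb)
      opt <- optimize_gmyc_params(cnt, extra_starts = matrix(cur_opt$raw, 1),
                                  grid = FALSE)
      if (opt$logL > cur_logL + tol_improve &&
          (is.null(best_nb) || opt$logL > best_nb$logL)) {
        best_nb <- list(state = nb, opt = opt, logL = opt$logL)
      }
    }
    if (is.null(best_nb)) break
    state <- best_nb$state
    # polish the accepted state from the full start grid
    cur_opt <- optimize_gmyc_params(gmyc_interval_counts(pre, state),
                                    extra_starts = matrix(best_nb$opt$raw, 1))
    cur_logL <- cur_opt$logL
  }

  cnt <- gmyc_interval_counts(pre, state)
  ent <- gmyc_entities(pre, state)
  thr <- local_threshold_ages(pre, state)
  null_fit <- init$null
  test <- lrt(cur_logL, null_fit$logL, df = 3 * max(1, length(thr)))
  structure(list(
    method = "multiple",
    tree = pre$tree,
    params = cur_opt$par,
    threshold = if (length(thr)) max(thr) else NA_real_,
    thresholds = thr,
    cluster_roots = state,
    clusters = ent$clusters,
    singletons = ent$singletons,
    n_entities = cnt$n_entities,
    logL = cur_logL,
    null = null_fit,
    LRT = c(test, df = 3 * max(1, length(thr))),
    conf_entities = init$conf_entities,
    candidates = init$candidates,
    single_logL = init$logL,
    n_switches = length(thr),
    converged = cur_opt$converged
  ), class = "gmyc_fit")
}

# Local threshold ages: midpoint between each cluster root and its parent
# (beyond-root placement when the root itself is a cluster root), distinct
# values sorted oldest first.
local_threshold_ages <- function(pre, roots) {
  if (length(roots) == 0) return(numeric(0))
  ages <- vapply(roots, function(r) {
    if (r == pre$root) return(pre$root_age * 1.05)
    (pre$age[r] + pre$age[pre$parent[r]]) / 2
  }, numeric(1))
  sort(unique(round(ages, 12)), decreasing = TRUE)
}

#' Fit the GMYC model
#'
#' Convenience front end: fits the null model and the single-threshold
#' model, and optionally continues with the multiple-threshold hill climb.
#'
#' @param tree Binary ultrametric `phylo`.
#' @param method `"single"` or `"multiple"`.
#' @param tol Ultrametricity tolerance.
#' @return A `gmyc_fit` object.
#' @export
fit_gmyc <- function(tree, method = c("single", "multiple"), tol = 1e-6) {
  method <- match.arg(method)
  single <- fit_single_threshold(tree, tol = tol)
  if (method == "single") return(single)
  fit_multiple_threshold(tree, init = single, tol = tol)
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC fit (", x$method, " threshold)\n", sep = "")
  cat(sprintf("  logL (GMYC)  : %.4f\n", x$logL))
  cat(sprintf("  logL (null)  : %.4f\n", x$null$logL))
  cat(sprintf("  LRT          : 2dL = %.4f, df = %d, p = %.4g\n",
              x$LRT$statistic, x$LRT$df, x$LRT$p.value))
  thr <- paste(sprintf("%.6f", -x$thresholds), collapse = ", ")
  cat("  threshold(s) :", thr, "\n")
  cat(sprintf("  entities     : %d (%d clusters + %d singletons)\n",
              x$n_entities, length(x$clusters), length(x$singletons)))
  cat("  conf. set    :", paste(x$conf_entities, collapse = ", "),
      "entities\n")
  invisible(x)
}

#' Tidy a GMYC fit into a tip-to-entity table
#'
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `tip`, `entity` (e.g. `"cluster_1"`,
#'   `"singleton_1"`) and `type`.
#' @method tidy gmyc_fit
#' @export
tidy.gmyc_fit <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x$clusters)) {
    rows[[length(rows) + 1L]] <- tibble(tip = x$clusters[[i]],
                                        entity = paste0("cluster_", i),
                                        type = "cluster")
  }
  for (i in seq_along(x$singletons)) {
    rows[[length(rows) + 1L]] <- tibble(tip = x$singletons[i],
                                        entity = paste0("singleton_", i),
                                        type = "singleton")
  }
  dplyr::bind_rows(rows) %>% dplyr::arrange(.data$tip)
}

#' One-row summary of a GMYC fit
#'
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihoods, LRT, entity accounting and
#'   the (negative-time) threshold.
#' @method glance gmyc_fit
#' @export
glance.gmyc_fit <- function(x, ...) {
  tibble(method = x$method,
         logL = x$logL, logL0 = x$null$logL,
         LRT_stat = x$LRT$statistic, LRT_df = x$LRT$df,
         LRT_p = x$LRT$p.value,
         threshold_time = -x$threshold,
         n_clusters = length(x$clusters),
         n_singletons = length(x$singletons),
         n_entities = x$n_entities,
         conf_low = min(x$conf_entities),
         conf_high = max(x$conf_entities))
}

#' @method autoplot gmyc_fit
#' @export
autoplot.gmyc_fit <- function(object, ...) {
  curve <- ltt_curve(object$tree)
  p <- autoplot(curve)
  p + ggplot2::geom_vline(xintercept = -object$thresholds,
                          colour = "red", linetype = "dashed") +
    ggplot2::labs(title = sprintf("GMYC (%s threshold): %d entities",
                                  object$method, object$n_entities))
}

#' Turn a GMYC fit into a named delimitation scenario
#'
#' Entities become species labels so a fit can feed the concordance and
#' species-tree stages directly.
#'
#' @param fit A `gmyc_fit`.
#' @param name Scenario name (default derived from the entity count).
#' @return A tibble with columns `sample` and `species`, plus attribute
#'   `scenario_name`.
#' @export
scenario_from_gmyc <- function(fit, name = NULL) {
  tab <- tidy.gmyc_fit(fit)
  name <- name %||% paste0("gmyc", fit$n_entities)
  out <- tibble(sample = tab$tip, species = tab$entity)
  attr(out, "scenario_name") <- name
  out
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
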