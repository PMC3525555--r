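#' Age of the most recent common ancestor of two tips
#'
#' @param gene_tree An ultrametric `phylo`.
#' @param tip_a,tip_b Tip labels.
#' @param tol Ultrametricity tolerance.
#' @return The MRCA's age (time back from the tips).
#' @export
coalescence_time <- function(gene_tree, tip_a, tip_b, tol = 1e-6) {
  validate_chronogram(gene_tree, tol = tol)
  miss <- setdiff(c(tip_a, tip_b), gene_tree$tip.label)
  if (length(miss) > 0) {
    stop_coaldelim(paste0("tips absent from tree: ", paste(miss, collapse = ", ")),
                   "coaldelim_validation_error")
  }
  mrca <- ape::getMRCA(gene_tree, c(tip_a, tip_b))
  node_ages(gene_tree)[mrca]
}

#' Maximum-tree (GLASS) species-tree estimate
#'
#' Estimates each species-pair divergence as the minimum coalescence time
#' over loci and over cross-species tip pairs, then builds the ultrametric
#' species tree by single-linkage clustering on those minima. Ties are
#' broken by alphabetical species-label order.
#'
#' @param gene_trees List of ultrametric `phylo` gene trees (loci).
#' @param scenario Data frame with columns `sample`, `species`.
#' @param tol Ultrametricity tolerance.
#' @return An ultrametric `phylo` over the species labels; node ages equal
#'   the single-linkage merge heights.
#' @export
maximum_tree <- function(gene_trees, scenario, tol = 1e-6) {
  scenario <- validate_scenario(scenario)
  species <- sort(unique(scenario$species))
  if (length(species) < 2) {
    stop_coaldelim("need at least 2 species for a species tree",
                   "coaldelim_validation_error")
  }
  D <- matrix(Inf, length(species), length(species),
              dimnames = list(species, species))
  for (tr in gene_trees) {
    validate_chronogram(tr, tol = tol)
    ages <- node_ages(tr)
    labs <- tr$tip.label
    sp_of <- scenario$species[match(labs, scenario$sample)]
    if (anyNA(sp_of)) {
      stop_coaldelim(paste0("gene-tree tips not in scenario: ",
                            paste(labs[is.na(sp_of)], collapse = ", ")),
                     "coaldelim_validation_error")
    }
    mrca_ages <- pairwise_mrca_ages(tr, ages)
    for (i in seq_along(labs)) {
      for (j in seq_len(i - 1L)) {
        si <- sp_of[i]; sj <- sp_of[j]
        if (si == sj) next
        a <- mrca_ages[i, j]
        if (a < D[si, sj]) D[si, sj] <- D[sj, si] <- a
      }
    }
  }
  off <- D[upper.tri(D)]
  if (any(!is.finite(off))) {
    bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
    pair <- paste0(species[bad[1, 1]], "/", species[bad[1, 2]])
    stop_coaldelim(paste0("species pair never co-sampled in any locus: ", pair),
                   "coaldelim_validation_error")
  }
  # hclust heights equal the supplied dissimilarities; ape halves them when
  # converting, so feed 2*D to land node ages on the divergence estimates
  hc <- stats::hclust(stats::as.dist(2 * D), method = "single")
  phy <- ape::as.phylo(hc)
  phy
}

# All-pairs MRCA ages for one tree (tips indexed as in tip.label).
pairwise_mrca_ages <- function(tr, ages) {
  n <- ape::Ntip(tr)
  out <- matrix(0, n, n)
  # for each internal node, tip pairs split between its two child subtrees
  # have their MRCA there
  children <- vector("list", n + tr$Nnode)
  for (i in seq_len(nrow(tr$edge))) {
    children[[tr$edge[i, 1L]]] <- c(children[[tr$edge[i, 1L]]], tr$edge[i, 2L])
  }
  tips_under <- vector("list", n + tr$Nnode)
  for (t in seq_len(n)) tips_under[[t]] <- t
  level <- integer(n + tr$Nnode)
  queue <- n + 1L
  while (length(queue) > 0) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in children[[v]]) { level[ch] <- level[v] + 1L; queue <- c(queue, ch) }
  }
  internals <- (n + 1L):(n + tr$Nnode)
  for (v in internals[order(level[internals], decreasing = TRUE)]) {
    kids <- children[[v]]
    sets <- lapply(kids, function(k) tips_under[[k]])
    for (a in seq_along(sets)) {
      for (b in seq_len(a - 1L)) {
        out[sets[[a]], sets[[b]]] <- ages[v]
        out[sets[[b]], sets[[a]]] <- ages[v]
      }
    }
    tips_under[[v]] <- unlist(sets)
  }
  out
}

#' Multispecies-coalescent log-likelihood of gene trees given a species tree
#'
#' Analytic coalescent likelihood with a single population-size parameter
#' `theta` shared across all species-tree branches: within a population
#' carrying `j` gene lineages over a span `dt` the contribution is
#' `-j*(j-1)*dt/theta`, plus `log(2/theta)` per coalescence inside it.
#' Gene-tree coalescences between species must be older than the species
#' divergence; otherwise the likelihood is `-Inf` (returned as a sentinel
#' with a diagnostic attribute, never an exception).
#'
#' @param gene_trees List of binary ultrametric `phylo` gene trees.
#' @param species_tree Ultrametric `phylo` over species labels, or `NULL`
#'   for the one-species model (a single panmictic population).
#' @param scenario Data frame with columns `sample`, `species`.
#' @param theta Scaled population size, `> 0`.
#' @param tol Ultrametricity tolerance.
#' @return Log-likelihood summed over loci. Attribute `"suff"` carries the
#'   sufficient statistics `c(A, C)` (`A` = total of `j*(j-1)*dt`, `C` =
#'   total coalescences), so `logL = C*log(2/theta) - A/theta`.
#' @export
msc_loglik <- function(gene_trees, species_tree, scenario, theta = 1,
                       tol = 1e-6) {
  if (theta <= 0) {
    stop_coaldelim("theta must be > 0", "coaldelim_validation_error")
  }
  suff <- msc_suffstats(gene_trees, species_tree, scenario, tol = tol)
  if (!is.null(attr(suff, "incompatible"))) {
    out <- -Inf
    attr(out, "incompatible") <- attr(suff, "incompatible")
    return(out)
  }
  out <- suff[["C"]] * log(2 / theta) - suff[["A"]] / theta
  attr(out, "suff") <- suff
  out
}

# Sufficient statistics (A = sum j(j-1)dt, C = number of coalescences) of
# the MSC likelihood; -Inf cases flagged via attr "incompatible".
msc_suffstats <- function(gene_trees, species_tree, scenario, tol = 1e-6) {
  scenario <- validate_scenario(scenario)
  A <- 0; C <- 0
  violations <- character(0)

  if (!is.null(species_tree)) {
    validate_chronogram(species_tree, tol = tol)
    sp_ages <- node_ages(species_tree)
    sp_ntip <- ape::Ntip(species_tree)
    sp_parent <- integer(sp_ntip + species_tree$Nnode)
    for (i in seq_len(nrow(species_tree$edge))) {
      sp_parent[species_tree$edge[i, 2L]] <- species_tree$edge[i, 1L]
    }
    sp_root <- sp_ntip + 1L
  }

  for (li in seq_along(gene_trees)) {
    tr <- gene_trees[[li]]
    validate_chronogram(tr, tol = tol)
    if (!ape::is.binary(tr)) {
      stop_coaldelim("gene trees must be fully bifurcating",
                     "coaldelim_validation_error")
    }
    ages <- node_ages(tr)
    n <- ape::Ntip(tr)
    sp_of_tip <- scenario$species[match(tr$tip.label, scenario$sample)]
    if (anyNA(sp_of_tip)) {
      stop_coaldelim("gene-tree tips missing from scenario",
                     "coaldelim_validation_error")
    }

    if (is.null(species_tree)) {
      # one population: standard coalescent bookkeeping on event ages
      ev <- sort(ages[(n + 1L):(n + tr$Nnode)])
      j <- n
      t_prev <- 0
      for (e in ev) {
        A <- A + j * (j - 1) * (e - t_prev)
        C <- C + 1
        j <- j - 1L
        t_prev <- e
      }
      next
    }

    # map each gene-tree coalescence to its species-tree population
    st_tip_idx <- match(sp_of_tip, species_tree$tip.label)
    if (anyNA(st_tip_idx)) {
      stop_coaldelim("scenario species missing from species tree",
                     "coaldelim_validation_error")
    }
    gt_children <- vector("list", n + tr$Nnode)
    for (i in seq_len(nrow(tr$edge))) {
      gt_children[[tr$edge[i, 1L]]] <- c(gt_children[[tr$edge[i, 1L]]],
                                         tr$edge[i, 2L])
    }
    level <- integer(n + tr$Nnode)
    queue <- n + 1L
    while (length(queue) > 0) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ch in gt_children[[v]]) { level[ch] <- level[v] + 1L; queue <- c(queue, ch) }
    }
    # species-tree MRCA node of the tips under each gene-tree node
    st_mrca <- integer(n + tr$Nnode)
    st_mrca[seq_len(n)] <- st_tip_idx
    internals <- (n + 1L):(n + tr$Nnode)
    ord <- internals[order(level[internals], decreasing = TRUE)]
    st_mrca_pair <- function(a, b) {
      # walk ancestors of a (cheap: species trees are small)
      anc <- a
      v <- a
      while (v != sp_root) { v <- sp_parent[v]; anc <- c(anc, v) }
      v <- b
      while (!(v %in% anc)) v <- sp_parent[v]
      v
    }
    events <- vector("list", length(ord))
    for (k in seq_along(ord)) {
      v <- ord[k]
      kids <- gt_children[[v]]
      st_mrca[v] <- st_mrca_pair(st_mrca[kids[1L]], st_mrca[kids[2L]])
      # population containing the event: walk up from the species MRCA
      # until the branch's span [age(u), age(parent(u))) covers the event
      t_ev <- ages[v]
      if (t_ev < sp_ages[st_mrca[v]] - tol * max(sp_ages)) {
        violations <- c(violations,
                        sprintf("locus %d node at age %.6g predates divergence of %s",
                                li, t_ev,
                                paste(unique(sp_of_tip[match(tip_set(tr, v), tr$tip.label)]),
                                      collapse = "/")))
        next
      }
      u <- st_mrca[v]
      while (u != sp_root && sp_ages[sp_parent[u]] <= t_ev) u <- sp_parent[u]
      events[[k]] <- c(pop = u, age = t_ev)
    }
    if (length(violations) > 0) next

    # per-population lineage bookkeeping, tips-to-root over species tree
    ev_pop <- vapply(events, function(e) e[["pop"]], numeric(1))
    ev_age <- vapply(events, function(e) e[["age"]], numeric(1))
    sp_level <- integer(sp_ntip + species_tree$Nnode)
    sp_children <- vector("list", sp_ntip + species_tree$Nnode)
    for (i in seq_len(nrow(species_tree$edge))) {
      sp_children[[species_tree$edge[i, 1L]]] <-
        c(sp_children[[species_tree$edge[i, 1L]]], species_tree$edge[i, 2L])
    }
    queue <- sp_root
    while (length(queue) > 0) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ch in sp_children[[v]]) { sp_level[ch] <- sp_level[v] + 1L; queue <- c(queue, ch) }
    }
    all_pops <- seq_len(sp_ntip + species_tree$Nnode)
    exiting <- integer(sp_ntip + species_tree$Nnode)
    for (u in all_pops[order(sp_level[all_pops], decreasing = TRUE)]) {
      t0 <- sp_ages[u]
      t1 <- if (u == sp_root) Inf else sp_ages[sp_parent[u]]
      j <- if (u <= sp_ntip) sum(st_tip_idx == u)
           else sum(exiting[sp_children[[u]]])
      inside <- which(ev_pop == u)
      for (e in inside[order(ev_age[inside])]) {
        A <- A + j * (j - 1) * (ev_age[e] - t0)
        C <- C + 1
        j <- j - 1L
        t0 <- ev_age[e]
      }
      if (is.finite(t1)) A <- A + j * (j - 1) * (t1 - t0)
      exiting[u] <- j
    }
  }

  out <- c(A = A, C = C)
  if (length(violations) > 0) attr(out, "incompatible") <- violations
  out
}

tip_set <- function(tr, v) {
  n <- ape::Ntip(tr)
  if (v <= n) return(tr$tip.label[v])
  ape::extract.clade(tr, v)$tip.label
}

#' Profile maximum-likelihood estimate of theta
#'
#' With `C` coalescences and `A = sum j(j-1)dt` across loci and
#' populations, the shared-theta likelihood `C*log(2/theta) - A/theta` is
#' maximized at `theta = A/C`.
#'
#' @inheritParams msc_loglik
#' @return A list with `theta`, `logL`.
#' @export
profile_theta <- function(gene_trees, species_tree, scenario, tol = 1e-6) {
  suff <- msc_suffstats(gene_trees, species_tree, scenario, tol = tol)
  if (!is.null(attr(suff, "incompatible"))) {
    return(list(theta = NA_real_, logL = -Inf,
                incompatible = attr(suff, "incompatible")))
  }
  theta <- suff[["A"]] / suff[["C"]]
  list(theta = theta,
       logL = suff[["C"]] * log(2 / theta) - suff[["A"]] / theta)
}

#' Compare species-delimitation scenarios under the multispecies coalescent
#'
#' For each scenario: estimates the species tree by [maximum_tree()]
#' (one-species scenarios use a single panmictic population), computes the
#' MSC log-likelihood with a shared `theta` (fixed, or profiled per
#' scenario), and reports `-lnL`, parameter count `k = #species + 1`,
#' `delta lnL` against the reference scenario, a Bonferroni-corrected LRT
#' p-value (`df = delta k`, factor = number of comparisons against the
#' reference), and `AIC = 2k + 2(-lnL)`. Scenarios are ranked by
#' `delta lnL`; the AIC-best scenario is flagged separately.
#'
#' @param gene_trees List of binary ultrametric `phylo` gene trees.
#' @param scenarios Named list of scenario data frames (`sample`,
#'   `species`); the first is the reference unless one is named
#'   `"1-species"` or has a single species.
#' @param theta Fixed shared theta (default 1), ignored when
#'   `theta_policy = "profile"`.
#' @param theta_policy `"fixed"` or `"profile"`.
#' @param tol Ultrametricity tolerance.
#' @return A tibble with one row per scenario: `scenario`, `neg_lnL`, `k`,
#'   `delta_lnL`, `p_corrected`, `AIC`, `theta`, `aic_best`, ordered as
#'   given; classed `msc_comparison`.
#' @export
compare_scenarios <- function(gene_trees, scenarios, theta = 1,
                              theta_policy = c("fixed", "profile"),
                              tol = 1e-6) {
  theta_policy <- match.arg(theta_policy)
  if (length(scenarios) < 2) {
    stop_coaldelim("need at least 2 scenarios", "coaldelim_validation_error")
  }
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  scenarios <- lapply(scenarios, validate_scenario)
  universes <- lapply(scenarios, function(s) sort(unique(s$sample)))
  if (length(unique(universes)) != 1) {
    stop_coaldelim("scenarios must cover the same samples",
                   "coaldelim_validation_error")
  }

  rows <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    n_sp <- length(unique(sc$species))
    sp_tree <- if (n_sp == 1) NULL else maximum_tree(gene_trees, sc, tol = tol)
    if (theta_policy == "profile") {
      pr <- profile_theta(gene_trees, sp_tree, sc, tol = tol)
      th <- pr$theta; ll <- pr$logL
    } else {
      th <- theta
      ll <- as.numeric(msc_loglik(gene_trees, sp_tree, sc, theta = th, tol = tol))
    }
    tibble(scenario = nm, lnL = ll, k = n_sp + 1L, n_species = n_sp,
           theta = th)
  })
  out <- dplyr::bind_rows(rows)

  ref_idx <- which(out$n_species == 1)
  ref_idx <- if (length(ref_idx) > 0) ref_idx[1] else 1L
  ref_lnL <- out$lnL[ref_idx]
  ref_k <- out$k[ref_idx]
  n_comp <- nrow(out) - 1L
  out <- out %>%
    dplyr::mutate(
      neg_lnL = -.data$lnL,
      delta_lnL = .data$lnL - ref_lnL,
      AIC = 2 * .data$k + 2 * .data$neg_lnL)
  out$p_raw <- vapply(seq_len(nrow(out)), function(i) {
    df <- abs(out$k[i] - ref_k)
    lrt(out$lnL[i], ref_lnL, df = df)$p.value
  }, numeric(1))
  out$p_corrected <- pmin(1, out$p_raw * n_comp)
  out$p_corrected[ref_idx] <- NA_real_
  out$aic_best <- seq_len(nrow(out)) == which.min(out$AIC)
  out <- out %>%
    dplyr::select("scenario", "neg_lnL", "k", "delta_lnL", "p_corrected",
                  "AIC", "theta", "n_species", "aic_best")
  class(out) <- c("msc_comparison", class(out))
  out
}

#' Scenario-table arithmetic from externally supplied likelihood scores
#'
#' The reporting half of [compare_scenarios()], usable when per-scenario
#' `-lnL` values and parameter counts come from elsewhere (e.g. a published
#' table): computes `delta lnL` against the reference scenario,
#' Bonferroni-corrected LRT p-values and AIC.
#'
#' @param scenario Character vector of scenario names.
#' @param neg_lnL Numeric vector of `-lnL` scores.
#' @param k Integer vector of parameter counts.
#' @param reference Index or name of the reference scenario (default 1).
#' @return A tibble with `scenario`, `neg_lnL`, `k`, `delta_lnL`,
#'   `p_corrected`, `AIC`.
#' @export
scenario_table <- function(scenario, neg_lnL, k, reference = 1L) {
  stopifnot(length(scenario) == length(neg_lnL),
            length(scenario) == length(k))
  if (is.character(reference)) reference <- match(reference, scenario)
  lnL <- -neg_lnL
  ref_lnL <- lnL[reference]
  ref_k <- k[reference]
  n_comp <- length(scenario) - 1L
  p_raw <- vapply(seq_along(scenario), function(i) {
    lrt(lnL[i], ref_lnL, df = abs(k[i] - ref_k))$p.value
  }, numeric(1))
  p_corrected <- pmin(1, p_raw * n_comp)
  p_corrected[reference] <- NA_real_
  tibble(scenario = scenario, neg_lnL = neg_lnL, k = as.integer(k),
         delta_lnL = lnL - ref_lnL, p_corrected = p_corrected,
         AIC = 2 * k + 2 * neg_lnL)
}
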