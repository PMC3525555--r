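# Independent oracles used to cross-check the package's likelihoods and
# algorithms. These deliberately share no code with the implementation:
# ages come from ape::dist.nodes geometry, Fitch counts from exhaustive
# enumeration, and intervals are accumulated one by one in plain loops.

# Straight-line GMYC/coalescent log-likelihood. `cluster_tipsets` are the
# tip-label sets of the coalescent clusters (each a complete clade of the
# tree); everything else is diversification. Slices time at every distinct
# internal-node age and sums interval by interval.
oracle_mixed_loglik <- function(tree, cluster_tipsets, lambda_y, p_y,
                                lambda_c, p_c) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  dn <- ape::dist.nodes(tree)
  depth <- dn[root, ]
  age <- max(depth[seq_len(ntip)]) - depth
  age[seq_len(ntip)] <- 0
  node_ids <- seq_len(ntip + tree$Nnode)
  tips_below <- lapply(node_ids, function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    ape::extract.clade(tree, v)$tip.label
  })
  # each cluster is a complete clade, so membership is tip-subset inclusion
  node_cluster <- integer(length(node_ids))
  for (k in seq_along(cluster_tipsets)) {
    inside <- vapply(node_ids, function(v) {
      all(tips_below[[v]] %in% cluster_tipsets[[k]])
    }, logical(1))
    node_cluster[inside] <- k
  }
  parent_of <- function(v) tree$edge[tree$edge[, 2] == v, 1]

  int_ages <- age[(ntip + 1L):(ntip + tree$Nnode)]
  ev <- sort(unique(int_ages), decreasing = TRUE)
  bounds <- c(ev, 0)
  ll <- 0
  for (j in seq_along(ev)) {
    hi <- bounds[j]; lo <- bounds[j + 1]
    mid <- (hi + lo) / 2
    crossing <- Filter(function(v) {
      v != root && age[v] < mid && age[parent_of(v)] > mid
    }, node_ids)
    # a crossing branch belongs to the cluster containing its parent node
    cl <- vapply(crossing, function(v) node_cluster[parent_of(v)], integer(1))
    ny <- sum(cl == 0)
    vsum <- 0
    for (k in seq_along(cluster_tipsets)) {
      nk <- sum(cl == k)
      if (nk > 1) vsum <- vsum + (nk * (nk - 1))^p_c
    }
    b <- lambda_y * (if (ny > 0) ny^p_y else 0) + lambda_c * vsum
    m <- sum(abs(int_ages - hi) < 1e-9)
    if (b <= 0 && m > 0) return(-Inf)
    ll <- ll + m * log(b) - b * (hi - lo)
  }
  ll
}

# Single-population special case of the oracle.
oracle_null_loglik <- function(tree, lambda, p) {
  oracle_mixed_loglik(tree, list(tree$tip.label), 0, 1, lambda, p)
}

# Exhaustive Fitch oracle: minimum changes over all internal-node state
# assignments (feasible for <= 8 tips).
oracle_fitch <- function(tree, states) {
  states <- states[!is.na(states)]
  tree <- ape::keep.tip(tree, intersect(tree$tip.label, names(states)))
  ntip <- ape::Ntip(tree)
  obs <- sort(unique(as.character(states)))
  nnode <- tree$Nnode
  grid <- expand.grid(rep(list(obs), nnode), stringsAsFactors = FALSE)
  tip_state <- as.character(states[tree$tip.label])
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(tip_state, unlist(grid[g, ], use.names = FALSE))
    changes <- sum(assign_all[tree$edge[, 1]] != assign_all[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Convenience: a well-separated mixed tree plus its truth.
sim_separated <- function(K, n_per, seed, theta = 1, separation = 10) {
  simulate_gmyc_tree(K = K, n_per = n_per, theta = theta, lambda = 1,
                     separation = separation, seed = seed)
}
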