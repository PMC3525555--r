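# Internal machinery shared by the GMYC likelihoods and threshold searches.
#
# A fitted model state is represented by the set of *cluster roots*: the
# antichain of internal nodes whose subtrees are the coalescent clusters.
# Tips not below any cluster root are singletons. Branches above cluster
# roots (and above singletons) are diversification ("Yule") lineages;
# branches at or below a cluster root are within-species lineages. This is
# equivalent to a set of subtree-local thresholds: the threshold governing a
# cluster lies anywhere strictly between the cluster root's age and its
# parent's age.

# One-off preprocessing of a binary ultrametric tree.
gmyc_preprocess <- function(tree, tol = 1e-6) {
  validate_chronogram(tree, tol = tol, binary = TRUE)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  if (ntip < 3) {
    stop_coaldelim("GMYC needs at least 3 tips", "coaldelim_degenerate_error")
  }
  age <- node_ages(tree)
  age[seq_len(ntip)] <- 0  # snap tip ages: ultrametricity already validated
  root <- ntip + 1L
  parent <- integer(ntip + nnode)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]

  internals <- (ntip + 1L):(ntip + nnode)
  # descendant internal nodes (self included) and descendant tips, per node
  children <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(tree$edge))) {
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  }
  desc_internal <- vector("list", ntip + nnode)
  desc_tips <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) desc_tips[[t]] <- t
  # postorder over internal nodes: order by decreasing topological level
  level <- integer(ntip + nnode)
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in children[[v]]) { level[ch] <- level[v] + 1L; queue <- c(queue, ch) }
  }
  for (v in internals[order(level[internals], decreasing = TRUE)]) {
    kids <- children[[v]]
    desc_internal[[v]] <- c(v, unlist(desc_internal[kids]))
    desc_tips[[v]] <- unlist(desc_tips[kids])
  }

  # distinct branching ages (zero-length spans merged) and interval grid
  int_age <- age[internals]
  ord <- order(int_age, decreasing = TRUE)
  sorted <- int_age[ord]
  grp_tol <- max(age[root], 1e-300) * 1e-10
  grp <- cumsum(c(1L, as.integer(diff(sorted) < -grp_tol)))
  d <- as.numeric(tapply(sorted, grp, mean))          # distinct ages, descending
  mult <- as.integer(table(grp))                      # events per distinct age
  K <- length(d)
  lower <- c(d[-1L], 0)
  x <- d - lower                                      # interval widths, root-ward first
  mids <- (d + lower) / 2

  # crossing geometry: which branches span each interval (root-independent)
  bch <- tree$edge[, 2L]
  bca <- age[bch]
  bpa <- age[tree$edge[, 1L]]
  cross <- outer(mids, bca, `>`) & outer(mids, bpa, `<`)  # K x B

  list(tree = tree, ntip = ntip, nnode = nnode, root = root, age = age,
       parent = parent, children = children,
       desc_internal = desc_internal, desc_tips = desc_tips,
       internals = internals, d = d, mult = mult, x = x, K = K,
       cross = cross, branch_child = bch, root_age = age[root])
}

# Cluster roots implied by a single global threshold age T:
# internal nodes younger than T whose parent is at/older than T (or the
# root itself when the whole tree is younger than T).
cluster_roots_at_threshold <- function(pre, T) {
  v <- pre$internals
  pa <- pre$parent[v]
  pa_age <- rep(Inf, length(v))        # the root has no parent
  pa_age[pa > 0] <- pre$age[pa[pa > 0]]
  v[pre$age[v] < T & pa_age >= T]
}

# Per-interval lineage bookkeeping for a given cluster-root set.
# Returns the pieces the likelihood needs: nY (diversification lineages per
# interval), W (per-cluster n_j*(n_j-1) matrix), plus entity accounting.
gmyc_interval_counts <- function(pre, roots) {
  B <- length(pre$branch_child)
  cluster_of_node <- integer(pre$ntip + pre$nnode)
  if (length(roots) > 0) {
    for (i in seq_along(roots)) {
      cluster_of_node[pre$desc_internal[[roots[i]]]] <- i
    }
  }
  # a branch belongs to cluster i iff its parent node is inside cluster i
  bcl <- cluster_of_node[pre$parent[pre$branch_child]]
  # (parent of root is 0 -> treated as interspecific; root has no branch
  # above it anyway because branch_child never equals root)
  inter <- bcl == 0L
  nY <- rowSums(pre$cross[, inter, drop = FALSE])
  nC <- length(roots)
  if (nC > 0) {
    ind <- matrix(0, B, nC)
    sel <- bcl > 0L
    ind[cbind(which(sel), bcl[sel])] <- 1
    Ncl <- pre$cross %*% ind
    W <- Ncl * (Ncl - 1)
  } else {
    W <- matrix(0, pre$K, 0)
  }
  tips <- seq_len(pre$ntip)
  sing <- tips[cluster_of_node[pre$parent[tips]] == 0L]
  list(nY = nY, W = W, Wpos = W > 0, x = pre$x, mult = pre$mult,
       roots = roots, singletons = sing,
       n_entities = length(roots) + length(sing))
}

# Materialize cluster tip memberships (labels) for reporting.
gmyc_entities <- function(pre, roots) {
  labs <- pre$tree$tip.label
  clusters <- lapply(roots, function(r) labs[pre$desc_tips[[r]]])
  sing <- gmyc_interval_counts(pre, roots)$singletons
  list(clusters = clusters, singletons = labs[sing])
}
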