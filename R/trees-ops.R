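#' Resolve polytomies into zero-length bifurcations
#'
#' Every multifurcation is replaced by a left-to-right caterpillar of
#' bifurcations joined by zero-length internal branches, so the tip set and
#' all pairwise tip path lengths are unchanged. Child order within a
#' polytomy is the alphabetical order of each child clade's smallest tip
#' label; supplying a `seed` replaces that order by a seed-determined
#' shuffle. Support labels, if present, stay attached to the original node;
#' inserted nodes carry empty labels.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param seed Optional integer; shuffles child order reproducibly.
#' @return A fully bifurcating `phylo` with the same tips and path lengths.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  # a basal trifurcation counts as a root polytomy here, so the usual
  # is.rooted() check (which calls such trees unrooted) is deliberately
  # not applied
  if (!inherits(tree, "phylo")) {
    stop_coaldelim("not a phylo object", "coaldelim_validation_error")
  }
  if (is.null(tree$edge.length)) {
    stop_coaldelim("tree has no branch lengths", "coaldelim_validation_error")
  }
  # treat a basal trifurcation as a polytomy too, so count children directly
  if (max(tabulate(tree$edge[, 1L])) <= 2L) return(tree)

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  children <- vector("list", ntip + nnode)
  edge_len <- numeric(ntip + nnode)  # length of branch above each node
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    children[[p]] <- c(children[[p]], ch)
    edge_len[ch] <- tree$edge.length[i]
  }
  node_lab <- tree$node.label %||% rep("", nnode)

  # smallest tip label under each node, for deterministic child ordering;
  # process internal nodes deepest-first (topological level, robust to
  # zero-length branches) so children are always resolved before parents
  level <- integer(ntip + nnode)
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in children[[v]]) {
      level[ch] <- level[v] + 1L
      queue <- c(queue, ch)
    }
  }
  min_tip <- character(ntip + nnode)
  min_tip[seq_len(ntip)] <- tree$tip.label
  internals <- (ntip + 1L):(ntip + nnode)
  for (v in internals[order(level[internals], decreasing = TRUE)]) {
    min_tip[v] <- min(min_tip[children[[v]]])
  }

  emit <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    kids <- children[[v]]
    kids <- kids[order(min_tip[kids])]
    if (!is.null(seed) && length(kids) > 2L) kids <- sample(kids)
    parts <- vapply(kids, function(k) {
      paste0(emit(k), ":", format(edge_len[k], digits = 15, scientific = FALSE))
    }, character(1))
    lab <- node_lab[v - ntip]
    if (length(parts) == 2L) {
      return(paste0("(", parts[1L], ",", parts[2L], ")", lab))
    }
    cur <- paste0("(", parts[1L], ",", parts[2L], ")")
    for (i in seq(3L, length(parts))) {
      close_lab <- if (i == length(parts)) lab else ""
      cur <- paste0("(", cur, ":0,", parts[i], ")", close_lab)
    }
    cur
  }

  newick <- with_seed(seed, paste0(emit(root), ";"))
  out <- ape::read.tree(text = newick)
  out
}

#' Drop tips from a tree
#'
#' Removes the given tips, suppressing the resulting degree-two nodes and
#' summing their branch lengths (the usual outgroup-removal step before
#' model fitting).
#'
#' @param tree A `phylo` object.
#' @param labels Character vector of tip labels to remove (may be empty).
#' @return The induced subtree on the remaining tips.
#' @export
prune_tips <- function(tree, labels) {
  if (!inherits(tree, "phylo")) {
    stop_coaldelim("not a phylo object", "coaldelim_validation_error")
  }
  labels <- as.character(labels)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown) > 0) {
    stop_coaldelim(paste0("tips not in tree: ", paste(unknown, collapse = ", ")),
                   "coaldelim_validation_error")
  }
  if (length(labels) == 0) return(tree)
  if (ape::Ntip(tree) - length(labels) < 2) {
    stop_coaldelim("fewer than 2 tips would remain", "coaldelim_validation_error")
  }
  ape::drop.tip(tree, labels)
}

#' Lineage-through-time curve
#'
#' For a binary ultrametric tree, returns the step coordinates of the
#' lineage-through-time curve: one row per branching event, with time on the
#' negative-age convention (0 = present, root at `-root age`) and the number
#' of lineages immediately after the event. The first row has 2 lineages at
#' the root; the last reaches the number of tips.
#'
#' @param tree A binary ultrametric `phylo`.
#' @param tol Ultrametricity tolerance passed to [validate_chronogram()].
#' @return A tibble with columns `time` and `lineages`, classed
#'   `coaldelim_ltt` so that [ggplot2::autoplot()] draws the step plot.
#' @export
ltt_curve <- function(tree, tol = 1e-6) {
  validate_chronogram(tree, tol = tol, binary = TRUE)
  ages <- node_ages(tree)[(ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)]
  ages <- sort(ages, decreasing = TRUE)
  out <- tibble(time = -ages, lineages = seq.int(2L, ape::Ntip(tree)))
  class(out) <- c("coaldelim_ltt", class(out))
  out
}

#' @method autoplot coaldelim_ltt
#' @export
autoplot.coaldelim_ltt <- function(object, ...) {
  df <- as_tibble(object)
  # extend the curve to the present so the final count is visible
  df2 <- rbind(df, tibble(time = 0, lineages = max(df$lineages)))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$time, y = .data$lineages)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "time before present", y = "lineages") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
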