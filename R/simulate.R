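# Seeded generators with the statistical structure the analyses assume:
# Yule species trees, Kingman coalescents within populations of a species
# tree, mixed species/population trees with known membership, clade-
# associated discrete characters, and Jukes-Cantor alignments.

fmt_bl <- function(x) sprintf("%.15g", x)

# Lineages are (newick, root age) pairs; coalesce them with pairwise rate
# 2/theta from time t0 until t_end (Inf = until one lineage remains).
# Returns the surviving lineages and the time reached.
coalesce_lineages <- function(lineages, theta, t0, t_end) {
  t <- t0
  while (length(lineages) > 1) {
    j <- length(lineages)
    wait <- stats::rexp(1, rate = j * (j - 1) / theta)
    if (t + wait > t_end) return(list(lineages = lineages, t = t_end))
    t <- t + wait
    pair <- sample.int(j, 2)
    a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
    merged <- list(
      nwk = paste0("(", a$nwk, ":", fmt_bl(t - a$age), ",",
                   b$nwk, ":", fmt_bl(t - b$age), ")"),
      age = t)
    lineages <- c(lineages[-pair], list(merged))
  }
  list(lineages = lineages, t = t)
}

lineage_tip <- function(label) list(nwk = label, age = 0)

finish_tree <- function(lineages) {
  stopifnot(length(lineages) == 1)
  ape::read.tree(text = paste0(lineages[[1]]$nwk, ";"))
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Forward construction: starting from two lineages at the root, with `i`
#' lineages the next speciation arrives after an exponential wait with rate
#' `lambda * i`; after the K-th lineage appears one further exponential
#' stretch (rate `lambda * K`) separates the last split from the present,
#' so the expected root age is `sum_{i=2..K} 1/(i*lambda)`.
#'
#' @param K Number of species (>= 2).
#' @param lambda Speciation rate (> 0).
#' @param seed Optional integer seed.
#' @param labels Tip labels (default `sp1..spK`).
#' @return An ultrametric `phylo` with `K` tips.
#' @export
simulate_yule_tree <- function(K, lambda = 1, seed = NULL,
                               labels = paste0("sp", seq_len(K))) {
  if (K < 2) stop_coaldelim("K must be >= 2", "coaldelim_validation_error")
  if (lambda <= 0) stop_coaldelim("lambda must be > 0",
                                  "coaldelim_validation_error")
  with_seed(seed, {
    # record split depths going forward, then convert to ages
    waits <- stats::rexp(K - 1, rate = lambda * (2:K))
    # split i happens after cumulative time; root at time 0
    split_times <- c(0, cumsum(waits)[seq_len(K - 2)])
    total <- sum(waits)
    # build by forward splitting: each active lineage later becomes a cherry
    # use a recursive assembly on the (random) lineage chosen to split
    lineage_birth <- c(0, 0)            # birth time of each active lineage
    lineage_id <- c(1L, 2L)
    splits <- list()                     # (parent id, time, new id)
    next_id <- 3L
    for (s in seq_len(K - 2)) {
      t_split <- split_times[s + 1]
      pick <- sample.int(length(lineage_id), 1)
      splits[[s]] <- c(parent = lineage_id[pick], time = t_split,
                       child = next_id)
      lineage_birth <- c(lineage_birth, t_split)
      lineage_id <- c(lineage_id, next_id)
      next_id <- next_id + 1L
    }
    # assemble newick backwards: each lineage is a path with cherries
    # hanging off at its split times
    subtree <- function(id, birth) {
      ev <- Filter(function(sp) sp[["parent"]] == id, splits)
      times <- vapply(ev, `[[`, numeric(1), "time")
      ord <- order(times)
      cur_nwk <- labels[id]
      cur_age <- 0
      # walk from present backwards over this lineage's splits
      for (k in rev(ord)) {
        t_sp <- times[k]
        child <- ev[[k]][["child"]]
        depth_here <- total - t_sp     # age of this split
        ch <- subtree(child, t_sp)
        cur_nwk <- paste0("(", cur_nwk, ":", fmt_bl(depth_here - cur_age),
                          ",", ch$nwk, ":", fmt_bl(depth_here - ch$age), ")")
        cur_age <- depth_here
      }
      list(nwk = cur_nwk, age = cur_age)
    }
    left <- subtree(1L, 0)
    right <- subtree(2L, 0)
    root_age <- total
    nwk <- paste0("(", left$nwk, ":", fmt_bl(root_age - left$age), ",",
                  right$nwk, ":", fmt_bl(root_age - right$age), ");")
    ape::read.tree(text = nwk)
  })
}

#' Simulate a single-population Kingman coalescent tree
#'
#' Pairwise coalescence rate `2/theta`: with `j` lineages the waiting time
#' to the next coalescence is exponential with rate `j*(j-1)/theta`.
#'
#' @param n Number of tips (>= 2).
#' @param theta Scaled population size (> 0).
#' @param seed Optional integer seed.
#' @param labels Tip labels.
#' @return An ultrametric `phylo`.
#' @export
simulate_coalescent_tree <- function(n, theta = 1, seed = NULL,
                                     labels = paste0("t", seq_len(n))) {
  if (n < 2) stop_coaldelim("n must be >= 2", "coaldelim_validation_error")
  if (theta <= 0) stop_coaldelim("theta must be > 0",
                                 "coaldelim_validation_error")
  with_seed(seed, {
    res <- coalesce_lineages(lapply(labels, lineage_tip), theta, 0, Inf)
    finish_tree(res$lineages)
  })
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Kingman coalescent (pairwise rate `2/theta`) within each population of
#' the species tree; surviving lineages are pooled at species divergences
#' and the process continues above the root with the same `theta`. Tips are
#' labelled `species_sample`.
#'
#' @param species_tree Ultrametric `phylo` over species labels.
#' @param n_per Samples per species: scalar or named vector.
#' @param theta Scaled population size (> 0).
#' @param loci Number of gene trees to simulate.
#' @param seed Optional integer seed.
#' @return List of ultrametric `phylo` gene trees (length `loci`).
#' @export
simulate_msc_gene_trees <- function(species_tree, n_per, theta = 1,
                                    loci = 1, seed = NULL) {
  if (theta <= 0) stop_coaldelim("theta must be > 0",
                                 "coaldelim_validation_error")
  validate_chronogram(species_tree)
  sp <- species_tree$tip.label
  if (length(n_per) == 1 && is.null(names(n_per))) {
    n_per <- stats::setNames(rep(n_per, length(sp)), sp)
  }
  if (!all(sp %in% names(n_per))) {
    stop_coaldelim("n_per must name every species", "coaldelim_validation_error")
  }
  ages <- node_ages(species_tree)
  ntip <- ape::Ntip(species_tree)
  parent <- integer(ntip + species_tree$Nnode)
  children <- vector("list", ntip + species_tree$Nnode)
  for (i in seq_len(nrow(species_tree$edge))) {
    parent[species_tree$edge[i, 2L]] <- species_tree$edge[i, 1L]
    children[[species_tree$edge[i, 1L]]] <-
      c(children[[species_tree$edge[i, 1L]]], species_tree$edge[i, 2L])
  }
  root <- ntip + 1L
  level <- integer(ntip + species_tree$Nnode)
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in children[[v]]) { level[ch] <- level[v] + 1L; queue <- c(queue, ch) }
  }
  pops <- seq_len(ntip + species_tree$Nnode)
  pops <- pops[order(level[pops], decreasing = TRUE)]

  sim_one <- function() {
    pending <- vector("list", ntip + species_tree$Nnode)
    for (u in pops) {
      if (u <= ntip) {
        labs <- paste0(sp[u], "_", seq_len(n_per[[sp[u]]]))
        incoming <- lapply(labs, lineage_tip)
        t0 <- 0
      } else {
        incoming <- do.call(c, pending[children[[u]]])
        t0 <- ages[u]
      }
      t1 <- if (u == root) Inf else ages[parent[u]]
      res <- coalesce_lineages(incoming, theta, t0, t1)
      pending[[u]] <- res$lineages
    }
    finish_tree(pending[[root]])
  }
  with_seed(seed, lapply(seq_len(loci), function(i) sim_one()))
}

#' Simulate a mixed species/population chronogram with known membership
#'
#' A Yule species tree sets the between-species divergences; a Kingman
#' coalescent genealogy of each species' samples is grafted at its tip. The
#' species tree is rescaled so within- and between-species branching are
#' separated: with `separation_mode = "ratio"` (default) ages are scaled so
#' that the youngest species divergence equals `separation` times the
#' deepest within-species coalescence; with `"multiplier"` ages are simply
#' multiplied by `separation` (an error results if a within-species
#' genealogy would then predate its species' divergence). `separation = 0`
#' collapses the model to a single panmictic coalescent (the GMYC null).
#'
#' @param K Number of species.
#' @param n_per Samples per species (scalar or vector of length `K`).
#' @param theta Within-species coalescent parameter.
#' @param lambda Yule speciation rate.
#' @param separation Separation ratio or multiplier (see above).
#' @param separation_mode `"ratio"` or `"multiplier"`.
#' @param seed Optional integer seed.
#' @return A list with `tree` (ultrametric `phylo` over all samples) and
#'   `scenario` (tibble `sample`, `species`: the generating truth).
#' @export
simulate_gmyc_tree <- function(K = 12, n_per = 10, theta = 1, lambda = 1,
                               separation = 10,
                               separation_mode = c("ratio", "multiplier"),
                               seed = NULL) {
  separation_mode <- match.arg(separation_mode)
  if (length(n_per) == 1) n_per <- rep(n_per, K)
  if (length(n_per) != K) {
    stop_coaldelim("n_per must have length 1 or K", "coaldelim_validation_error")
  }
  if (sum(n_per) < 4) {
    stop_coaldelim("need at least 4 samples in total", "coaldelim_validation_error")
  }
  sp_labels <- paste0("sp", seq_len(K))

  with_seed(seed, {
    if (K == 1 || separation == 0) {
      labs <- unlist(lapply(seq_len(K), function(i) {
        paste0(sp_labels[i], "_", seq_len(n_per[i]))
      }))
      res <- coalesce_lineages(lapply(labs, lineage_tip), theta, 0, Inf)
      tree <- finish_tree(res$lineages)
      scenario <- tibble(sample = labs,
                         species = sub("_[0-9]+$", "", labs))
      return(list(tree = tree, scenario = scenario))
    }

    sp_tree <- simulate_yule_tree(K, lambda = lambda, labels = sp_labels)
    subtrees <- lapply(seq_len(K), function(i) {
      labs <- paste0(sp_labels[i], "_", seq_len(n_per[i]))
      if (length(labs) == 1) return(lineage_tip(labs))
      res <- coalesce_lineages(lapply(labs, lineage_tip), theta, 0, Inf)
      res$lineages[[1]]
    })
    tmrca <- vapply(subtrees, `[[`, numeric(1), "age")

    sp_ages <- node_ages(sp_tree)
    ntipK <- ape::Ntip(sp_tree)
    div_ages <- sp_ages[(ntipK + 1L):(ntipK + sp_tree$Nnode)]
    scale_by <- 1
    if (separation_mode == "ratio") {
      scale_by <- separation * max(tmrca, 1e-12) / min(div_ages)
    } else {
      scale_by <- separation
    }
    sp_tree$edge.length <- sp_tree$edge.length * scale_by
    sp_ages <- sp_ages * scale_by

    # attachment age of each species = its parent divergence
    parent <- integer(ntipK + sp_tree$Nnode)
    for (i in seq_len(nrow(sp_tree$edge))) {
      parent[sp_tree$edge[i, 2L]] <- sp_tree$edge[i, 1L]
    }
    attach_age <- sp_ages[parent[seq_len(ntipK)]]
    idx <- match(sp_tree$tip.label, sp_labels)
    if (any(tmrca[idx] >= attach_age)) {
      stop_coaldelim(
        "within-species genealogy predates the species divergence; increase separation",
        "coaldelim_validation_error")
    }

    # graft: render the species tree with each species tip replaced by its
    # population subtree (tip branch shortened by the subtree's root age)
    children <- vector("list", ntipK + sp_tree$Nnode)
    for (i in seq_len(nrow(sp_tree$edge))) {
      children[[sp_tree$edge[i, 1L]]] <-
        c(children[[sp_tree$edge[i, 1L]]], sp_tree$edge[i, 2L])
    }
    render <- function(v) {
      if (v <= ntipK) {
        st <- subtrees[[match(sp_tree$tip.label[v], sp_labels)]]
        return(list(nwk = st$nwk, age = st$age))
      }
      kids <- lapply(children[[v]], render)
      # branch length from child subtree root up to this divergence
      parts <- vapply(seq_along(kids), function(i) {
        paste0(kids[[i]]$nwk, ":", fmt_bl(sp_ages[v] - kids[[i]]$age))
      }, character(1))
      list(nwk = paste0("(", paste(parts, collapse = ","), ")"),
           age = sp_ages[v])
    }
    res <- render(ntipK + 1L)
    tree <- ape::read.tree(text = paste0(res$nwk, ";"))
    labs <- tree$tip.label
    scenario <- tibble(sample = labs, species = sub("_[0-9]+$", "", labs))
    list(tree = tree, scenario = scenario)
  })
}

#' Simulate clade-associated discrete characters
#'
#' Each character is, independently with probability `association`, a
#' deterministic function of the species label (perfect clade association);
#' otherwise its states are iid uniform across specimens.
#'
#' @param scenario Data frame (`sample`, `species`).
#' @param count Number of characters.
#' @param association Probability in \[0, 1\] that a character is perfectly
#'   clade-associated.
#' @param n_states Number of states per character (default 3).
#' @param seed Optional integer seed.
#' @return A tibble: `specimen` plus `char1..charN` columns (integer-coded
#'   states starting at 0).
#' @export
simulate_characters <- function(scenario, count, association, n_states = 3,
                                seed = NULL) {
  if (association < 0 || association > 1) {
    stop_coaldelim("association must be in [0, 1]", "coaldelim_validation_error")
  }
  scenario <- validate_scenario(scenario)
  sp_index <- as.integer(factor(scenario$species))
  n <- nrow(scenario)
  with_seed(seed, {
    cols <- lapply(seq_len(count), function(ch) {
      if (stats::runif(1) < association) {
        (sp_index - 1L) %% n_states
      } else {
        sample.int(n_states, n, replace = TRUE) - 1L
      }
    })
    names(cols) <- paste0("char", seq_len(count))
    dplyr::bind_cols(tibble(specimen = scenario$sample), as_tibble(cols))
  })
}

#' Simulate an alignment under Jukes-Cantor evolution
#'
#' A uniform-random root sequence evolves along the tree: per site and
#' branch the number of substitution events is Poisson with mean
#' `rate * branch length`, each event replacing the state by one of the
#' other three bases uniformly. Zero-length cherries therefore yield
#' identical sequences, and `rate = 0` copies the root sequence everywhere.
#'
#' @param tree A `phylo` with branch lengths.
#' @param length Number of sites (>= 1).
#' @param rate Per-site substitution rate (>= 0).
#' @param seed Optional integer seed.
#' @return Named character vector of sequences (one per tip), compatible
#'   with [collapse_identical_haplotypes()].
#' @export
simulate_alignment <- function(tree, length, rate, seed = NULL) {
  if (length < 1) stop_coaldelim("length must be >= 1",
                                 "coaldelim_validation_error")
  if (rate < 0) stop_coaldelim("rate must be >= 0",
                               "coaldelim_validation_error")
  bases <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  children <- vector("list", nn)
  blen <- numeric(nn)
  for (i in seq_len(nrow(tree$edge))) {
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
    blen[tree$edge[i, 2L]] <- tree$edge.length[i]
  }
  with_seed(seed, {
    seqs <- vector("list", nn)
    root <- ntip + 1L
    seqs[[root]] <- sample(4L, length, replace = TRUE)
    queue <- root
    while (length(queue) > 0) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ch in children[[v]]) {
        s <- seqs[[v]]
        nev <- stats::rpois(length, rate * blen[ch])
        for (site in which(nev > 0)) {
          for (e in seq_len(nev[site])) {
            s[site] <- sample(setdiff(1:4, s[site]), 1)
          }
        }
        seqs[[ch]] <- s
        queue <- c(queue, ch)
      }
    }
    out <- vapply(seq_len(ntip), function(t) {
      paste(bases[seqs[[t]]], collapse = "")
    }, character(1))
    names(out) <- tree$tip.label
    out
  })
}
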