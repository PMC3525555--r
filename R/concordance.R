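#' Test a set of tips for monophyly in a gene tree
#'
#' Monophyly is judged on the *shared* tips: members of `tips` absent from
#' the tree are ignored, and if fewer than two members remain the question
#' is not assessable. Unrooted trees are rooted at the declared outgroup tip
#' first (midpoint rooting when no outgroup is given).
#'
#' @param tree A `phylo` gene tree (rooted or unrooted).
#' @param tips Character vector of tip labels forming the putative clade.
#' @param outgroup Optional tip label to root an unrooted tree.
#' @return `TRUE`/`FALSE`, or `NA` when fewer than 2 of `tips` occur in the
#'   tree.
#' @export
is_monophyletic <- function(tree, tips, outgroup = NULL) {
  tree <- root_for_scoring(tree, outgroup)
  shared <- intersect(tips, tree$tip.label)
  if (length(shared) < 2) return(NA)
  if (length(shared) == ape::Ntip(tree)) return(TRUE)
  mrca <- ape::getMRCA(tree, shared)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  setequal(clade_tips, shared)
}

root_for_scoring <- function(tree, outgroup = NULL) {
  if (!inherits(tree, "phylo")) {
    stop_coaldelim("not a phylo object", "coaldelim_validation_error")
  }
  if (ape::is.rooted(tree)) return(tree)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop_coaldelim(paste0("outgroup tip '", outgroup, "' absent from tree"),
                     "coaldelim_validation_error")
    }
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE))
  }
  phangorn::midpoint(tree)
}

# Bootstrap support of the clade containing exactly `shared` tips, read
# from the node label of their MRCA. NA when labels are absent/blank.
clade_support <- function(tree, shared) {
  if (is.null(tree$node.label)) return(NA_real_)
  mrca <- ape::getMRCA(tree, shared)
  lab <- tree$node.label[mrca - ape::Ntip(tree)]
  if (is.na(lab) || !nzchar(lab)) return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

#' Genealogical concordance table
#'
#' Scores each putative species of a delimitation scenario in each
#' single-locus gene tree (and, optionally, a combined-data tree): is the
#' species recovered as a monophyletic group on the tips shared with that
#' tree, and if so with what bootstrap support? Cells are
#' `"supported"` (monophyletic with support >= `support_threshold`),
#' `"present"` (monophyletic but unsupported or without a support value),
#' `"absent"` (not monophyletic), or `"n/a"` (fewer than 2 shared tips).
#'
#' @param trees Named list of `phylo` gene trees (names become columns).
#' @param scenario Data frame with columns `sample` and `species`.
#' @param combined Optional combined-data `phylo`, scored as an extra
#'   column named `"combined"` (first).
#' @param support_threshold Bootstrap percentage at/above which a clade
#'   counts as supported (default 70).
#' @param outgroup Optional outgroup tip label used to root unrooted trees.
#' @return A tibble in long form: `species`, `tree`, `status`, `support`,
#'   `n_shared`; plus a per-species `n_present` summary column (number of
#'   single-locus trees where the species is present or supported).
#' @export
concordance_table <- function(trees, scenario, combined = NULL,
                              support_threshold = 70, outgroup = NULL) {
  if (support_threshold <= 0 || support_threshold > 100) {
    stop_coaldelim("support_threshold must be in (0, 100]",
                   "coaldelim_validation_error")
  }
  scenario <- validate_scenario(scenario)
  if (is.null(names(trees))) {
    names(trees) <- paste0("locus", seq_along(trees))
  }
  all_trees <- trees
  if (!is.null(combined)) {
    all_trees <- c(list(combined = combined), trees)
  }
  all_trees <- lapply(all_trees, root_for_scoring, outgroup = outgroup)

  species <- split(scenario$sample, scenario$species)
  rows <- list()
  for (sp in names(species)) {
    members <- species[[sp]]
    if (length(members) < 2) {
      rows[[length(rows) + 1L]] <- tibble(
        species = sp, tree = names(all_trees), status = "n/a",
        support = NA_real_, n_shared = NA_integer_)
      next
    }
    for (tn in names(all_trees)) {
      tr <- all_trees[[tn]]
      shared <- intersect(members, tr$tip.label)
      if (length(shared) < 2) {
        st <- "n/a"; sup <- NA_real_
      } else {
        mono <- is_monophyletic(tr, shared)
        if (!isTRUE(mono)) {
          st <- "absent"; sup <- NA_real_
        } else {
          sup <- clade_support(tr, shared)
          st <- if (!is.na(sup) && sup >= support_threshold) "supported" else "present"
        }
      }
      rows[[length(rows) + 1L]] <- tibble(species = sp, tree = tn,
                                          status = st, support = sup,
                                          n_shared = length(shared))
    }
  }
  out <- dplyr::bind_rows(rows)
  locus_names <- names(trees)
  summary <- out %>%
    dplyr::filter(.data$tree %in% locus_names) %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(n_present = sum(.data$status %in% c("present", "supported")),
                     .groups = "drop")
  out <- dplyr::left_join(out, summary, by = "species")
  class(out) <- c("concordance_table", class(out))
  out
}

validate_scenario <- function(scenario) {
  scenario <- as_tibble(scenario)
  if (!all(c("sample", "species") %in% names(scenario))) {
    stop_coaldelim("scenario needs columns 'sample' and 'species'",
                   "coaldelim_validation_error")
  }
  if (anyDuplicated(scenario$sample)) {
    stop_coaldelim("scenario maps a sample to more than one species",
                   "coaldelim_validation_error")
  }
  scenario$sample <- as.character(scenario$sample)
  scenario$species <- as.character(scenario$species)
  scenario
}

#' Pivot a concordance table to the wide, publication-style layout
#'
#' One row per species, one column per tree; supported clades show their
#' support value, present-but-unsupported clades `"+"`, absent clades
#' `"-"`, unassessable cells `"n/a"`.
#'
#' @param x A `concordance_table`.
#' @return A wide tibble.
#' @export
concordance_wide <- function(x) {
  x %>%
    dplyr::mutate(cell = dplyr::case_when(
      .data$status == "supported" ~ format(.data$support, trim = TRUE),
      .data$status == "present" ~ "+",
      .data$status == "absent" ~ "-",
      TRUE ~ "n/a")) %>%
    dplyr::select("species", "tree", "cell", "n_present") %>%
    tidyr::pivot_wider(names_from = "tree", values_from = "cell")
}
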