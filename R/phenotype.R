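#' Fitch parsimony step count for one character
#'
#' Minimum number of unordered state changes needed to explain a discrete
#' character on a reference tree (Fitch's bottom-up pass: intersect child
#' state sets where possible, otherwise take the union and count a step).
#' Tips with missing states are pruned for the character; an invariant
#' character scores 0.
#'
#' @param tree A `phylo` (need not be ultrametric; polytomies allowed —
#'   each internal node combines its children pairwise, which for the
#'   Fitch count on unordered states equals the multifurcating pass).
#' @param states Named vector/factor of states, names = tip labels; `NA`
#'   means missing.
#' @return Integer step count.
#' @export
fitch_steps <- function(tree, states) {
  if (is.null(names(states))) {
    stop_coaldelim("states must be named by tip label",
                   "coaldelim_validation_error")
  }
  states <- states[!is.na(states)]
  scored <- intersect(tree$tip.label, names(states))
  if (length(scored) < 2) {
    stop_coaldelim("fewer than 2 scored tips", "coaldelim_validation_error")
  }
  drop <- setdiff(tree$tip.label, scored)
  if (length(drop) > 0) tree <- prune_tips(tree, drop)

  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  }
  level <- integer(nn)
  queue <- ntip + 1L
  while (length(queue) > 0) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in children[[v]]) { level[ch] <- level[v] + 1L; queue <- c(queue, ch) }
  }
  state_levels <- sort(unique(as.character(states)))
  sets <- vector("list", nn)
  for (t in seq_len(ntip)) {
    sets[[t]] <- as.character(states[[tree$tip.label[t]]])
  }
  steps <- 0L
  internals <- (ntip + 1L):nn
  for (v in internals[order(level[internals], decreasing = TRUE)]) {
    kids <- children[[v]]
    cur <- sets[[kids[1L]]]
    for (k in kids[-1L]) {
      inter <- intersect(cur, sets[[k]])
      if (length(inter) > 0) {
        cur <- inter
      } else {
        cur <- union(cur, sets[[k]])
        steps <- steps + 1L
      }
    }
    sets[[v]] <- cur
  }
  steps
}

#' Homoplasy indices (CI, RI) for a character matrix
#'
#' Per character: `m` = minimum conceivable steps (observed states − 1),
#' `s` = Fitch steps on the reference tree, `M` = maximum conceivable steps
#' (scored tips − frequency of the modal state), consistency index
#' `CI = m/s` and retention index `RI = (M−s)/(M−m)`. Invariant characters
#' (`m = 0`) and characters with `M = m` (e.g. binary autapomorphies) have
#' undefined CI resp. RI, reported as `NA`.
#'
#' @param tree Reference `phylo`.
#' @param matrix Data frame: first column `specimen` (or row names), the
#'   rest one column per character; missing states as `NA` (or `"?"`).
#' @return A tibble (class `homoplasy_report`): `character`, `m`, `s`, `M`,
#'   `CI`, `RI`, `n_scored`, `n_states`.
#' @export
homoplasy_indices <- function(tree, matrix) {
  matrix <- normalize_character_matrix(matrix)
  chars <- setdiff(names(matrix), "specimen")
  rows <- lapply(chars, function(ch) {
    states <- matrix[[ch]]
    names(states) <- matrix$specimen
    states <- states[!is.na(states)]
    states <- states[names(states) %in% tree$tip.label]
    n_scored <- length(states)
    tabs <- table(states)
    n_states <- length(tabs)
    m <- n_states - 1L
    M <- n_scored - max(tabs)
    s <- if (n_states < 2 || n_scored < 2) 0L else fitch_steps(tree, states)
    CI <- if (s > 0) m / s else NA_real_
    RI <- if (M > m) (M - s) / (M - m) else NA_real_
    tibble(character = ch, m = m, s = as.integer(s), M = as.integer(M),
           CI = CI, RI = RI, n_scored = n_scored, n_states = n_states)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("homoplasy_report", class(out))
  out
}

normalize_character_matrix <- function(matrix) {
  matrix <- as_tibble(matrix)
  if (!"specimen" %in% names(matrix)) {
    stop_coaldelim("character matrix needs a 'specimen' column",
                   "coaldelim_validation_error")
  }
  matrix$specimen <- as.character(matrix$specimen)
  if (anyDuplicated(matrix$specimen)) {
    stop_coaldelim("duplicate specimens in character matrix",
                   "coaldelim_validation_error")
  }
  for (ch in setdiff(names(matrix), "specimen")) {
    v <- as.character(matrix[[ch]])
    v[v %in% c("?", "-", "")] <- NA_character_
    matrix[[ch]] <- v
  }
  matrix
}

#' Clade-by-state contingency test for one character
#'
#' Pearson chi-square test of association between species (clades of a
#' delimitation scenario) and character states. Specimens with missing
#' states, excluded species, and empty rows/columns are dropped before
#' testing. A warning attribute flags expected counts below 5.
#'
#' @param scenario Data frame (`sample`, `species`).
#' @param states Named vector of states (names = sample ids), `NA` missing.
#' @param exclude Character vector of species to exclude (e.g. a
#'   morphologically deviating species).
#' @return A list of class `contingency_result`: `table` (observed counts),
#'   `statistic`, `df`, `p.value`, `low_expected` (logical).
#' @export
contingency_test <- function(scenario, states, exclude = character(0)) {
  scenario <- validate_scenario(scenario)
  scenario <- scenario[!scenario$species %in% exclude, , drop = FALSE]
  st <- states[match(scenario$sample, names(states))]
  keep <- !is.na(st)
  sp <- scenario$species[keep]
  st <- as.character(st[keep])
  if (length(unique(sp)) < 2 || length(unique(st)) < 2) {
    stop_coaldelim("contingency table is degenerate (needs >= 2 clades and >= 2 states)",
                   "coaldelim_degenerate_error")
  }
  tab <- table(clade = sp, state = st)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value,
                 low_expected = any(ct$expected < 5)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Chi-square = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p.value,
              if (x$low_expected) "  (some expected counts < 5)" else ""))
  invisible(x)
}

#' Phenotype-association report across a character matrix
#'
#' Combines [homoplasy_indices()] on the reference tree with
#' [contingency_test()] per character against a delimitation scenario —
#' the per-character homoplasy/association summary table.
#'
#' @param tree Reference `phylo`.
#' @param matrix Character matrix (see [homoplasy_indices()]).
#' @param scenario Delimitation scenario (`sample`, `species`).
#' @param exclude_species Species excluded from the contingency tests.
#' @param exclude_characters Characters excluded from the contingency tests
#'   (still scored for CI/RI), e.g. under-sampled organs.
#' @return A tibble: homoplasy columns plus `chisq`, `df`, `p.value`,
#'   `low_expected` (NA where a character was excluded or degenerate).
#' @export
phenotype_report <- function(tree, matrix, scenario,
                             exclude_species = character(0),
                             exclude_characters = character(0)) {
  matrix <- normalize_character_matrix(matrix)
  hom <- homoplasy_indices(tree, matrix)
  tests <- lapply(hom$character, function(ch) {
    if (ch %in% exclude_characters) {
      return(tibble(chisq = NA_real_, df = NA_integer_,
                    p.value = NA_real_, low_expected = NA))
    }
    states <- matrix[[ch]]
    names(states) <- matrix$specimen
    res <- tryCatch(contingency_test(scenario, states,
                                     exclude = exclude_species),
                    coaldelim_degenerate_error = function(e) NULL)
    if (is.null(res)) {
      return(tibble(chisq = NA_real_, df = NA_integer_,
                    p.value = NA_real_, low_expected = NA))
    }
    tibble(chisq = res$statistic, df = as.integer(res$df),
           p.value = res$p.value, low_expected = res$low_expected)
  })
  dplyr::bind_cols(hom, dplyr::bind_rows(tests))
}
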