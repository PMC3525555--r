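#' Read a tree from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates tip labels and,
#' optionally, interprets internal node labels as bootstrap support values
#' in \[0, 100\].
#'
#' @param path Path to a newick file (single tree).
#' @param supports If `TRUE`, internal node labels are checked to be numeric
#'   support values in \[0, 100\] (blank labels allowed) and kept on the
#'   returned tree's `node.label`.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path, supports = FALSE) {
  if (!file.exists(path)) {
    stop_coaldelim(paste0("file not found: ", path), "coaldelim_io_error")
  }
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) {
      stop_coaldelim(paste0("malformed newick in '", path, "': ",
                            conditionMessage(e)),
                     "coaldelim_parse_error")
    }
  )
  if (is.null(tree)) {
    stop_coaldelim(paste0("malformed newick in '", path,
                          "': no tree could be parsed"),
                   "coaldelim_parse_error")
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  check_tip_labels(tree)
  if (supports) check_supports(tree)
  tree
}

#' Write a tree to a newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @param digits Number of significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

check_tip_labels <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_coaldelim(paste0("duplicate tip labels: ",
                          paste(dup, collapse = ", ")),
                   "coaldelim_validation_error")
  }
  invisible(tree)
}

check_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(invisible(tree))
  lab <- lab[!is.na(lab) & nzchar(lab)]
  val <- suppressWarnings(as.numeric(lab))
  if (anyNA(val) || any(val < 0 | val > 100)) {
    stop_coaldelim("internal node labels are not support values in [0, 100]",
                   "coaldelim_validation_error")
  }
  invisible(tree)
}

#' Node ages of a rooted tree
#'
#' Ages are measured back from the tips: age 0 at the tips (for an
#' ultrametric tree), increasing toward the root. For non-ultrametric trees
#' the age of a node is the maximum root-to-tip depth minus the node's depth.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, indexed like ape's node
#'   numbering (tips first).
#' @export
node_ages <- function(tree) {
  assert_rooted(tree)
  if (is.null(tree$edge.length)) {
    stop_coaldelim("tree has no branch lengths", "coaldelim_validation_error")
  }
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

assert_rooted <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop_coaldelim("not a phylo object", "coaldelim_validation_error")
  }
  if (!ape::is.rooted(tree)) {
    stop_coaldelim("tree must be rooted", "coaldelim_validation_error")
  }
  invisible(tree)
}

#' Validate an ultrametric chronogram
#'
#' Checks that a rooted tree is ultrametric: all root-to-tip path lengths
#' equal within a relative tolerance. Trees that fail are rejected, not
#' rescaled. Optionally also requires the tree to be fully bifurcating.
#'
#' @param tree A rooted `phylo` object.
#' @param tol Relative tolerance on root-to-tip path length spread
#'   (default `1e-6`).
#' @param binary Require every internal node to have exactly two children.
#' @return `tree`, invisibly, if validation passes.
#' @export
validate_chronogram <- function(tree, tol = 1e-6, binary = FALSE) {
  assert_rooted(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  span <- max(depth) - min(depth)
  scale <- max(depth, 1e-300)
  if (span > tol * scale) {
    stop_coaldelim(
      sprintf("tree is not ultrametric: root-to-tip paths span [%.6g, %.6g] (relative spread %.3g > tol %.3g)",
              min(depth), max(depth), span / scale, tol),
      "coaldelim_validation_error")
  }
  if (binary && !ape::is.binary(tree)) {
    stop_coaldelim("tree contains polytomies; resolve them first",
                   "coaldelim_validation_error")
  }
  invisible(tree)
}

is_ultrametric_tree <- function(tree, tol = 1e-6) {
  ok <- TRUE
  tryCatch(validate_chronogram(tree, tol = tol),
           coaldelim_validation_error = function(e) ok <<- FALSE)
  ok
}
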