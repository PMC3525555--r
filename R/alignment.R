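#' Read and concatenate per-locus FASTA alignments
#'
#' Each file holds one locus; within a locus all sequences must be the same
#' length. Samples missing from a locus are padded with `?` for that locus,
#' and partition boundaries are recorded so downstream steps know where each
#' locus sits in the concatenated matrix.
#'
#' @param paths Character vector of FASTA file paths; names are used as
#'   locus names (defaulting to file base names).
#' @return A named character vector of concatenated sequences (one per
#'   sample, in first-seen order) with attribute `partitions`, a named
#'   integer vector of locus widths.
#' @export
read_fasta_alignment <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  loci <- lapply(paths, function(p) {
    x <- ape::read.FASTA(p)
    if (length(x) == 0) {
      stop_coaldelim(paste0("no sequences in ", p), "coaldelim_io_error")
    }
    seqs <- toupper(vapply(as.character(x), paste, character(1), collapse = ""))
    len <- unique(nchar(seqs))
    if (length(len) != 1) {
      stop_coaldelim(paste0("unequal sequence lengths in ", p),
                     "coaldelim_validation_error")
    }
    if (anyDuplicated(names(seqs))) {
      stop_coaldelim(paste0("duplicate sample ids in ", p),
                     "coaldelim_validation_error")
    }
    seqs
  })
  samples <- unique(unlist(lapply(loci, names)))
  widths <- vapply(loci, function(s) nchar(s[[1]]), integer(1))
  concat <- vapply(samples, function(id) {
    paste(vapply(seq_along(loci), function(i) {
      if (id %in% names(loci[[i]])) loci[[i]][[id]]
      else strrep("?", widths[i])
    }, character(1)), collapse = "")
  }, character(1))
  structure(concat, partitions = widths)
}

#' Collapse identical haplotypes
#'
#' Groups sequences that are indistinguishable and keeps one representative
#' per group (the first by input order). Two sequences are considered
#' identical when they agree at every *mutually unambiguous* column: a `?`,
#' `N` or `-` in either sequence makes that column non-discriminating for
#' the pair. Grouping is greedy in input order: each sequence joins the
#' first already-kept representative it matches.
#'
#' @param alignment Named character vector of equal-length sequences (e.g.
#'   from [read_fasta_alignment()] or [simulate_alignment()]).
#' @return A list with `alignment` (the kept representatives, attributes
#'   preserved) and `groups`, a tibble with columns `haplotype` (kept id)
#'   and `sample` (every id assigned to it, representatives included).
#' @export
collapse_identical_haplotypes <- function(alignment) {
  seqs <- unclass(alignment)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_coaldelim("alignment must have unique sample names",
                   "coaldelim_validation_error")
  }
  if (length(unique(nchar(seqs))) > 1) {
    stop_coaldelim("sequences have unequal lengths",
                   "coaldelim_validation_error")
  }
  n <- length(seqs)
  mat <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = n, byrow = TRUE)
  amb <- mat == "?" | mat == "N" | mat == "-"

  same_pair <- function(i, j) {
    all(mat[i, ] == mat[j, ] | amb[i, ] | amb[j, ])
  }
  reps <- integer(0)
  assign_to <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in reps) {
      if (same_pair(i, r)) { hit <- r; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      assign_to[i] <- i
    } else {
      assign_to[i] <- hit
    }
  }
  kept <- seqs[reps]
  attributes(kept) <- c(attributes(kept),
                        attributes(alignment)[setdiff(names(attributes(alignment)),
                                                      c("names", "class"))])
  names(kept) <- names(seqs)[reps]
  groups <- tibble(haplotype = names(seqs)[assign_to], sample = names(seqs))
  list(alignment = kept, groups = groups)
}
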