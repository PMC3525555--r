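test_that("newick reading validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(unname(node_ages(tr)[4]), 2)  # root age

  # support labels kept and validated
  writeLines("((A:1,B:1)95:1,C:2);", f)
  trs <- read_newick(f, supports = TRUE)
  expect_equal(trs$node.label[ape::getMRCA(trs, c("A", "B")) - 3], "95")
  writeLines("((A:1,B:1)xx:1,C:2);", f)
  expect_error(read_newick(f, supports = TRUE), class = "coaldelim_validation_error")

  # duplicate tips and malformed text are rejected
  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), class = "coaldelim_validation_error")
  writeLines("((A:1,B:1:1,C:2);", f)
  expect_error(read_newick(f), class = "coaldelim_parse_error")

  # write o read is the identity on topology and lengths
  tr2 <- simulate_coalescent_tree(20, theta = 1, seed = 11)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr2, out)
  back <- read_newick(out)
  expect_true(ape::all.equal.phylo(tr2, back, use.edge.length = FALSE))
  d1 <- ape::cophenetic.phylo(tr2); d2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-9)
})

test_that("ultrametricity validation rejects unequal root-to-tip paths", {
  bad <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(validate_chronogram(bad), class = "coaldelim_validation_error")
  good <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_silent(validate_chronogram(good))
})

test_that("polytomy resolution is deterministic and distance-preserving", {
  # basal trifurcation: sorted child labels give ((A,B),C) with a zero branch
  tp <- ape::read.tree(text = "(B:1,C:1,A:1);")
  r <- resolve_polytomies(tp)
  expect_true(max(tabulate(r$edge[, 1])) == 2)
  expect_true(is_monophyletic(r, c("A", "B")))
  expect_equal(sort(r$edge.length), c(0, 1, 1, 1))

  # already binary -> identical
  tb <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(ape::write.tree(resolve_polytomies(tb)), ape::write.tree(tb))

  # 5-way polytomy: a binary tree on n tips has n-1 internal nodes
  t5 <- ape::read.tree(text = "((A:1,B:1,C:1,D:1,E:1):1,F:2);")
  r5 <- resolve_polytomies(t5)
  expect_equal(r5$Nnode, ape::Ntip(r5) - 1L)
  d_before <- ape::cophenetic.phylo(t5)
  d_after <- ape::cophenetic.phylo(r5)[rownames(d_before), colnames(d_before)]
  expect_equal(d_before, d_after, tolerance = 1e-12)

  # seed-controlled shuffle is reproducible
  s1 <- resolve_polytomies(t5, seed = 1)
  s2 <- resolve_polytomies(t5, seed = 1)
  expect_equal(ape::write.tree(s1), ape::write.tree(s2))
})

test_that("tip pruning keeps induced distances and validates labels", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pruned <- prune_tips(tr, "C")
  expect_equal(sort(pruned$tip.label), c("A", "B"))
  expect_equal(unname(max(node_ages(pruned))), 1)

  expect_equal(ape::write.tree(prune_tips(tr, character(0))),
               ape::write.tree(tr))
  expect_error(prune_tips(tr, "Z"), class = "coaldelim_validation_error")
  expect_error(prune_tips(tr, c("A", "B")), class = "coaldelim_validation_error")

  big <- simulate_coalescent_tree(20, theta = 1, seed = 5)
  drop <- big$tip.label[c(2, 5, 9, 13, 20)]
  sub <- prune_tips(big, drop)
  keep <- setdiff(big$tip.label, drop)
  d_before <- ape::cophenetic.phylo(big)[keep, keep]
  d_after <- ape::cophenetic.phylo(sub)[keep, keep]
  expect_equal(d_before, d_after, tolerance = 1e-9)
})

test_that("LTT curve steps through every branching event", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  curve <- ltt_curve(tr)
  expect_equal(curve$time, c(-2, -1))
  expect_equal(curve$lineages, c(2L, 3L))

  t4 <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  c4 <- ltt_curve(t4)
  expect_equal(c4$lineages, c(2L, 3L, 4L))
  expect_equal(c4$time, c(-3, -1, -1))

  ty <- simulate_yule_tree(50, lambda = 1, seed = 9)
  cy <- ltt_curve(ty)
  expect_equal(nrow(cy), 49)            # tips - 1 steps
  expect_equal(max(cy$lineages), 50L)   # final count = tip number
  expect_true(all(diff(cy$lineages) == 1L))

  expect_error(ltt_curve(ape::read.tree(text = "((A:1,B:2):1,C:2);")),
               class = "coaldelim_validation_error")
})

test_that("haplotype collapsing groups under the mutual-ambiguity rule", {
  aln <- c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA")
  res <- collapse_identical_haplotypes(aln)
  expect_equal(names(res$alignment), c("s1", "s3"))
  expect_equal(res$groups$haplotype[res$groups$sample == "s2"], "s1")

  # all distinct -> identity
  aln2 <- c(a = "AAAA", b = "CCCC", c = "GGGG")
  expect_equal(names(collapse_identical_haplotypes(aln2)$alignment),
               c("a", "b", "c"))

  # ambiguity codes make a column non-discriminating for the pair
  aln3 <- c(x = "AC?T", y = "ACGT", z = "AAGT")
  res3 <- collapse_identical_haplotypes(aln3)
  expect_equal(names(res3$alignment), c("x", "z"))  # y joins x (first match)
  expect_equal(res3$groups$haplotype, c("x", "x", "z"))

  expect_error(collapse_identical_haplotypes(c(a = "AC", b = "ACG")),
               class = "coaldelim_validation_error")
})

test_that("FASTA loci concatenate with partitions and missing-locus padding", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s2", "ACGA"), f1)
  writeLines(c(">s1", "TTT"), f2)
  aln <- read_fasta_alignment(c(locA = f1, locB = f2))
  expect_equal(attr(aln, "partitions"), c(locA = 4L, locB = 3L))
  expect_equal(unname(aln["s1"]), "ACGTTTT")
  expect_equal(unname(aln["s2"]), "ACGA???")
})
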