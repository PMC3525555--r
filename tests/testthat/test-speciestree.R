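test_that("coalescence times equal MRCA ages and half the path length", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(coalescence_time(tr, "A", "B"), 1)
  expect_equal(coalescence_time(tr, "A", "C"), 2)
  expect_error(coalescence_time(tr, "A", "Z"),
               class = "coaldelim_validation_error")

  rt <- simulate_coalescent_tree(12, theta = 1, seed = 4)
  d <- ape::cophenetic.phylo(rt)
  for (pair in list(c(1, 5), c(2, 9), c(3, 12))) {
    a <- rt$tip.label[pair[1]]; b <- rt$tip.label[pair[2]]
    expect_equal(coalescence_time(rt, a, b), d[a, b] / 2, tolerance = 1e-9)
  }
})

test_that("maximum-tree estimation single-links minimum cross coalescences", {
  # two species, one locus: cherry at the minimum cross coalescence
  g <- ape::read.tree(text = "((a1:0.8,b1:0.8):1.2,(a2:0.3,a3:0.3):1.7);")
  scen <- data.frame(sample = c("a1", "a2", "a3", "b1"),
                     species = c("A", "A", "A", "B"))
  st <- maximum_tree(list(g), scen)
  expect_equal(ape::Ntip(st), 2)
  expect_equal(unname(max(node_ages(st))), 0.8, tolerance = 1e-9)

  # D = {AB:1, AC:3, BC:3} -> ((A,B):1, C) with root age 3
  g3 <- ape::read.tree(text = "((a1:1,b1:1):2,c1:3);")
  scen3 <- data.frame(sample = c("a1", "b1", "c1"), species = c("A", "B", "C"))
  st3 <- maximum_tree(list(g3), scen3)
  expect_true(is_monophyletic(st3, c("A", "B")))
  ages <- sort(node_ages(st3)[(3 + 1):(3 + st3$Nnode)])
  expect_equal(unname(ages), c(1, 3), tolerance = 1e-9)

  # deep-split simulation: topology matches the generating species tree
  spt <- simulate_yule_tree(5, lambda = 1, seed = 12)
  spt$edge.length <- spt$edge.length * 500
  gts <- simulate_msc_gene_trees(spt, n_per = 3, theta = 1, loci = 4, seed = 13)
  scen5 <- tibble::tibble(sample = gts[[1]]$tip.label,
                          species = sub("_[0-9]+$", "", gts[[1]]$tip.label))
  est <- maximum_tree(gts, scen5)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(est), ape::unroot(spt))), 0)

  # a pair never co-sampled is an error naming the pair
  g_a <- ape::read.tree(text = "(a1:1,a2:1);")
  g_b <- ape::read.tree(text = "(b1:1,b2:1);")
  scen_ab <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                        species = c("A", "A", "B", "B"))
  expect_error(maximum_tree(list(g_a, g_b), scen_ab), "A/B")
})

test_that("MSC likelihood matches closed forms and flags incompatibility", {
  # one species, one 2-tip tree coalescing at t: logL = log 2 - 2t (theta 1)
  g <- ape::read.tree(text = "(x1:0.7,x2:0.7);")
  scen <- data.frame(sample = c("x1", "x2"), species = "s")
  expect_equal(as.numeric(msc_loglik(list(g), NULL, scen, theta = 1)),
               log(2) - 2 * 0.7, tolerance = 1e-12)

  # theta profile MLE is 2 * mean(t) for n two-tip loci, and matches a
  # numeric maximization of the closed-form likelihood
  ts <- c(0.3, 0.9, 1.4, 0.2, 0.6)
  loci <- lapply(ts, function(t) {
    ape::read.tree(text = sprintf("(x1:%g,x2:%g);", t, t))
  })
  pr <- profile_theta(loci, NULL, scen)
  expect_equal(pr$theta, 2 * mean(ts), tolerance = 1e-12)
  num <- stats::optimize(function(th) {
    sum(vapply(loci, function(g) as.numeric(msc_loglik(list(g), NULL, scen,
                                                       theta = th)),
               numeric(1)))
  }, c(0.01, 20), maximum = TRUE, tol = 1e-9)
  expect_equal(pr$theta, num$maximum, tolerance = 1e-5)
  expect_equal(pr$logL, num$objective, tolerance = 1e-8)

  # coalescence younger than the species divergence: -Inf sentinel with
  # a diagnostic, never an exception
  spt <- ape::read.tree(text = "(A:2,B:2);")
  g_bad <- ape::read.tree(text = "(a1:0.5,b1:0.5);")
  scen2 <- data.frame(sample = c("a1", "b1"), species = c("A", "B"))
  v <- msc_loglik(list(g_bad), spt, scen2)
  expect_identical(as.numeric(v), -Inf)
  expect_true(length(attr(v, "incompatible")) > 0)
})

test_that("a two-population model integrates lineage counts across the divergence", {
  # ((a1,a2):tau split at 1), gene tree: a1,a2 coalesce at 0.4 (inside A),
  # that lineage meets b1 at 1.5 (root population). theta = 1:
  #  pop A: 2 lineages over [0, 0.4]: -2*0.4 + log 2; 1 lineage to 1.0: 0
  #  pop B: 1 lineage: 0
  #  root pop: 2 lineages over [1.0, 1.5]: -2*0.5 + log 2
  spt <- ape::read.tree(text = "(A:1,B:1);")
  g <- ape::read.tree(text = "((a1:0.4,a2:0.4):1.1,b1:1.5);")
  scen <- data.frame(sample = c("a1", "a2", "b1"),
                     species = c("A", "A", "B"))
  expect_equal(as.numeric(msc_loglik(list(g), spt, scen, theta = 1)),
               2 * log(2) - 0.8 - 1.0, tolerance = 1e-9)
  # one-species lumping of the same data uses a single population:
  #  3 lineages over [0,0.4], 2 over [0.4,1.5]
  scen1 <- data.frame(sample = c("a1", "a2", "b1"), species = "all")
  expect_equal(as.numeric(msc_loglik(list(g), NULL, scen1, theta = 1)),
               2 * log(2) - 6 * 0.4 - 2 * 1.1, tolerance = 1e-9)
})

test_that("scenario comparison ranks by delta lnL with Bonferroni-corrected LRTs", {
  spt <- simulate_yule_tree(4, lambda = 1, seed = 3)
  spt$edge.length <- spt$edge.length * 100
  gts <- simulate_msc_gene_trees(spt, n_per = 3, theta = 1, loci = 3, seed = 9)
  samples <- gts[[1]]$tip.label
  truth <- tibble::tibble(sample = samples,
                          species = sub("_[0-9]+$", "", samples))
  lump <- tibble::tibble(sample = samples, species = "all")
  cmp <- compare_scenarios(gts, list("1-species" = lump, "true" = truth))
  expect_s3_class(cmp, "msc_comparison")
  expect_equal(cmp$delta_lnL[cmp$scenario == "1-species"], 0)
  expect_true(is.na(cmp$p_corrected[cmp$scenario == "1-species"]))
  expect_equal(cmp$k, c(2L, 5L))            # species + 1
  expect_gt(cmp$delta_lnL[cmp$scenario == "true"], 0)
  expect_equal(cmp$AIC, 2 * cmp$k + 2 * cmp$neg_lnL)

  # comparing a scenario with itself: delta 0, p = 1 (df = 0)
  cmp2 <- compare_scenarios(gts, list(a = truth, b = truth))
  expect_equal(cmp2$delta_lnL, c(0, 0))
  expect_equal(cmp2$p_corrected[2], 1)
})

test_that("compatible refinements never lose likelihood", {
  for (s in 1:6) {
    spt <- simulate_yule_tree(4, lambda = 1, seed = 300 + s)
    spt$edge.length <- spt$edge.length * 100
    gts <- simulate_msc_gene_trees(spt, n_per = 3, theta = 1, loci = 2,
                                   seed = 400 + s)
    samples <- gts[[1]]$tip.label
    fine <- tibble::tibble(sample = samples,
                           species = sub("_[0-9]+$", "", samples))
    # coarse scenario: merge sp1+sp2 (a clade-compatible lump)
    coarse <- dplyr::mutate(fine, species = ifelse(species %in% c("sp1", "sp2"),
                                                   "sp12", species))
    st_f <- maximum_tree(gts, fine)
    st_c <- maximum_tree(gts, coarse)
    ll_f <- as.numeric(msc_loglik(gts, st_f, fine, theta = 1))
    ll_c <- as.numeric(msc_loglik(gts, st_c, coarse, theta = 1))
    expect_true(is.finite(ll_f) && is.finite(ll_c))
    expect_gte(ll_f, ll_c - 1e-9)
  }
})

test_that("published-style scenario arithmetic reproduces delta lnL and AIC", {
  tab <- scenario_table(c("one", "nine"), c(100.5, 90.25), c(2, 10))
  expect_equal(tab$delta_lnL, c(0, 10.25))
  expect_equal(tab$AIC, c(2 * 2 + 201, 2 * 10 + 180.5))
  expect_true(is.na(tab$p_corrected[1]))
  expect_equal(tab$p_corrected[2],
               pchisq(2 * 10.25, df = 8, lower.tail = FALSE))
})
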