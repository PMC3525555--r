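test_that("Fitch step counts match trivial cases and the exhaustive oracle", {
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_steps(t4, c(A = "0", B = "0", C = "0", D = "0")), 0L)
  expect_equal(fitch_steps(t4, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  # missing tips pruned per character
  expect_equal(fitch_steps(t4, c(A = "0", B = "1", C = NA, D = NA)), 1L)
  expect_error(fitch_steps(t4, c(A = "0")), class = "coaldelim_validation_error")

  # property: equals exhaustive minimization on random <=8-tip instances
  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(4:8, 1)
      tr <- simulate_coalescent_tree(n, theta = 1,
                                     labels = paste0("t", seq_len(n)))
      states <- setNames(as.character(sample(0:2, n, replace = TRUE)),
                         tr$tip.label)
      expect_equal(fitch_steps(tr, states), oracle_fitch(tr, states),
                   info = paste("replicate", rep))
    }
  })
})

test_that("Fitch counts agree with phangorn's parsimony", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(6:12, 1)
      tr <- simulate_coalescent_tree(n, theta = 1,
                                     labels = paste0("t", seq_len(n)))
      st <- sample(0:2, n, replace = TRUE)
      states <- setNames(as.character(st), tr$tip.label)
      pd <- phangorn::phyDat(matrix(st, ncol = 1,
                                    dimnames = list(tr$tip.label, NULL)),
                             type = "USER", levels = 0:2)
      expect_equal(fitch_steps(tr, states),
                   as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
    }
  })
})

test_that("homoplasy indices follow the m/s/M definitions", {
  # hand case: 10 tips, binary 5/5 character arranged to need s = 3 steps
  nw <- "(((t1:1,t2:1):1,(t3:1,t4:1):1):2,(((t5:1,t6:1):1,(t7:1,t8:1):1):1,(t9:2,t10:2):1):1);"
  tr <- ape::read.tree(text = nw)
  cm <- tibble::tibble(
    specimen = paste0("t", 1:10),
    charA = c("1", "1", "0", "0", "1", "1", "0", "0", "1", "0"))
  expect_equal(fitch_steps(tr, setNames(cm$charA, cm$specimen)), 3L)
  rep <- homoplasy_indices(tr, cm)
  expect_equal(rep$m, 1L)
  expect_equal(rep$s, 3L)
  expect_equal(rep$M, 5L)
  expect_equal(rep$CI, 1 / 3)
  expect_equal(rep$RI, (5 - 3) / (5 - 1))

  # clean synapomorphy: s = m = 1, CI = RI = 1
  cm2 <- tibble::tibble(specimen = paste0("t", 1:10),
                        syn = c(rep("1", 4), rep("0", 6)))
  rep2 <- homoplasy_indices(tr, cm2)
  expect_equal(rep2$CI, 1)
  expect_equal(rep2$RI, 1)

  # binary autapomorphy: M = m = 1 -> RI undefined, CI = 1
  cm3 <- tibble::tibble(specimen = paste0("t", 1:10),
                        aut = c("1", rep("0", 9)))
  rep3 <- homoplasy_indices(tr, cm3)
  expect_equal(rep3$CI, 1)
  expect_true(is.na(rep3$RI))

  # invariant character: undefined CI, s = 0
  cm4 <- tibble::tibble(specimen = paste0("t", 1:10), inv = rep("0", 10))
  rep4 <- homoplasy_indices(tr, cm4)
  expect_equal(rep4$s, 0L)
  expect_true(is.na(rep4$CI))

  # collapsing two states can never increase the step count
  cm5 <- tibble::tibble(specimen = paste0("t", 1:10),
                        tern = c("0", "1", "2", "0", "1", "2", "0", "1", "2", "0"))
  s3 <- homoplasy_indices(tr, cm5)$s
  cm5b <- dplyr::mutate(cm5, tern = ifelse(tern == "2", "1", tern))
  expect_lte(homoplasy_indices(tr, cm5b)$s, s3)
})

test_that("contingency tests use the Pearson chi-square with (r-1)(c-1) df", {
  scen <- data.frame(sample = paste0("s", 1:10),
                     species = rep(c("x", "y"), each = 5))
  st <- setNames(c(rep("0", 5), rep("1", 5)), paste0("s", 1:10))
  res <- contingency_test(scen, st)
  expect_equal(res$statistic, 10, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(res$p.value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_true(res$low_expected)

  # 3 states across 9 clades: df = (9-1)(3-1) = 16
  scen9 <- data.frame(sample = paste0("s", 1:90),
                      species = rep(paste0("c", 1:9), each = 10))
  st9 <- setNames(as.character(rep(0:2, 30)), paste0("s", 1:90))
  expect_equal(contingency_test(scen9, st9)$df, 16L)

  # excluded species are removed before testing
  res_ex <- contingency_test(scen9, st9, exclude = "c1")
  expect_equal(res_ex$df, 14L)

  # degenerate tables error out
  expect_error(contingency_test(scen, setNames(rep("0", 10), paste0("s", 1:10))),
               class = "coaldelim_degenerate_error")
})

test_that("the phenotype report joins homoplasy and association per character", {
  sim <- sim_separated(K = 4, n_per = 6, seed = 55)
  chars <- simulate_characters(sim$scenario, count = 4, association = 1,
                               seed = 56)
  rep <- phenotype_report(sim$tree, chars, sim$scenario,
                          exclude_characters = "char4")
  expect_equal(nrow(rep), 4)
  # perfectly clade-associated characters: CI = 1 and p ~ 0
  scored <- rep[rep$character != "char4", ]
  expect_true(all(scored$CI == 1, na.rm = TRUE))
  expect_true(all(scored$p.value < 1e-6, na.rm = TRUE))
  expect_true(is.na(rep$p.value[rep$character == "char4"]))
})
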