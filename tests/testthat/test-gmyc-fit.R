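# Interval/entity accounting at explicit thresholds, via the internal
# cluster-root machinery the fitters use.
test_that("threshold placement partitions nodes into clusters and singletons", {
  t4 <- ape::read.tree(text = "((A:0.5,B:0.5):9.5,(C:0.4,D:0.4):9.6);")
  pre <- coaldelim:::gmyc_preprocess(t4)

  roots <- coaldelim:::cluster_roots_at_threshold(pre, 1)
  cnt <- coaldelim:::gmyc_interval_counts(pre, roots)
  expect_equal(length(roots), 2)               # two 2-tip clusters
  expect_equal(cnt$n_entities, 2)
  expect_equal(length(cnt$singletons), 0)
  expect_equal(sort(vapply(roots, function(r)
    length(pre$desc_tips[[r]]), integer(1))), c(2L, 2L))

  # threshold older than the root: one cluster holding every tip
  roots_all <- coaldelim:::cluster_roots_at_threshold(pre, 100)
  cnt_all <- coaldelim:::gmyc_interval_counts(pre, roots_all)
  expect_equal(length(roots_all), 1)
  expect_equal(cnt_all$n_entities, 1)

  # threshold at zero: every node is diversification, entities = tips
  roots_none <- coaldelim:::cluster_roots_at_threshold(pre, 0)
  cnt_none <- coaldelim:::gmyc_interval_counts(pre, roots_none)
  expect_equal(length(roots_none), 0)
  expect_equal(cnt_none$n_entities, ape::Ntip(t4))
})

test_that("single-threshold fitting recovers well-separated species", {
  sim <- sim_separated(K = 6, n_per = 5, seed = 42)
  fit <- fit_single_threshold(sim$tree)
  expect_s3_class(fit, "gmyc_fit")
  expect_equal(fit$n_entities, 6)
  expect_equal(length(fit$clusters), 6)
  # delimited clusters match the generating species exactly
  truth <- lapply(split(sim$scenario$sample, sim$scenario$species), sort)
  found <- lapply(fit$clusters, sort)
  expect_setequal(vapply(found, paste, character(1), collapse = ","),
                  vapply(truth, paste, character(1), collapse = ","))
  # confidence set contains the ML entity count
  expect_true(fit$n_entities %in% fit$conf_entities)
  expect_lt(fit$LRT$p.value, 0.01)
})

test_that("GMYC nests the null model and the fit glances tidily", {
  for (s in 1:4) {
    tr <- simulate_coalescent_tree(25, theta = 1, seed = 100 + s)
    fit <- fit_single_threshold(tr)
    expect_gte(fit$logL, fit$null$logL - 1e-6)
  }
  sim <- sim_separated(K = 5, n_per = 5, seed = 8)
  fit <- fit_single_threshold(sim$tree)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_entities, fit$n_entities)
  td <- tidy(fit)
  expect_setequal(td$tip, sim$tree$tip.label)
  expect_equal(dplyr::n_distinct(td$entity), fit$n_entities)
})

test_that("entity count and LRT statistic are invariant to time rescaling", {
  sim <- sim_separated(K = 5, n_per = 5, seed = 17)
  f1 <- fit_single_threshold(sim$tree)
  tr2 <- sim$tree
  tr2$edge.length <- tr2$edge.length * 50
  f2 <- fit_single_threshold(tr2)
  expect_equal(f2$n_entities, f1$n_entities)
  expect_equal(f2$LRT$statistic, f1$LRT$statistic, tolerance = 1e-3)
  expect_equal(f2$threshold, f1$threshold * 50, tolerance = 1e-6)
})

test_that("degenerate trees are rejected by the threshold fitters", {
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(fit_single_threshold(t3), class = "coaldelim_degenerate_error")
  # 4 tips but only 2 distinct branching ages
  t_flat <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(fit_single_threshold(t_flat),
               class = "coaldelim_degenerate_error")
})

test_that("multiple-threshold search never loses likelihood and stays put on shared depths", {
  sim <- sim_separated(K = 6, n_per = 5, seed = 42)
  single <- fit_single_threshold(sim$tree)
  multi <- fit_multiple_threshold(sim$tree, init = single)
  expect_gte(multi$logL, single$logL - 1e-9)
  # equal-theta clusters share one depth scale: no switch clears the
  # acceptance gain, so the single-threshold solution survives unchanged
  expect_equal(multi$n_entities, single$n_entities)
  expect_setequal(vapply(multi$clusters, paste, character(1), collapse = ","),
                  vapply(single$clusters, paste, character(1), collapse = ","))
})

test_that("heterogeneous cluster depths trigger local switches", {
  # two shallow and two deep clusters under deep divergences: a global
  # threshold cannot serve both depth classes, so the climb places
  # subtree-local switches (and may reclassify slow coalescences)
  mk <- function(seed) {
    withr::with_seed(seed, {
      cl <- function(nm, d, n = 5) {
        t <- simulate_coalescent_tree(n, theta = 1, labels = paste0(nm, 1:n))
        t$edge.length <- t$edge.length * d / max(node_ages(t))
        sub(";$", "", ape::write.tree(t))
      }
      txt <- sprintf("((%s:9.9,%s:9.9):10,(%s:9,%s:9):10);",
                     cl("a", 0.1), cl("b", 0.1), cl("c", 1.0), cl("d", 1.0))
      ape::read.tree(text = txt)
    })
  }
  tt <- mk(1)
  single <- fit_single_threshold(tt)
  multi <- fit_multiple_threshold(tt, init = single, tol_improve = 1e-6)
  expect_gte(multi$logL, single$logL - 1e-9)
  expect_gte(multi$n_switches, 2)
})

test_that("fit_gmyc dispatches on method and prints a summary", {
  sim <- sim_separated(K = 4, n_per = 5, seed = 31)
  fs <- fit_gmyc(sim$tree, method = "single")
  expect_equal(fs$method, "single")
  fm <- fit_gmyc(sim$tree, method = "multiple")
  expect_equal(fm$method, "multiple")
  expect_gte(fm$logL, fs$logL - 1e-9)
  expect_output(print(fs), "GMYC fit")
  sc <- scenario_from_gmyc(fs, name = "demo")
  expect_setequal(sc$sample, sim$tree$tip.label)
  expect_equal(attr(sc, "scenario_name"), "demo")
})
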