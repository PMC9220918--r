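test_that("richness null conserves richness, totals and the count multiset", {
  tree <- simulate_tree(80, seed = 1)
  d <- simulate_communities(tree, sim_params(n_samples = 6, n_taxa = 80,
                                             depth = 4000, core_size = 4,
                                             seed = 2))
  for (seed in 1:5) {
    r <- richness_null(d$table, seed = seed)
    expect_equal(rowSums(r > 0), rowSums(d$table > 0))
    expect_equal(rowSums(r), rowSums(d$table))
    for (s in rownames(r))
      expect_equal(sort(r[s, r[s, ] > 0]), sort(d$table[s, d$table[s, ] > 0]),
                   ignore_attr = TRUE)
  }
  expect_identical(richness_null(d$table, seed = 3),
                   richness_null(d$table, seed = 3))
})

test_that("a full-presence sample keeps its presence pattern, counts permuted", {
  tab <- rbind(S1 = c(5L, 9L, 2L, 7L))
  colnames(tab) <- paste0("a", 1:4)
  r <- richness_null(tab, seed = 8)
  expect_true(all(r > 0))
  expect_setequal(as.integer(r), c(5L, 9L, 2L, 7L))
})

test_that("SES classification uses the +/-2 bounds with boundaries as null", {
  expect_equal(classify_ses(-2.5), "clustered")
  expect_equal(classify_ses(0), "null")
  expect_equal(classify_ses(2.5), "overdispersed")
  expect_equal(classify_ses(c(-2, 2)), c("null", "null"))
  expect_error(classify_ses(NaN), "finite")
})

test_that("a metric-constant table yields a flagged degenerate SES, label null", {
  # every sample contains every ASV: randomization cannot change the
  # presence set, so PD is constant and null_sd = 0
  tab <- matrix(5L, 3, 6, dimnames = list(paste0("S", 1:3), paste0("a", 1:6)))
  tab[1, 1] <- 7L
  tree <- simulate_tree(6, seed = 4)
  colnames(tab) <- tree$tip.label
  expect_warning(s <- ses_metric(tab, tree, metric = "PD", n_replicates = 30,
                                 seed = 5), "degenerate")
  expect_true(all(s$degenerate))
  expect_true(all(s$label == "null"))
  expect_true(all(is.na(s$ses)))
})

test_that("SES is invariant to relabelling ASVs consistently on table and tree", {
  tree <- simulate_tree(40, seed = 6)
  d <- simulate_communities(tree, sim_params(n_samples = 4, n_taxa = 40,
                                             depth = 3000, core_size = 3,
                                             seed = 7))
  s1 <- ses_metric(d$table, tree, metric = "PSC", n_replicates = 50, seed = 9)
  relabel <- setNames(sprintf("tx%02d", seq_len(40)), tree$tip.label)
  tree2 <- tree; tree2$tip.label <- unname(relabel[tree$tip.label])
  tab2 <- d$table; colnames(tab2) <- unname(relabel[colnames(d$table)])
  s2 <- ses_metric(tab2, tree2, metric = "PSC", n_replicates = 50, seed = 9)
  expect_equal(s1$ses, s2$ses, tolerance = 1e-12)
  expect_equal(s1$observed, s2$observed, tolerance = 1e-12)
})

test_that("the full null distribution is fixed bit-for-bit by the seed", {
  tree <- simulate_tree(30, seed = 10)
  d <- simulate_communities(tree, sim_params(n_samples = 3, n_taxa = 30,
                                             depth = 2000, core_size = 3,
                                             seed = 11))
  s1 <- ses_metric(d$table, tree, metric = "PSC", n_replicates = 40, seed = 12,
                   keep_replicates = TRUE)
  s2 <- ses_metric(d$table, tree, metric = "PSC", n_replicates = 40, seed = 12,
                   keep_replicates = TRUE)
  expect_identical(attr(s1, "replicates"), attr(s2, "replicates"))
})

test_that("quartile subsets are re-derived per replicate (frozen-pool mode differs)", {
  tree <- simulate_tree(60, seed = 13)
  d <- simulate_communities(tree, sim_params(n_samples = 3, n_taxa = 60,
                                             depth = 4000, core_size = 4,
                                             seed = 14))
  s_re <- ses_metric(d$table, tree, metric = "PSC", partition = "quartile",
                     n_replicates = 60, seed = 15)
  s_fr <- ses_metric(d$table, tree, metric = "PSC", partition = "quartile",
                     n_replicates = 60, seed = 15, freeze_subsets = TRUE)
  expect_equal(nrow(s_re), 6)  # 3 samples x rare/abundant
  expect_equal(s_re$observed, s_fr$observed, tolerance = 1e-12)
  # frozen mode draws from the subset's own pool: a different, non-degenerate null
  expect_false(any(s_fr$degenerate))
  expect_false(isTRUE(all.equal(s_re$null_mean, s_fr$null_mean)))
})

test_that("the null generator's own data is not rejected too often", {
  # SES of samples that ARE null draws should sit near 0 with unit spread
  tree <- simulate_tree(60, seed = 16)
  d <- simulate_communities(tree, sim_params(n_samples = 30, n_taxa = 60,
                                             depth = 3000, core_size = 4,
                                             seed = 17))
  obs <- richness_null(d$table, seed = 18)
  s <- ses_metric(obs, tree, metric = "PSC", n_replicates = 150, seed = 19)
  expect_lt(mean(abs(s$ses) > 2), 0.2)
  expect_lt(abs(mean(s$ses)), 0.5)
})
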