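cherry_tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")

test_that("Faith PD matches the hand-computed subtree sums", {
  expect_equal(faith_pd(cherry_tree, c("A", "B", "C", "D")), 6)
  expect_equal(faith_pd(cherry_tree, "A"), 2)          # path A -> root
  expect_equal(faith_pd(cherry_tree, c("A", "C")), 4)  # two tips + two stems
  # without the root, a cherry is just its two tip branches
  expect_equal(faith_pd(cherry_tree, c("A", "B"), include_root = FALSE), 2)
})

test_that("phylogenetic correlation matches shared-path arithmetic", {
  C <- phylo_correlation(cherry_tree, c("A", "B", "C", "D"))
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1, D = 1))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  expect_equal(unname(phylo_correlation(star, c("A", "B", "C", "D"))), diag(4))

  # ultrametric closed form: C_ij = MRCA depth / total depth
  for (seed in 1:3) {
    tr <- withr::with_seed(seed, ape::rcoal(6))
    taxa <- tr$tip.label
    C <- phylo_correlation(tr, taxa)
    total <- max(ape::node.depth.edgelength(tr))
    depths <- ape::node.depth.edgelength(tr)
    for (i in 1:5) for (j in (i + 1):6) {
      mrca <- ape::getMRCA(tr, taxa[c(i, j)])
      expect_equal(C[taxa[i], taxa[j]], depths[mrca] / total, tolerance = 1e-9)
    }
  }
})

test_that("PSC matches the hand-computed examples", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  expect_equal(psc(star, c("A", "B", "C", "D")), 1)
  expect_equal(psc(cherry_tree, c("A", "B", "C", "D")), 0.5)
  shallow <- ape::read.tree(text = "((A:0.1,B:0.1):1.9,(C:0.1,D:0.1):1.9):0;")
  expect_equal(psc(shallow, c("A", "B", "C", "D")), 0.05)
})

test_that("PD and PSC agree with brute-force path enumeration on random trees", {
  max_err <- 0
  for (seed in 1:100) {
    tr <- random_test_tree(8, seed = seed)
    taxa_all <- tr$tip.label
    sub <- withr::with_seed(seed * 13L, sample(taxa_all, sample(2:8, 1)))
    for (taxa in list(taxa_all, sub)) {
      max_err <- max(max_err,
        abs(faith_pd(tr, taxa) - oracle_pd(tr, taxa)),
        abs(faith_pd(tr, taxa, include_root = FALSE) -
              oracle_pd(tr, taxa, include_root = FALSE)),
        abs(psc(tr, taxa) - oracle_psc(tr, taxa)))
    }
  }
  expect_lt(max_err, 1e-9)
})

test_that("PD and PSC agree with picante on a simulated community", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(40, seed = 2)
  d <- simulate_communities(tree, sim_params(n_samples = 4, n_taxa = 40,
                                             depth = 2000, core_size = 5,
                                             seed = 3))
  ours_pd <- vapply(rownames(d$table), function(s)
    faith_pd(tree, colnames(d$table)[d$table[s, ] > 0]), numeric(1))
  ref <- picante::pd(d$table, tree, include.root = TRUE)
  expect_equal(unname(ours_pd), ref$PD, tolerance = 1e-9)

  ours_psc <- vapply(rownames(d$table), function(s)
    psc(tree, colnames(d$table)[d$table[s, ] > 0]), numeric(1))
  ref_psc <- picante::psc(d$table, tree)
  expect_equal(unname(ours_psc), ref_psc$PSCs, tolerance = 1e-9)
})

test_that("PD is monotone in the taxon set and totals the tree at all tips", {
  tr <- random_test_tree(20, seed = 9)
  taxa <- withr::with_seed(10, sample(tr$tip.label))
  pds <- vapply(2:20, function(k) faith_pd(tr, taxa[1:k]), numeric(1))
  expect_true(all(diff(pds) >= -1e-12))
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length), tolerance = 1e-12)
  expect_true(all(pds <= faith_pd(tr, tr$tip.label) + 1e-12))
})

test_that("PSC is invariant to rescaling branch lengths and bounded in [0,1]", {
  for (seed in 1:10) {
    tr <- random_test_tree(12, seed = seed)
    taxa <- withr::with_seed(seed, sample(tr$tip.label, 6))
    v1 <- psc(tr, taxa)
    tr2 <- tr; tr2$edge.length <- tr2$edge.length * 37.5
    expect_equal(psc(tr2, taxa), v1, tolerance = 1e-12)
    expect_gte(v1, 0); expect_lte(v1, 1)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(psc(cherry_tree, "A"), "at least two")
  expect_error(faith_pd(cherry_tree, character(0)), "no taxa")
  zero_tip <- ape::read.tree(text = "((A:0,B:1):0,(C:1,D:1):1):0;")
  expect_error(psc(zero_tip, c("A", "B", "C", "D")), "zero distance")
})

test_that("phylo_metrics emits the long sample x subset table", {
  tree <- simulate_tree(30, seed = 5)
  d <- simulate_communities(tree, sim_params(n_samples = 3, n_taxa = 30,
                                             depth = 3000, core_size = 3,
                                             seed = 6))
  parts <- quartile_partitions(d$table)
  pm <- phylo_metrics(d$table, tree, partitions = parts)
  expect_equal(nrow(pm), 3 * 3 * 2)  # samples x subsets x metrics
  for (s in unique(pm$sample_id)) {
    a <- pm$value[pm$sample_id == s & pm$metric == "PD" & pm$subset_label == "all"]
    subs <- pm$value[pm$sample_id == s & pm$metric == "PD" & pm$subset_label != "all"]
    expect_true(all(subs <= a + 1e-12))  # PD(all) >= PD(any subset)
  }
  expect_true(all(pm$value[pm$metric == "PSC"] >= 0 &
                  pm$value[pm$metric == "PSC"] <= 1))
})
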