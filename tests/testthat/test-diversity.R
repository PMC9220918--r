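test_that("rarefaction conserves depth and is the identity at full depth", {
  tab <- toy_table()
  full <- rarefy(tab, depth = min(rowSums(tab)), seed = 1)
  expect_true(all(rowSums(full) == min(rowSums(tab))))
  # a sample already at the target depth is passed through unchanged
  depths <- rowSums(tab)
  r <- suppressWarnings(rarefy(tab, depth = depths["S2"], seed = 2,
                               on_small = "drop"))
  expect_identical(r["S2", ], tab["S2", ])
  # never creates counts above the originals
  r2 <- rarefy(tab, 10, seed = 3)
  expect_true(all(r2 <= tab))
  expect_true(all(rowSums(r2) == 10))
})

test_that("rarefaction inclusion frequencies match the hypergeometric expectation", {
  # counts (6,3,1), depth 5: E[kept_i] = 5 * k_i / 10; check each ASV's mean
  # kept count over many seeded draws against a 3-sigma band
  tab <- matrix(c(6L, 3L, 1L), 1, 3, dimnames = list("S1", c("a", "b", "c")))
  n_draws <- 10000
  draws <- withr::with_seed(42, {
    t(vapply(seq_len(n_draws), function(i) rarefy(tab, 5)[1, ], numeric(3)))
  })
  k <- c(6, 3, 1); N <- 10; n <- 5
  expectation <- n * k / N
  variance <- n * (k / N) * (1 - k / N) * (N - n) / (N - 1)  # mv hypergeometric
  z <- (colMeans(draws) - expectation) / sqrt(variance / n_draws)
  expect_true(all(abs(z) < 3))
  expect_true(all(rowSums(draws) == 5))
})

test_that("rarefaction refuses or drops samples below depth, naming them", {
  tab <- toy_table()  # totals 25, 27, 21
  expect_error(rarefy(tab, 26), "S1")
  expect_warning(r <- rarefy(tab, 26, on_small = "drop"), "S1")
  expect_equal(rownames(r), "S2")
})

test_that("Shannon diversity matches the closed form in both bases", {
  tab <- rbind(S1 = c(10L, 10L, 10L, 10L))
  colnames(tab) <- paste0("a", 1:4)
  expect_equal(alpha_diversity(tab, "e")$shannon, log(4), tolerance = 1e-12)
  expect_equal(alpha_diversity(tab, "2")$shannon, 2, tolerance = 1e-12)

  tab2 <- rbind(S1 = c(5L, 3L, 2L)); colnames(tab2) <- paste0("a", 1:3)
  p <- c(5, 3, 2) / 10
  expect_equal(alpha_diversity(tab2, "e")$shannon, -sum(p * log(p)),
               tolerance = 1e-12)
  expect_equal(round(alpha_diversity(tab2, "e")$shannon, 4), 1.0297)

  tab3 <- rbind(S1 = c(7L, 0L, 0L)); colnames(tab3) <- paste0("a", 1:3)
  a <- alpha_diversity(tab3)
  expect_equal(a$observed, 1L)
  expect_equal(a$shannon, 0)
})

test_that("Shannon is bounded by log(richness), attained only when even", {
  set.seed(5)
  for (i in 1:20) {
    v <- rmultinom(1, 500, prob = runif(8))[, 1]
    tab <- rbind(S1 = as.integer(v)); colnames(tab) <- paste0("a", 1:8)
    a <- alpha_diversity(tab, "e")
    expect_lte(a$shannon, log(a$observed) + 1e-12)
  }
  even <- rbind(S1 = rep(9L, 8)); colnames(even) <- paste0("a", 1:8)
  expect_equal(alpha_diversity(even, "e")$shannon, log(8), tolerance = 1e-12)
})

test_that("beta diversity matches the set/count formulas and is bounded", {
  same <- rbind(S1 = c(3L, 2L, 1L), S2 = c(3L, 2L, 1L))
  colnames(same) <- paste0("a", 1:3)
  expect_equal(as.numeric(beta_diversity(same, "bray_curtis")), 0)
  expect_equal(as.numeric(beta_diversity(same, "jaccard")), 0)

  disjoint <- rbind(S1 = c(3L, 2L, 0L, 0L), S2 = c(0L, 0L, 4L, 1L))
  colnames(disjoint) <- paste0("a", 1:4)
  expect_equal(as.numeric(beta_diversity(disjoint, "bray_curtis")), 1)
  expect_equal(as.numeric(beta_diversity(disjoint, "jaccard")), 1)

  uv <- rbind(u = c(10L, 0L, 5L), v = c(5L, 5L, 5L))
  colnames(uv) <- paste0("a", 1:3)
  expect_equal(as.numeric(beta_diversity(uv, "bray_curtis")), 10 / 30,
               tolerance = 1e-12)
  expect_equal(as.numeric(beta_diversity(uv, "jaccard")), 1 - 2 / 3,
               tolerance = 1e-12)

  # Jaccard sees only presence: scaling one sample's counts changes nothing
  uv2 <- uv; uv2["u", ] <- uv2["u", ] * 7L
  expect_equal(as.numeric(beta_diversity(uv2, "jaccard")),
               as.numeric(beta_diversity(uv, "jaccard")))

  tab <- toy_table()
  for (m in c("bray_curtis", "jaccard")) {
    d <- as.numeric(beta_diversity(tab, m))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("UPGMA reproduces hand agglomeration with half-distance heights", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  phy <- upgma(d2)
  expect_equal(attr(phy, "merge_heights"), 1.5)

  m <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  phy <- upgma(m)
  expect_equal(attr(phy, "merge_heights"), c(1, 4))
  # s1 and s2 form the first cherry
  cherry <- ape::extract.clade(phy, ape::getMRCA(phy, c("s1", "s2")))
  expect_setequal(cherry$tip.label, c("s1", "s2"))

  perm <- c("s3", "s1", "s2")
  phy2 <- upgma(m[perm, perm])
  expect_true(ape::all.equal.phylo(phy, phy2))

  m_bad <- m; m_bad[1, 3] <- m_bad[3, 1] <- NaN
  expect_error(upgma(m_bad), "NA")
})

test_that("transect distances are absolute position differences", {
  meta <- data.frame(sample_id = paste0("S", 1:10),
                     position_m = seq(0, 1.5, length.out = 10))
  d <- as.matrix(geographic_distances(meta))
  expect_equal(d["S1", "S10"], 1.5)
  expect_equal(diag(d), setNames(rep(0, 10), paste0("S", 1:10)))
  expect_equal(d["S1", "S2"], 1.5 / 9, tolerance = 1e-12)
  expect_error(geographic_distances(data.frame(sample_id = "S1",
                                               position_m = NA_real_)),
               "position")
})

test_that("Mantel test: identity gives r = 1 and the minimal p-value", {
  set.seed(11)
  d <- dist(matrix(rnorm(20), 10))
  res <- mantel_test(d, d, n_permutations = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_false(res$exhaustive)        # 10! > 999: randomization scheme
  expect_equal(res$p, 1 / 1000)

  res5 <- mantel_test(dist(matrix(rnorm(10), 5)), dist(matrix(rnorm(10), 5)),
                      n_permutations = 999, seed = 2)
  expect_true(res5$exhaustive)        # 5! = 120 <= 999: exact enumeration
  expect_gte(res5$p, 1 / 120)
})

test_that("Mantel permutation p equals exhaustive enumeration on 4 labels", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- dist(matrix(rnorm(8), 4))
    b <- dist(matrix(rnorm(8), 4))
    res <- mantel_test(a, b, n_permutations = 999)
    orc <- oracle_mantel_exhaustive(a, b)
    expect_true(res$exhaustive)
    expect_equal(res$r, orc$r, tolerance = 1e-12)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
  }
})

test_that("Mantel r agrees with vegan and errors on degenerate input", {
  set.seed(3)
  a <- dist(matrix(rnorm(20), 10))
  b <- dist(matrix(rnorm(20), 10))
  res <- mantel_test(a, b, n_permutations = 99, seed = 4)
  ref <- vegan::mantel(a, b, permutations = 9)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)

  flat <- matrix(1, 4, 4) - diag(4)
  dimnames(flat) <- list(letters[1:4], letters[1:4])
  expect_error(mantel_test(flat, flat), "zero variance")
})
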