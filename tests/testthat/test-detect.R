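random_distance <- function(n, labels = paste0("h", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

test_that("Mantel statistic and p behave at the self- and anti-correlation limits", {
  set.seed(3)
  # n = 10 so that a random permutation is essentially never the identity
  d <- random_distance(10)
  res <- mantel_test(d, d, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 1000)
  res2 <- mantel_test(d, 5 - 2 * d, n_perm = 99, seed = 1)
  expect_equal(res2$statistic, -1)
  expect_gt(res2$p_value, 0.9)
  expect_error(mantel_test(d, matrix(1, 10, 10) - diag(10)), "variance")
})

test_that("Monte Carlo Mantel p converges to the exact enumeration p", {
  for (n in c(4L, 5L)) {
    set.seed(n * 7)
    d1 <- random_distance(n)
    d2 <- random_distance(n)
    exact <- mantel_exact_oracle(d1, d2)
    res <- mantel_test(d1, d2, n_perm = 9999, seed = 2)
    expect_equal(res$statistic, exact$r, tolerance = 1e-12)
    # binomial error of the MC estimate around the enumeration value
    se <- sqrt(exact$p * (1 - exact$p) / 9999)
    expect_lt(abs(res$p_value - exact$p), 4 * se + 2e-4)
  }
})

test_that("Mantel agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(13)
  d1 <- random_distance(10)
  d2 <- matrix(0, 10, 10, dimnames = dimnames(d1))
  d2[lower.tri(d2)] <- 0.6 * d1[lower.tri(d1)] + 0.4 * stats::runif(45)
  d2 <- d2 + t(d2)
  ours <- mantel_test(d1, d2, n_perm = 9999, seed = 4)
  ref <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       permutations = 9999)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.02)
})

test_that("UPGMA produces the hand-derived ultrametric dendrogram", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(sort(unname(t2$edge.length)), c(1.5, 1.5))

  d4 <- matrix(6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4[cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))] <- 2
  diag(d4) <- 0
  t4 <- upgma(d4)
  expect_setequal(t4$tip.label, LETTERS[1:4])
  # merges at heights 1, 1, 3
  depths <- ape::node.depth.edgelength(t4)
  node_heights <- max(depths) - depths[(5):(4 + t4$Nnode)]
  expect_equal(sort(node_heights), c(1, 1, 3))
  # topology ((A,B),(C,D))
  expect_equal(nrf_clade_oracle(
    t4, ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")), 0)
})

test_that("normalized RF equals brute-force clade comparison and phangorn", {
  t1 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  t2 <- ape::read.tree(text = "(((d:1,c:1):1,b:2):1,a:3);")
  expect_equal(normalized_rf(t1, t1), 0)
  expect_equal(normalized_rf(t1, t2), 1)  # no shared non-trivial clade
  expect_equal(normalized_rf(t1, t2), normalized_rf(t2, t1))
  # branch lengths are ignored
  t1b <- t1
  t1b$edge.length <- t1b$edge.length * 3
  expect_equal(normalized_rf(t1, t1b), 0)

  has_phangorn <- requireNamespace("phangorn", quietly = TRUE)
  set.seed(9)
  for (i in 1:10) {
    x <- sim_yule_tree(25)
    y <- sim_yule_tree(25)
    y$tip.label <- sample(x$tip.label)
    expect_equal(normalized_rf(x, y), nrf_clade_oracle(x, y))
    if (has_phangorn) {
      expect_equal(normalized_rf(x, y),
                   phangorn::RF.dist(x, y, rooted = TRUE) / (2 * (25 - 2)))
    }
  }
  t3 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(normalized_rf(t1, t3), "tip labels")
})

test_that("dendrogram test recovers a tree from its own cophenetic matrix", {
  set.seed(15)
  for (i in 1:5) {
    tr <- sim_yule_tree(12)
    res <- dendrogram_test(tr, cophenetic_distances(tr), n_perm = 199,
                           seed = i)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1 / 200)
  }
  # p respects the permutation floor and cap
  tr <- sim_yule_tree(10, seed = 44)
  d <- random_distance(10, tr$tip.label)
  for (nm in c("tip_shuffle", "random_trees")) {
    res <- dendrogram_test(tr, d, n_perm = 99, null_model = nm, seed = 5)
    expect_gte(res$p_value, 1 / 100)
    expect_lte(res$p_value, 1)
    expect_identical(res$null_model, nm)
  }
})

test_that("the dendrogram tip-shuffle null equals explicit relabel-and-recompute", {
  set.seed(25)
  tr <- sim_yule_tree(10)
  d <- random_distance(10, tr$tip.label)
  dend <- upgma(d)
  res <- dendrogram_test(tr, d, n_perm = 200, seed = 6)
  # recompute the null by brute force: shuffle labels on a copy of the tree
  set.seed(6)
  brute <- vapply(seq_len(200), function(k) {
    shuf <- tr
    shuf$tip.label <- tr$tip.label[sample.int(10)]
    nrf_clade_oracle(shuf, dend)
  }, numeric(1))
  # identical RNG stream: the two null samples must match draw for draw
  expect_equal(res$null_stats, brute)
  expect_equal(res$statistic, nrf_clade_oracle(tr, dend))
})

test_that("trait Mantel uses Euclidean trait distances", {
  set.seed(35)
  traits <- matrix(stats::rnorm(8), dimnames = list(paste0("h", 1:8), NULL))
  d <- random_distance(8)
  res <- trait_mantel(traits, d, n_perm = 99, seed = 1)
  ref <- mantel_test(as.matrix(stats::dist(traits)), d, n_perm = 99, seed = 1)
  expect_equal(res$statistic, ref$statistic)
  expect_identical(res$method, "trait_mantel")
  # single trait: Euclidean distance is the absolute difference
  expect_equal(unname(as.matrix(stats::dist(traits))[2, 1]),
               unname(abs(traits[2, 1] - traits[1, 1])))
  expect_error(trait_mantel(matrix(rep(1, 8), 8, 1,
                                   dimnames = list(paste0("h", 1:8), NULL)),
                            d), "variance")
})

test_that("cophenetic distances equal breadth-first edge walks", {
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  D <- cophenetic_distances(tr)
  expect_equal(D["a", "b"], 1)
  expect_equal(D["a", "c"], 2)
  set.seed(45)
  for (i in 1:5) {
    tr <- sim_yule_tree(6)
    D <- cophenetic_distances(tr)
    W <- cophenetic_walk_oracle(tr)
    expect_equal(D[rownames(W), colnames(W)], W, tolerance = 1e-12)
    expect_true(all(D <= 2 + 1e-9))  # unit-height tree: path <= 2
  }
})

test_that("phylosymbiosis_test wires data, metric and method together", {
  set.seed(55)
  tr <- sim_yule_tree(8)
  mt <- sim_yule_tree(30)
  ht <- sim_host_traits(tr, delta = 0.1)
  mp <- rescale_microbe_traits(sim_bm_traits(mt), ht$traits)
  tab <- assemble_system(ht$traits, mp, assembly_params(), seed = 3)
  res <- phylosymbiosis_test(tr, tab, method = "mantel", metric = "wunifrac",
                             microbe_tree = mt, n_perm = 99, seed = 1)
  ref <- mantel_test(cophenetic_distances(tr),
                     distance_matrix(tab, "wunifrac", mt),
                     n_perm = 99, seed = 1)
  expect_s3_class(res, "phylosym_test")
  expect_equal(res$statistic, ref$statistic)
  expect_equal(res$p_value, ref$p_value)
  expect_identical(res$metric, "wunifrac")
  res2 <- phylosymbiosis_test(tr, tab, method = "trait_mantel",
                              metric = "braycurtis", host_traits = ht$traits,
                              n_perm = 99, seed = 1)
  expect_identical(res2$method, "trait_mantel")
  expect_error(phylosymbiosis_test(tr, tab, method = "trait_mantel",
                                   metric = "braycurtis", n_perm = 9),
               "host_traits")
  expect_output(print(summary(res)), "Phylosymbiosis test")
})
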