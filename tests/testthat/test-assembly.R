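make_prefs <- function(v) {
  matrix(v, ncol = 1, dimnames = list(paste0("m", seq_along(v)), "trait1"))
}

test_that("environmental fitness is a Gaussian kernel of trait mismatch", {
  prefs <- make_prefs(c(0, 0.5, 3))
  f <- environmental_fitness(0, prefs, niche_breadth = 0.5)
  expect_equal(unname(f[1]), 1)
  expect_equal(unname(f[2]), exp(-0.5), tolerance = 1e-12)
  expect_true(f[3] < f[2] && f[2] < f[1])
  # monotone decay in |h - m|
  grid <- make_prefs(seq(0, 5, by = 0.5))
  expect_true(all(diff(environmental_fitness(0, grid, 0.5)) < 0))
  # product over trait dimensions
  prefs2 <- matrix(c(0.5, 0.5), 1, 2)
  f2 <- environmental_fitness(c(0, 0), prefs2, 0.5)
  expect_equal(unname(f2), exp(-0.5)^2, tolerance = 1e-12)
  expect_error(environmental_fitness(0, prefs, 0), "niche_breadth")
})

test_that("competition penalty reflects niche overlap with residents", {
  prefs <- make_prefs(c(0, 0, 4))
  expect_equal(competition_penalty(c(0, 0, 0), prefs, 0.5), rep(1, 3))
  # community entirely made of microbe 1: its own penalty is 0
  pen <- competition_penalty(c(150, 0, 0), prefs, 0.5)
  expect_equal(unname(pen[1]), 0)
  # identical preferences get identical penalties
  expect_equal(unname(pen[1]), unname(pen[2]))
  # a distant microbe is barely penalized
  expect_gt(pen[3], 0.99)
})

test_that("recruitment mixes normalized components by the beta weights", {
  p0 <- assembly_params(beta_env = 1, beta_abun = 0)
  e <- c(0.2, 0.1, 0.1)
  expect_equal(recruitment_probabilities(e, c(0, 0, 0), rep(1, 3), p0),
               e / sum(e))
  p1 <- assembly_params(beta_env = 0, beta_abun = 1)
  expect_equal(recruitment_probabilities(e, c(3, 1, 0), rep(1, 3), p1),
               c(0.75, 0.25, 0))
  p2 <- assembly_params(beta_env = 0.5, beta_abun = 0.5)
  expect_equal(recruitment_probabilities(c(1, 1), c(1, 0), c(1, 1), p2),
               c(0.75, 0.25))
  # empty community: abundance component is uniform
  expect_equal(recruitment_probabilities(c(1, 1), c(0, 0), c(1, 1), p1),
               c(0.5, 0.5))
  expect_error(recruitment_probabilities(c(-1, 1), c(0, 0), c(1, 1), p1),
               "nonnegative")
})

test_that("assembled communities always hold exactly `capacity` individuals", {
  prefs <- make_prefs(stats::rnorm(20))
  pars <- assembly_params(capacity = 77L, years = 5L)
  a <- assemble_community(0.3, prefs, pars, seed = 1)
  expect_identical(sum(a), 77L)
  expect_named(a, rownames(prefs))
  # single-microbe pool is forced
  one <- assemble_community(0, make_prefs(0), pars, seed = 2)
  expect_identical(unname(one), 77L)
})

test_that("pure filtering equals one multinomial draw with Gaussian weights", {
  prefs <- make_prefs(c(-0.5, 0, 0.4, 1.5))
  pars <- assembly_params(beta_env = 1, beta_abun = 0, beta_comp = 0,
                          years = 20L, capacity = 150L)
  efit <- environmental_fitness(0.1, prefs, 0.5)
  p_exp <- efit / sum(efit)
  set.seed(31)
  reps <- 1000L
  counts <- vapply(seq_len(reps),
                   function(i) assemble_community(0.1, prefs, pars),
                   integer(4))
  # pooled counts are multinomial(reps * capacity, p_exp) if the claim
  # holds: chi-square goodness of fit
  expect_gt(stats::chisq.test(rowSums(counts), p = p_exp)$p.value, 1e-3)
  expect_true(all(abs(rowMeans(counts) / 150 - p_exp) < 0.01))

  # T-step process with no abundance/competition feedback is distributionally
  # one multinomial draw: per-taxon abundance distributions at T=1 and T=20
  # must agree (KS, Bonferroni-adjusted, alpha = 0.01)
  pars1 <- assembly_params(beta_env = 1, beta_abun = 0, years = 1L)
  set.seed(32)
  a20 <- vapply(seq_len(1000), function(i) assemble_community(0.1, prefs, pars),
                integer(4))
  a1 <- vapply(seq_len(1000), function(i) assemble_community(0.1, prefs, pars1),
               integer(4))
  pvals <- vapply(1:4, function(j) {
    suppressWarnings(stats::ks.test(a20[j, ], a1[j, ])$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01 / 4))
})

test_that("neutral assembly drifts: uniform mean, growing variance", {
  prefs <- make_prefs(stats::rnorm(5))
  neutral <- function(years) {
    assembly_params(beta_env = 0, beta_abun = 1, years = years,
                    capacity = 100L)
  }
  set.seed(41)
  reps <- 1000L
  f1 <- vapply(seq_len(reps),
               function(i) assemble_community(0, prefs, neutral(1L)) / 100,
               numeric(5))
  f20 <- vapply(seq_len(reps),
                function(i) assemble_community(0, prefs, neutral(20L)) / 100,
                numeric(5))
  # martingale: expected relative abundance stays uniform
  expect_true(all(abs(rowMeans(f20) - 0.2) < 0.05))
  # drift accumulates variance across steps
  expect_gt(mean(apply(f20, 1, stats::var)), 2 * mean(apply(f1, 1, stats::var)))
})

test_that("per-host assembly is reproducible and trait-driven", {
  set.seed(51)
  prefs <- make_prefs(stats::rnorm(30))
  traits <- matrix(c(0.2, 0.2, -1), dimnames = list(c("h1", "h2", "h3"),
                                                    "trait1"))
  pars <- assembly_params()
  tab <- assemble_system(traits, prefs, pars, seed = 5)
  expect_identical(dim(tab), c(3L, 30L))
  expect_true(all(rowSums(tab) == 150L))
  expect_identical(tab, assemble_system(traits, prefs, pars, seed = 5))
  # identical traits + identical per-host seed give identical rows
  r1 <- assemble_community(traits[1, ], prefs, pars, seed = 99)
  r2 <- assemble_community(traits[2, ], prefs, pars, seed = 99)
  expect_identical(r1, r2)

  # sharp niche: individuals concentrate on the closest preferences
  sharp <- assembly_params(niche_breadth = 0.01)
  host <- 0.2
  comm <- assemble_community(host, prefs, sharp, seed = 6)
  nearest <- order(abs(prefs[, 1] - host))[1:3]
  expect_gt(sum(comm[nearest]) / 150, 0.9)
})

test_that("stronger filtering strengthens the trait-community correlation", {
  set.seed(61)
  n_h <- 12L
  prefs <- make_prefs(stats::rnorm(40))
  traits <- matrix(stats::rnorm(n_h), dimnames = list(paste0("h", 1:n_h),
                                                      "trait1"))
  mean_r <- vapply(c(0, 0.5, 1), function(be) {
    pars <- assembly_params(beta_env = be, beta_abun = 1 - be)
    rs <- vapply(seq_len(40), function(i) {
      tab <- assemble_system(traits, prefs, pars)
      d <- distance_matrix(tab, "braycurtis")
      mantel_test(as.matrix(stats::dist(traits)), d, n_perm = 1)$statistic
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  # neutral communities are independent of host traits ...
  expect_lt(abs(mean_r[1]), 0.15)
  # ... and the correlation does not decrease with filter strength
  expect_true(mean_r[1] <= mean_r[2] + 0.05 && mean_r[2] <= mean_r[3] + 0.05)
  expect_gt(mean_r[3], 0.3)
})
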