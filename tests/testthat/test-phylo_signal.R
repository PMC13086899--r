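test_that("K is exactly 1 on star phylogenies for any non-constant trait", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    tr <- star_tree(n, d = runif(1, 0.5, 3))
    x <- stats::setNames(rnorm(n), tr$tip.label)
    expect_equal(blomberg_k(tr, x), 1, tolerance = 1e-10)
  }
})

test_that("K matches direct formula evaluation and phytools on random trees", {
  # frozen 4-tip example, independently verified
  expect_equal(blomberg_k(tree4(), c(A = 1, B = 2, C = 7, D = 9)),
               1.619095477387, tolerance = 1e-10)

  set.seed(8)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:8, 1))
    x <- stats::setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    expect_equal(blomberg_k(tr, x), k_oracle(vcv_bruteforce(tr), x),
                 tolerance = 1e-10)
  }

  skip_if_not_installed("phytools")
  tr <- ape::rtree(10)
  x <- stats::setNames(rnorm(10), tr$tip.label)
  expect_equal(blomberg_k(tr, x),
               unname(c(phytools::phylosig(tr, x, method = "K"))),
               tolerance = 1e-6)
})

test_that("K is invariant to affine trait transforms and tree rescaling", {
  tr <- simulate_tree(12, seed = 31)
  x <- simulate_bm(tr, 1, 0, seed = 7)
  k <- blomberg_k(tr, x)
  expect_equal(blomberg_k(tr, 3.7 * x - 11), k, tolerance = 1e-10)
  expect_equal(blomberg_k(tr, -x), k, tolerance = 1e-10)
  scaled <- tr
  scaled$edge.length <- tr$edge.length * 42
  expect_equal(blomberg_k(scaled, x), k, tolerance = 1e-10)
})

test_that("K rejects degenerate input", {
  tr <- tree4()
  expect_error(blomberg_k(tr, c(A = 1, B = 1, C = 1, D = 1)), "constant")
  expect_error(blomberg_k(tr, c(A = 1, B = 2)), "at least 3")
})

test_that("permutation test uses the add-one convention and is deterministic", {
  tr <- simulate_tree(10, seed = 17)
  x <- simulate_bm(tr, 1, 0, seed = 2)
  r1 <- permutation_test_k0(tr, x, n_perm = 999, seed = 5)
  r2 <- permutation_test_k0(tr, x, n_perm = 999, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 1000)          # add-one floor
  expect_lte(r1$p, 1)

  # recompute the add-one p with an independent loop over the same RNG
  # stream of tip shuffles
  x_ord <- x[tr$tip.label]
  set.seed(5)
  k_perm <- replicate(999, {
    shuffled <- stats::setNames(unname(sample(x_ord)), tr$tip.label)
    blomberg_k(tr, shuffled)
  })
  k_obs <- blomberg_k(tr, x)
  expect_equal(r1$p, (1 + sum(k_perm >= k_obs)) / 1000)
})

test_that("permutation p-values are uniform under the shuffle null", {
  tr <- simulate_tree(8, seed = 13)
  set.seed(99)
  ps <- sapply(1:500, function(i) {
    x <- stats::setNames(rnorm(8), tr$tip.label)   # exchangeable across tips
    permutation_test_k0(tr, x, n_perm = 199,
                        seed = sample.int(2^30, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BM simulation test is calibrated, symmetric and scale invariant", {
  tr <- simulate_tree(10, seed = 23)
  x <- simulate_bm(tr, 1, 0, seed = 3)
  a <- bm_simulation_test_k1(tr, x, n_sim = 500, seed = 11)
  b <- bm_simulation_test_k1(tr, 10 * x, n_sim = 500, seed = 11)
  expect_equal(a$K, b$K, tolerance = 1e-12)  # K scale invariance
  expect_identical(a$p, b$p)                 # carries to the test decision
  expect_lte(a$p, 1)

  # traits that are themselves BM should rarely reject K = 1
  set.seed(41)
  rej <- sapply(1:200, function(i) {
    y <- simulate_bm(tr, 1, 0)
    bm_simulation_test_k1(tr, y, n_sim = 199,
                          seed = sample.int(2^30, 1))$p < 0.05
  })
  expect_gte(mean(!rej), 0.94)
})

test_that("mean K over BM simulations on a 15-tip tree is about 1", {
  tr <- simulate_tree(15, seed = 77)
  set.seed(7)
  ks <- sapply(1:1000, function(i) blomberg_k(tr, simulate_bm(tr, 1, 0)))
  expect_gt(mean(ks), 0.9)
  expect_lt(mean(ks), 1.1)
})

test_that("signal_table reports K and both tests per neuropil", {
  sim <- simulate_dataset(sim_config(n_species = 10, seed = 19))
  summed <- sum_paired(sim$volumes)
  ref <- reference_volume(summed)
  analysed <- summed[!(summed$neuropil %in% lepibrain:::.reference_regions), ]
  traits <- relative_volumes(species_aggregate(analysed), ref)
  st <- signal_table(traits, sim$tree, n_perm = 99, n_sim = 99, seed = 1)
  expect_equal(nrow(st), ncol(traits$mean))
  expect_true(all(st$K > 0, na.rm = TRUE))
  expect_true(all(st$p_K0 > 0 & st$p_K0 <= 1, na.rm = TRUE))
  expect_true(all(st$p_K1 > 0 & st$p_K1 <= 1, na.rm = TRUE))
  # deterministic under the master seed
  st2 <- signal_table(traits, sim$tree, n_perm = 99, n_sim = 99, seed = 1)
  expect_identical(st, st2)
})
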