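# two-block trait structure: traits within a block share a latent BM factor
sim_blocks <- function(tree, block_sizes = c(4, 4), noise_sd = 0.01,
                       seed = 1) {
  set.seed(seed)
  sp <- tree$tip.label
  latents <- lapply(block_sizes, function(.) simulate_bm(tree, 1, 0))
  # decorrelate the block factors so the planted blocks are well separated
  # (independent BM draws on few tips can be strongly correlated by chance)
  for (g in seq_along(latents)[-1]) {
    l1 <- latents[[1]] - mean(latents[[1]])
    lg <- latents[[g]] - mean(latents[[g]])
    latents[[g]] <- lg - sum(lg * l1) / sum(l1 * l1) * l1
  }
  M <- do.call(cbind, lapply(seq_along(block_sizes), function(g) {
    sapply(seq_len(block_sizes[g]), function(j)
      latents[[g]] + rnorm(length(sp), 0, noise_sd))
  }))
  colnames(M) <- unlist(lapply(seq_along(block_sizes), function(g)
    paste0("blk", g, "_", seq_len(block_sizes[g]))))
  rownames(M) <- sp
  M
}

tree12 <- simulate_tree(12, seed = 321)
C12 <- vcv_matrix(tree12)

test_that("pairwise slopes are 1 on the diagonal and reciprocal when exact", {
  sp <- tree12$tip.label
  base <- simulate_bm(tree12, 1, 0, seed = 4)
  M <- cbind(a = 2 * base, b = base, c = -base + 5)   # exact log-linear links
  rownames(M) <- sp
  sm <- pairwise_slopes(M, C12, scale = "as_is")
  expect_equal(diag(sm$slope), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sm$slope["a", "b"], 2, tolerance = 1e-8)
  expect_equal(sm$slope["b", "a"], 0.5, tolerance = 1e-8)
  expect_equal(sm$slope["c", "b"], -1, tolerance = 1e-8)
})

test_that("insufficient species overlap marks cells missing", {
  sp <- tree12$tip.label
  M <- sim_blocks(tree12, c(2, 2), seed = 9)
  M[sp[1:9], 1] <- NA                      # only 3 species left for trait 1
  sm <- pairwise_slopes(M, C12, scale = "as_is", min_species = 4)
  expect_true(all(is.na(sm$slope[1, -1])))
  expect_false(anyNA(sm$slope[-1, -1]))
})

test_that("to_distance yields a symmetric non-negative distance on [0, 2]", {
  M <- sim_blocks(tree12, c(3, 3), noise_sd = 0.1, seed = 2)
  sm <- pairwise_slopes(M, C12, scale = "as_is")
  td <- to_distance(sm)
  d <- td$distance
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, ncol(M)), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 2 + 1e-12))
  expect_true(all(abs(td$association) <= 1 + 1e-12))
  # maximal association maps to distance 0, maximal opposition to 2
  expect_equal(min(d[upper.tri(d)]),
               1 - max(td$association[upper.tri(td$association)]))
})

test_that("planted blocks sit closer within than between and are recovered", {
  ok <- sapply(1:100, function(i) {
    M <- sim_blocks(tree12, c(4, 4), noise_sd = 0.01, seed = i)
    sm <- pairwise_slopes(M, C12, scale = "as_is")
    d <- to_distance(sm)$distance
    within <- c(d[1:4, 1:4][upper.tri(diag(4))], d[5:8, 5:8][upper.tri(diag(4))])
    between <- d[1:4, 5:8]
    cl <- hcluster(d, k = 2)$clusters
    max(within) < min(between) &&
      same_partition(cl, rep(1:2, each = 4))
  })
  expect_equal(mean(ok), 1)
})

test_that("hcluster is deterministic, exports Newick, and rejects bad input", {
  M <- sim_blocks(tree12, c(3, 3), seed = 5)
  d <- to_distance(pairwise_slopes(M, C12, scale = "as_is"))$distance
  a <- hcluster(d, k = 2)
  b <- hcluster(d, k = 2)
  expect_identical(a$newick, b$newick)
  expect_identical(a$clusters, b$clusters)
  # merges at tiny heights legitimately yield near-zero terminal branches
  dendro <- suppressWarnings(parse_newick(a$newick, default_branch_length = 1))
  expect_setequal(dendro$tip.label, colnames(M))

  dd <- d; dd[1, 2] <- dd[2, 1] <- NA
  expect_error(hcluster(dd), "finite")

  # identical traits merge at height zero
  sp <- tree12$tip.label
  base <- simulate_bm(tree12, 1, 0, seed = 8)
  M2 <- cbind(u = base, v = base, w = 3 * base + rnorm(12, 0, 0.2))
  rownames(M2) <- sp
  d2 <- to_distance(pairwise_slopes(M2, C12, scale = "as_is"))$distance
  hc <- hcluster(d2)$hclust
  expect_lt(hc$height[1], 1e-8)
})

test_that("missing associations are imputed with a warning or rejected", {
  sp <- tree12$tip.label
  M <- sim_blocks(tree12, c(2, 2), seed = 10)
  M[sp[1:9], 1] <- NA
  sm <- pairwise_slopes(M, C12, scale = "as_is", min_species = 4)
  expect_error(to_distance(sm, impute_missing = FALSE), "missing")
  expect_warning(td <- to_distance(sm), "imputed")
  expect_false(anyNA(td$distance))
})
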