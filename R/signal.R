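#' Blomberg's K phylogenetic-signal statistic
#'
#' K compares the observed ratio of non-phylogenetic to phylogenetic mean
#' squared error against its Brownian-motion expectation on the same tree:
#'
#' \deqn{K = \frac{MSE_0 / MSE}{E_{BM}[MSE_0/MSE]}}
#'
#' with the phylogenetic (GLS) mean \eqn{\hat a = (1'C^{-1}1)^{-1} 1'C^{-1}x},
#' \eqn{MSE_0 = (x-\hat a)'(x-\hat a)/(n-1)},
#' \eqn{MSE = (x-\hat a)'C^{-1}(x-\hat a)/(n-1)} and
#' \eqn{E_{BM}[MSE_0/MSE] = (tr(C) - n/(1'C^{-1}1))/(n-1)}.
#' K = 1 matches the BM expectation; K < 1 means relatives resemble each
#' other less than BM predicts, K > 1 more. K is invariant to affine
#' transforms of the trait and to the overall scale of the tree.
#'
#' @param tree A `"phylo"` object (>= 3 tips carrying the trait).
#' @param trait Named numeric vector; names must match tip labels.
#' @param ridge Non-negative diagonal inflation added to `C` when it is
#'   numerically singular (default 0: singularity is an error).
#' @return K (single numeric).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' blomberg_k(tr, c(A = 1, B = 2, C = 7, D = 9))
#' @export
blomberg_k <- function(tree, trait, ridge = 0) {
  prep <- .k_prepare(tree, trait, ridge)
  .k_stats(prep, matrix(prep$x, ncol = 1))[1]
}

# Precompute everything K needs from the tree; trait vector aligned to C.
.k_prepare <- function(tree, trait, ridge = 0) {
  if (is.null(names(trait))) stop("trait must be named by species", call. = FALSE)
  trait <- trait[!is.na(trait)]
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < 3L)
    stop("trait must be defined for at least 3 tips", call. = FALSE)
  if (length(common) < length(tree$tip.label))
    tree <- prune_to_species(tree, common)
  x <- trait[tree$tip.label]
  if (stats::var(x) == 0)
    stop("trait is constant; K is undefined", call. = FALSE)
  C <- vcv_matrix(tree)
  if (ridge > 0) C <- C + diag(ridge, nrow(C))
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance; consider a positive ridge",
         call. = FALSE))
  n <- length(x)
  one <- rep(1, n)
  sum_cinv <- sum(Cinv)
  w <- colSums(Cinv) / sum_cinv            # GLS mean weights
  expected <- (sum(diag(C)) - n / sum_cinv) / (n - 1)
  list(tree = tree, x = x, C = C, Cinv = Cinv, w = w, expected = expected,
       n = n)
}

# K for each column of trait matrix X (n x m), vectorized for permutation and
# simulation loops.
.k_stats <- function(prep, X) {
  ahat <- drop(crossprod(prep$w, X))
  D <- sweep(X, 2, ahat, "-")
  mse0 <- colSums(D * D)
  mse <- colSums(D * (prep$Cinv %*% D))
  (mse0 / mse) / prep$expected
}

#' Permutation test of K = 0 (no phylogenetic signal)
#'
#' Shuffles the trait values across the tips uniformly at random `n_perm`
#' times and compares the observed K to the permuted distribution; one-sided
#' (large K indicates signal) with add-one correction:
#' p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1).
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `K`, `p`, `n_perm`.
#' @export
permutation_test_k0 <- function(tree, trait, n_perm = 10000L, seed = 1L,
                                ridge = 0) {
  prep <- .k_prepare(tree, trait, ridge)
  k_obs <- .k_stats(prep, matrix(prep$x, ncol = 1))[1]
  set.seed(seed)
  perm <- replicate(n_perm, sample(prep$x))
  k_perm <- .k_stats(prep, perm)
  p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  list(K = k_obs, p = p, n_perm = as.integer(n_perm))
}

#' Brownian-motion simulation test of K = 1
#'
#' Simulates `n_sim` trait datasets under BM on the tree (unit rate; K is
#' scale-invariant so the rate is immaterial), computes K for each, and
#' performs a two-sided test of the observed K against the simulated
#' distribution with add-one correction:
#' p = min(1, 2 min(P(K_sim <= K_obs), P(K_sim >= K_obs))).
#'
#' @inheritParams blomberg_k
#' @param n_sim Number of BM simulations.
#' @param seed Integer seed.
#' @return List with `K`, `p`, `n_sim`.
#' @export
bm_simulation_test_k1 <- function(tree, trait, n_sim = 10000L, seed = 1L,
                                  ridge = 0) {
  prep <- .k_prepare(tree, trait, ridge)
  k_obs <- .k_stats(prep, matrix(prep$x, ncol = 1))[1]
  set.seed(seed)
  # tips under BM ~ MVN(0, C): draw all replicates in one matrix operation
  L <- t(chol(prep$C))
  Z <- matrix(stats::rnorm(prep$n * n_sim), prep$n, n_sim)
  k_sim <- .k_stats(prep, L %*% Z)
  p_lo <- (1 + sum(k_sim <= k_obs)) / (n_sim + 1)
  p_hi <- (1 + sum(k_sim >= k_obs)) / (n_sim + 1)
  list(K = k_obs, p = min(1, 2 * min(p_lo, p_hi)), n_sim = as.integer(n_sim))
}

#' Phylogenetic signal for every neuropil in a trait matrix
#'
#' Runs [blomberg_k()], the K = 0 permutation test and the K = 1 BM
#' simulation test on each neuropil's species-mean volumes. Traits enter as
#' log10 of relative volumes by default (`scale = "log_relative"`); raw
#' absolute means are available via `scale = "raw"`.
#'
#' @param traits A `"trait_matrix"` with `relative` filled in (see
#'   [relative_volumes()]), or any species x trait numeric matrix.
#' @param tree A `"phylo"` object.
#' @param scale `"log_relative"` (default) or `"raw"`.
#' @param n_perm,n_sim Replicates for the two tests.
#' @param seed Master seed; per-neuropil streams derive from it.
#' @param alpha Significance level for the flag columns.
#' @return Data.frame: `neuropil`, `n`, `K`, `p_K0`, `p_K1`, `signif_K0`,
#'   `signif_K1`.
#' @export
signal_table <- function(traits, tree, scale = c("log_relative", "raw"),
                         n_perm = 10000L, n_sim = 10000L, seed = 1L,
                         alpha = 0.05) {
  scale <- match.arg(scale)
  M <- .trait_values(traits, scale)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * ncol(M))
  rows <- lapply(seq_len(ncol(M)), function(k) {
    x <- M[, k]
    x <- x[!is.na(x)]
    if (length(x) < 3L || stats::var(x) == 0)
      return(data.frame(neuropil = colnames(M)[k], n = length(x),
                        K = NA_real_, p_K0 = NA_real_, p_K1 = NA_real_,
                        signif_K0 = NA, signif_K1 = NA,
                        stringsAsFactors = FALSE))
    t0 <- permutation_test_k0(tree, x, n_perm, seed = seeds[2 * k - 1])
    t1 <- bm_simulation_test_k1(tree, x, n_sim, seed = seeds[2 * k])
    data.frame(neuropil = colnames(M)[k], n = length(x), K = t0$K,
               p_K0 = t0$p, p_K1 = t1$p,
               signif_K0 = t0$p < alpha, signif_K1 = t1$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# species x trait matrix on the requested scale
.trait_values <- function(traits, scale = "log_relative") {
  if (inherits(traits, "trait_matrix")) {
    M <- switch(scale,
                log_relative = {
                  if (is.null(traits$relative))
                    stop("trait matrix has no relative volumes; call relative_volumes() first",
                         call. = FALSE)
                  log10(traits$relative)
                },
                raw = traits$mean)
  } else {
    M <- as.matrix(traits)
    if (scale == "log_relative") M <- log10(M)
  }
  M
}
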