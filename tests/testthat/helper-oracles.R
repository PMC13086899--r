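# Independent oracles, deliberately naive so they share no code path with the
# implementation they check.

# Shared-branch-length matrix by explicit root-to-tip path enumeration and
# common-prefix summation.
vcv_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(i) {
    p <- i
    node <- i
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      node <- tree$edge[e, 1]
      p <- c(node, p)
    }
    p
  })
  edgelen <- function(parent, child)
    tree$edge.length[tree$edge[, 1] == parent & tree$edge[, 2] == child]
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pi <- paths[[i]]
    pj <- paths[[j]]
    k <- 1L
    while (k < min(length(pi), length(pj)) && pi[k + 1L] == pj[k + 1L])
      k <- k + 1L
    s <- 0
    if (k > 1L) for (m in seq_len(k - 1L)) s <- s + edgelen(pi[m], pi[m + 1L])
    C[i, j] <- s
  }
  C
}

# Direct dense-matrix evaluation of the Blomberg K formula from a covariance
# matrix, independent of the package's prepared/vectorized path.
k_oracle <- function(C, x) {
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Ci %*% (x - a)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

# TRUE iff two flat clusterings are the same partition (ARI = 1).
same_partition <- function(a, b) {
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  all(outer(ta, ta, "==") == outer(tb, tb, "=="))
}

# small fixed trees used across files
tree3 <- function() parse_newick("((B:0.5,C:0.5):0.5,A:1.0);")
tree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
star_tree <- function(n = 6, d = 1) {
  parse_newick(paste0("(", paste0("t", seq_len(n), ":", d, collapse = ","), ");"))
}

# tiny volume table used in the volumetrics tests
toy_volumes <- function() {
  data.frame(
    species = rep(c("sp1", "sp2"), each = 5),
    specimen = rep(c("sp1_a", "sp2_a"), each = 5),
    neuropil = rep(c("ME", "ME", "EB", "superior", "gnathal"), 2),
    side = rep(c("left", "right", "unpaired", "unpaired", "unpaired"), 2),
    volume = c(10, 12, 7, 4, 2, 20, 24, 14, 8, 4),
    stringsAsFactors = FALSE)
}
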