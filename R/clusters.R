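#' Pairwise PGLS slope matrix across neuropils
#'
#' Regresses the log relative volume of every neuropil on every other via
#' [pgls_fit()], recording the slope b(i -> j) (row i regressed on column j),
#' its SE and the adjusted R-squared. The diagonal is 1 by definition. Pairs
#' with fewer than `min_species` species after pairwise deletion are marked
#' missing.
#'
#' @param traits A `"trait_matrix"` with relative volumes, or a species x
#'   neuropil matrix of log relative volumes when `scale = "as_is"`.
#' @param C Phylogenetic covariance, or `NULL` for OLS.
#' @param scale `"log_relative"` (default: natural log of the relative
#'   volumes) or `"as_is"`.
#' @param min_species Minimum species per pair (default 4).
#' @param ridge Passed to [pgls_fit()].
#' @return An object of class `"slope_matrix"`: list with `slope`, `se`,
#'   `adj_r_squared` (neuropil x neuropil matrices) and `sd` (whitened trait
#'   SDs used for symmetrization).
#' @export
pairwise_slopes <- function(traits, C = NULL, scale = c("log_relative", "as_is"),
                            min_species = 4L, ridge = 0) {
  scale <- match.arg(scale)
  M <- if (inherits(traits, "trait_matrix")) {
    if (is.null(traits$relative))
      stop("trait matrix has no relative volumes", call. = FALSE)
    log(traits$relative)
  } else if (scale == "log_relative") log(as.matrix(traits)) else as.matrix(traits)
  q <- ncol(M)
  if (q < 3L) stop("need at least 3 neuropils", call. = FALSE)
  nm <- colnames(M)
  slope <- se <- r2 <- matrix(NA_real_, q, q, dimnames = list(nm, nm))
  diag(slope) <- 1; diag(se) <- 0; diag(r2) <- 1
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) next
      sp <- rownames(M)[stats::complete.cases(M[, c(i, j)])]
      if (length(sp) < min_species) next
      y <- stats::setNames(M[sp, i], sp)
      x <- stats::setNames(M[sp, j], sp)
      fit <- pgls_fit(y, design_matrix(x), C, ridge = ridge)
      slope[i, j] <- unname(fit$coef["logx"])
      se[i, j] <- sqrt(fit$vcov["logx", "logx"])
      r2[i, j] <- fit$adj_r_squared
    }
  }
  # whitened trait SDs (dispersion about the phylogenetic mean, C-weighted)
  # for the scale-aware symmetrization in to_distance(); with these scales
  # b(i->j) sd_j/sd_i is exactly the whitened correlation of i and j
  sds <- apply(M, 2, function(v) {
    sp <- rownames(M)[!is.na(v)]
    v <- v[!is.na(v)]
    if (is.null(C)) return(stats::sd(v))
    L <- t(chol(C[sp, sp]))
    vw <- forwardsolve(L, v)
    onew <- forwardsolve(L, rep(1, length(v)))
    mu <- sum(onew * vw) / sum(onew^2)
    sqrt(sum((vw - mu * onew)^2) / (length(v) - 1))
  })
  out <- list(slope = slope, se = se, adj_r_squared = r2, sd = sds)
  class(out) <- "slope_matrix"
  out
}

#' Convert a slope matrix into a distance matrix
#'
#' Slopes are asymmetric (b(i -> j) differs from b(j -> i) whenever trait
#' scales differ), so each pair is symmetrized on a common scale:
#' `s_ij = (b(i->j) sd_j/sd_i + b(j->i) sd_i/sd_j)/2`, which for ordinary
#' regression reduces to the correlation of the two traits. The symmetrized
#' associations are normalized to \[-1, 1\] by the maximum absolute value and
#' converted to distances `d_ij = 1 - s_ij` (strongly negatively associated
#' neuropils sit farthest apart, at distance up to 2).
#'
#' @param sm A `"slope_matrix"`.
#' @param impute_missing Replace missing cells with the row/column median of
#'   the association matrix (with a warning); `FALSE` errors on missingness.
#' @return List with `association` (normalized, symmetric) and `distance`
#'   (symmetric, zero diagonal, non-negative).
#' @export
to_distance <- function(sm, impute_missing = TRUE) {
  stopifnot(inherits(sm, "slope_matrix"))
  b <- sm$slope
  sdr <- sm$sd
  q <- nrow(b)
  s <- matrix(NA_real_, q, q, dimnames = dimnames(b))
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) { s[i, j] <- NA; next }
      terms <- c(b[i, j] * sdr[j] / sdr[i], b[j, i] * sdr[i] / sdr[j])
      s[i, j] <- mean(terms, na.rm = TRUE)
    }
  }
  if (anyNA(s[upper.tri(s)])) {
    if (!impute_missing) stop("missing associations; set impute_missing=TRUE",
                              call. = FALSE)
    nas <- sum(is.na(s[upper.tri(s)]))
    warning(nas, " missing association(s) imputed by row/column medians",
            call. = FALSE)
    for (i in seq_len(q)) for (j in seq_len(q)) {
      if (i != j && is.na(s[i, j])) {
        med <- stats::median(c(s[i, ], s[, j]), na.rm = TRUE)
        if (is.na(med)) stop("neuropil with all associations missing",
                             call. = FALSE)
        s[i, j] <- s[j, i] <- med
      }
    }
  }
  s <- (s + t(s)) / 2          # exact symmetry after imputation
  mx <- max(abs(s), na.rm = TRUE)
  if (mx > 0) s <- s / mx
  d <- 1 - s
  diag(d) <- 0
  diag(s) <- 1
  list(association = s, distance = d)
}

#' Hierarchical clustering of neuropils by scaling similarity
#'
#' Agglomerative clustering of the slope-derived distance matrix. The
#' dendrogram can be exported as Newick; flat clusters are available by
#' count `k` or cut height `h`.
#'
#' @param d Symmetric distance matrix (e.g. `to_distance(...)$distance`).
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @param k,h Optional flat-cluster count or cut height.
#' @return List with `hclust`, `newick` (character) and, when `k` or `h` is
#'   given, `clusters` (named integer vector).
#' @export
hcluster <- function(d, linkage = c("average", "complete", "ward"),
                     k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (anyNA(d) || any(!is.finite(d)))
    stop("distance matrix must be finite", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  out <- list(hclust = hc,
              newick = ape::write.tree(ape::as.phylo(hc)))
  if (!is.null(k) || !is.null(h))
    out$clusters <- stats::cutree(hc, k = k, h = h)
  out
}
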