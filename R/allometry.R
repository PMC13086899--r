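#' Phylogenetic generalized least squares
#'
#' Exact GLS under Brownian motion: residual covariance proportional to the
#' phylogenetic matrix `C`. Coefficients are
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1}X'C^{-1}y}; the residual variance uses the
#' unbiased n - p denominator,
#' \eqn{\hat\sigma^2 = (y-X\hat\beta)'C^{-1}(y-X\hat\beta)/(n-p)}, and
#' \eqn{cov(\hat\beta) = \hat\sigma^2 (X'C^{-1}X)^{-1}}. R-squared is
#' computed on the whitened scale: `1 - RSS_C/TSS_C` with `TSS_C` the
#' C-weighted residual sum of squares of the intercept-only GLS model, so
#' with `C = I` every statistic reduces to its ordinary-regression
#' counterpart.
#'
#' @param y Named numeric response (typically a natural-log volume), one
#'   value per species.
#' @param X Design matrix with rownames matching species; an intercept column
#'   must be included by the caller (see [design_matrix()]).
#' @param C Phylogenetic covariance matrix (from [vcv_matrix()]), or `NULL`
#'   for ordinary least squares.
#' @param ridge Diagonal inflation for numerically singular `C` (default 0).
#' @param sigma2_denom `"unbiased"` (n - p, default) or `"ml"` (n).
#' @return An object of class `"pgls_fit"`: list with `coef`, `vcov`,
#'   `sigma2`, `n`, `p`, `residuals` (raw), `wresiduals` (whitened),
#'   `fitted`, `r_squared`, `adj_r_squared`, `species`, `terms`.
#' @export
pgls_fit <- function(y, X, C = NULL, ridge = 0,
                     sigma2_denom = c("unbiased", "ml")) {
  sigma2_denom <- match.arg(sigma2_denom)
  X <- as.matrix(X)
  if (is.null(rownames(X)) || is.null(names(y)))
    stop("y and X must carry species names", call. = FALSE)
  keep <- names(y)[!is.na(y)]
  keep <- keep[keep %in% rownames(X)]
  if (!is.null(C)) keep <- keep[keep %in% rownames(C)]
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1L)
    stop("need at least ", p + 1L, " species for ", p, " coefficients",
         call. = FALSE)
  if (is.null(C)) C <- diag(1, n, n)
  else C <- C[keep, keep, drop = FALSE]
  if (ridge > 0) C <- C + diag(ridge, n)
  L <- tryCatch(t(chol(C)), error = function(e)
    stop("singular phylogenetic covariance; consider a positive ridge",
         call. = FALSE))
  yw <- forwardsolve(L, y)
  Xw <- forwardsolve(L, X)
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < p)
    stop("design matrix is rank deficient (confounded factors?)", call. = FALSE)
  beta <- drop(solve(qrX, crossprod(Xw, yw)))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  wresid <- yw - drop(Xw %*% beta)
  rss <- sum(wresid^2)
  sigma2 <- rss / switch(sigma2_denom, unbiased = n - p, ml = n)
  vcov <- solve(qrX) * (rss / (n - p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # intercept-only GLS baseline for R^2 on the whitened scale
  onew <- forwardsolve(L, rep(1, n))
  mu <- sum(onew * yw) / sum(onew^2)
  tss <- sum((yw - mu * onew)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  out <- list(coef = beta, vcov = vcov, sigma2 = sigma2, n = n, p = p,
              residuals = stats::setNames(resid, keep),
              wresiduals = stats::setNames(wresid, keep),
              fitted = stats::setNames(fitted, keep),
              r_squared = r2, adj_r_squared = adj, species = keep,
              terms = colnames(X))
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", x$n, "species,", x$p, "coefficients\n")
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coef, se = se))
  cat(sprintf("sigma2 = %.4g, R2 = %.3f, adj R2 = %.3f\n",
              x$sigma2, x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Build a design matrix for allometric PGLS models
#'
#' Encodes `log y ~ log x` with optional group-specific intercepts and/or
#' slopes for a binary grouping. Group coding is treatment-style: the second
#' factor level's intercept/slope offsets are separate columns, so a Wald
#' test on the offset column tests equality across groups directly.
#'
#' @param logx Named numeric predictor (natural-log reference volume).
#' @param group Optional factor/character named by species with exactly 2
#'   levels.
#' @param group_intercept,group_slope Include group offsets on the intercept
#'   and/or slope.
#' @return Design matrix with columns among `(Intercept)`, `logx`,
#'   `group<level2>`, `logx:group<level2>`.
#' @export
design_matrix <- function(logx, group = NULL, group_intercept = FALSE,
                          group_slope = FALSE) {
  sp <- names(logx)
  X <- cbind(`(Intercept)` = rep(1, length(logx)), logx = unname(logx))
  rownames(X) <- sp
  if (!is.null(group) && (group_intercept || group_slope)) {
    g <- factor(group[sp])
    if (nlevels(g) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
    ind <- as.numeric(g == levels(g)[2])
    if (group_intercept) {
      X <- cbind(X, ind)
      colnames(X)[ncol(X)] <- paste0("group", levels(g)[2])
    }
    if (group_slope) {
      X <- cbind(X, unname(logx) * ind)
      colnames(X)[ncol(X)] <- paste0("logx:group", levels(g)[2])
    }
  }
  X
}

#' Wald chi-squared test of linear hypotheses on a PGLS fit
#'
#' Tests `R beta = r` via
#' \eqn{\chi^2 = (R\hat\beta - r)'[R\,cov(\hat\beta)\,R']^{-1}(R\hat\beta - r)}
#' on `nrow(R)` degrees of freedom. With a single constraint this is the
#' square of the usual z statistic. The asymptotic chi-squared reference is
#' mildly anticonservative at small n.
#'
#' @param fit A `"pgls_fit"`.
#' @param R Constraint matrix (q x p), or a character vector of coefficient
#'   names to test against `r` individually.
#' @param r Right-hand side (length q; default 0).
#' @return List with `chisq`, `df`, `p`.
#' @export
wald_chi2 <- function(fit, R, r = 0) {
  stopifnot(inherits(fit, "pgls_fit"))
  p <- length(fit$coef)
  if (is.character(R)) {
    idx <- match(R, names(fit$coef))
    if (anyNA(idx)) stop("unknown coefficient: ",
                         paste(R[is.na(idx)], collapse = ", "), call. = FALSE)
    Rm <- matrix(0, length(idx), p)
    Rm[cbind(seq_along(idx), idx)] <- 1
    R <- Rm
  }
  R <- as.matrix(R)
  if (ncol(R) != p) stop("constraint matrix has wrong width", call. = FALSE)
  if (qr(R)$rank < nrow(R)) stop("constraints are rank deficient", call. = FALSE)
  r <- rep_len(r, nrow(R))
  d <- drop(R %*% fit$coef) - r
  V <- R %*% fit$vcov %*% t(R)
  stat <- drop(t(d) %*% solve(V, d))
  df <- nrow(R)
  list(chisq = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Slope index against an isometric null
#'
#' `si = b - b0`. For volume-on-volume regressions the isometric null slope
#' is `b0 = 1`; for volume-on-length (e.g. brain volume on wingspan) a
#' dimension-matched null of 3 is appropriate. Positive si means steeper
#' than isometric scaling. The test is the Wald chi-squared of `b = b0`.
#'
#' @param fit A `"pgls_fit"` whose design has a `logx` slope column.
#' @param b0 Null slope (default 1).
#' @return List with `si`, `b`, `se_b`, `chisq`, `df`, `p`.
#' @export
slope_index <- function(fit, b0 = 1) {
  if (!"logx" %in% names(fit$coef))
    stop("fit has no slope coefficient 'logx'", call. = FALSE)
  b <- unname(fit$coef["logx"])
  test <- wald_chi2(fit, "logx", r = b0)
  list(si = b - b0, b = b, se_b = sqrt(fit$vcov["logx", "logx"]),
       chisq = test$chisq, df = test$df, p = test$p)
}

#' Grade-shift analysis between two ecological groups
#'
#' Two-step procedure. Step 1 fits the interaction model
#' `log y = log a_g + b_g log x` (group-specific intercept and slope) and
#' tests slope equality by Wald chi-squared. Step 2, only when the slopes are
#' not significantly different at `alpha`: refit with a common slope,
#' `log y = log a_g + b log x`, and report the grade-shift index
#' `gsi = a_1/a_2 - 1 = exp(log a_1 - log a_2) - 1` with its intercept-
#' equality test. When the slopes differ, the intercept comparison is
#' meaningless and `gsi` is reported `NA` with `gsi_valid = FALSE`.
#'
#' Group 1 is the *first* level of `factor(groups)` (alphabetical unless the
#' caller supplies a factor), so gsi > 0 means systematically larger volumes
#' in group 1.
#'
#' @param y Named numeric response (natural-log volume).
#' @param logx Named numeric predictor (natural-log reference volume).
#' @param groups Named character/factor with exactly 2 levels.
#' @param C Phylogenetic covariance, or `NULL` for OLS.
#' @param alpha Significance level of the slope-equality gate.
#' @param ridge Passed to [pgls_fit()].
#' @return List with `gsi`, `gsi_valid`, `slope_diff` (b1 - b2),
#'   `chisq_slope`, `p_slope`, `chisq_intercept`, `p_intercept`, `b_common`,
#'   `se_gsi_log` (SE of the log intercept difference), `n`, `groups`
#'   (level names, group 1 first), and the two fits.
#' @export
grade_shift <- function(y, logx, groups, C = NULL, alpha = 0.05, ridge = 0) {
  sp <- intersect(names(y)[!is.na(y)], names(logx))
  g <- factor(unlist(groups)[sp])
  if (nlevels(g) != 2L) stop("groups must have exactly 2 levels", call. = FALSE)
  if (min(table(g)) < 3L)
    stop("each group needs at least 3 species", call. = FALSE)
  names(g) <- sp
  X_int <- design_matrix(logx[sp], g, group_intercept = TRUE,
                         group_slope = TRUE)
  fit_int <- pgls_fit(y[sp], X_int, C, ridge = ridge)
  slope_col <- grep("^logx:group", names(fit_int$coef), value = TRUE)
  test_slope <- wald_chi2(fit_int, slope_col)
  # offset columns code level 2, so group1 - group2 = -offset
  slope_diff <- -unname(fit_int$coef[slope_col])

  out <- list(slope_diff = slope_diff, chisq_slope = test_slope$chisq,
              p_slope = test_slope$p, groups = levels(g),
              n = fit_int$n, fit_interaction = fit_int)
  if (test_slope$p < alpha) {
    out$gsi <- NA_real_
    out$gsi_valid <- FALSE
    out$chisq_intercept <- NA_real_
    out$p_intercept <- NA_real_
    out$b_common <- NA_real_
    out$se_gsi_log <- NA_real_
    out$fit_common <- NULL
    return(out)
  }
  X_com <- design_matrix(logx[sp], g, group_intercept = TRUE,
                         group_slope = FALSE)
  fit_com <- pgls_fit(y[sp], X_com, C, ridge = ridge)
  int_col <- grep("^group", names(fit_com$coef), value = TRUE)
  test_int <- wald_chi2(fit_com, int_col)
  dlog <- -unname(fit_com$coef[int_col])   # log a1 - log a2
  out$gsi <- exp(dlog) - 1
  out$gsi_valid <- TRUE
  out$chisq_intercept <- test_int$chisq
  out$p_intercept <- test_int$p
  out$b_common <- unname(fit_com$coef["logx"])
  out$se_gsi_log <- sqrt(fit_com$vcov[int_col, int_col])
  out$fit_common <- fit_com
  out
}

#' Leverage screen of a PGLS fit
#'
#' Each species' share of the total absolute whitened residual,
#' `|e_i| / sum |e|`; species above the mean + 2 SD of these normalized
#' values are flagged as exerting disproportionate influence. A zero residual
#' vector yields all-zero statistics and no flags.
#'
#' @param fit A `"pgls_fit"`.
#' @return Data.frame with `species`, `normalized_residual`, `flagged`.
#' @export
leverage_screen <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  a <- abs(fit$wresiduals)
  tot <- sum(a)
  stat <- if (tot > 0) a / tot else rep(0, length(a))
  cut <- mean(stat) + 2 * stats::sd(stat)
  data.frame(species = fit$species, normalized_residual = unname(stat),
             flagged = unname(stat > cut & tot > 0),
             stringsAsFactors = FALSE)
}

#' Two-factor PGLS robustness model
#'
#' Fits a model with both binary ecological factors (e.g. activity period and
#' migratory status) on the intercept and the slope, plus their intercept
#' interaction, and reports Wald chi-squared tests for each factor's
#' intercept and slope terms and the interaction. Perfectly confounded
#' factors surface as a rank-deficiency error rather than a silent drop.
#'
#' @param y Named numeric response (natural-log volume).
#' @param logx Named numeric predictor.
#' @param factor1,factor2 Named 2-level groupings.
#' @param C Phylogenetic covariance, or `NULL`.
#' @param ridge Passed to [pgls_fit()].
#' @return List with `fit` and a data.frame `tests` (term, chisq, df, p).
#' @export
two_factor_pgls <- function(y, logx, factor1, factor2, C = NULL, ridge = 0) {
  sp <- intersect(names(y)[!is.na(y)], names(logx))
  f1 <- factor(unlist(factor1)[sp])
  f2 <- factor(unlist(factor2)[sp])
  if (nlevels(f1) != 2L || nlevels(f2) != 2L)
    stop("both factors must have exactly 2 levels", call. = FALSE)
  i1 <- as.numeric(f1 == levels(f1)[2])
  i2 <- as.numeric(f2 == levels(f2)[2])
  X <- cbind(`(Intercept)` = 1, logx = unname(logx[sp]),
             f1 = i1, f2 = i2,
             `logx:f1` = unname(logx[sp]) * i1,
             `logx:f2` = unname(logx[sp]) * i2,
             `f1:f2` = i1 * i2)
  rownames(X) <- sp
  fit <- pgls_fit(y[sp], X, C, ridge = ridge)
  tests <- do.call(rbind, lapply(
    c(f1_intercept = "f1", f2_intercept = "f2",
      f1_slope = "logx:f1", f2_slope = "logx:f2",
      interaction = "f1:f2"),
    function(term) {
      t <- wald_chi2(fit, term)
      data.frame(chisq = t$chisq, df = t$df, p = t$p)
    }))
  tests <- cbind(term = rownames(tests), tests, stringsAsFactors = FALSE)
  rownames(tests) <- NULL
  list(fit = fit, tests = tests)
}
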