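# fixed study-scale tree shared by the Monte-Carlo checks
fixed_tree15 <- simulate_tree(15, seed = 2024)
C15 <- vcv_matrix(fixed_tree15)

# log-log allometric data with BM residuals on the fixed tree
sim_reg <- function(b = 1, a = 0, resid_sigma2 = 0.05, group_int = 0,
                    group_slope = 0, groups = NULL) {
  x <- simulate_bm(fixed_tree15, 0.5, log(2e7))
  e <- simulate_bm(fixed_tree15, resid_sigma2, 0)
  sp <- fixed_tree15$tip.label
  off_i <- off_b <- rep(0, length(sp))
  if (!is.null(groups)) {
    g1 <- groups[sp] == levels(factor(groups))[1]
    off_i[g1] <- group_int
    off_b[g1] <- group_slope
  }
  y <- a + off_i + (b + off_b) * x + e
  list(y = y, x = x)
}

alt_groups <- stats::setNames(rep(c("g1", "g2"), length.out = 15),
                              fixed_tree15$tip.label)

test_that("PGLS with identity covariance equals ordinary least squares", {
  set.seed(1)
  sp <- paste0("s", 1:12)
  x <- stats::setNames(rnorm(12), sp)
  y <- stats::setNames(2 + 0.8 * x + rnorm(12, 0, 0.3), sp)
  fit <- pgls_fit(y, design_matrix(x), C = NULL)
  ref <- lm(y ~ x)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(coef(summary(ref))[, "Std. Error"]), tolerance = 1e-8)
  expect_equal(fit$sigma2, summary(ref)$sigma^2, tolerance = 1e-8)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-8)
  expect_equal(fit$adj_r_squared, summary(ref)$adj.r.squared, tolerance = 1e-8)
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  # ultrametric tree: corBrownian is a correlation structure, so equality
  # with covariance-weighted GLS requires equal tip depths
  set.seed(6)
  tr <- ape::rcoal(10)
  x <- simulate_bm(tr, 1, 0)
  y <- 1 + 0.5 * x + simulate_bm(tr, 0.2, 0)
  fit <- pgls_fit(y, design_matrix(x), vcv_matrix(tr))
  df <- data.frame(y = y, x = x, sp = names(y))
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(ref$varBeta))), tolerance = 1e-6)
})

test_that("a perfectly linear response is fit exactly", {
  sp <- paste0("s", 1:8)
  x <- stats::setNames(1:8 / 2, sp)
  y <- stats::setNames(3 + 2 * x, sp)
  fit <- pgls_fit(y, design_matrix(x), C = NULL)
  expect_equal(unname(fit$coef), c(3, 2), tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-15)
})

test_that("pgls_fit validates its inputs", {
  x <- stats::setNames(rnorm(2), paste0("s", 1:2))
  y <- x
  expect_error(pgls_fit(y, design_matrix(x)), "at least")
  sp <- paste0("s", 1:6)
  x <- stats::setNames(rnorm(6), sp)
  X <- cbind(design_matrix(x), dup = unname(x))   # collinear column
  expect_error(pgls_fit(stats::setNames(rnorm(6), sp), X, NULL),
               "rank deficient")
})

test_that("PGLS slope estimation is unbiased on BM data", {
  set.seed(14)
  bhat <- sapply(1:500, function(i) {
    d <- sim_reg(b = 1.3)
    unname(pgls_fit(d$y, design_matrix(d$x), C15)$coef["logx"])
  })
  expect_gt(mean(bhat), 1.28)
  expect_lt(mean(bhat), 1.32)
})

test_that("Wald chi-squared identities hold", {
  set.seed(3)
  d <- sim_reg(b = 1)
  fit <- pgls_fit(d$y, design_matrix(d$x), C15)
  # constraint exactly met at the estimate
  t0 <- wald_chi2(fit, "logx", r = unname(fit$coef["logx"]))
  expect_equal(t0$chisq, 0, tolerance = 1e-12)
  expect_equal(t0$p, 1)
  # single constraint equals the squared z statistic
  b <- unname(fit$coef["logx"]); se <- sqrt(fit$vcov["logx", "logx"])
  t1 <- wald_chi2(fit, "logx", r = 1)
  expect_equal(t1$chisq, ((b - 1) / se)^2, tolerance = 1e-10)
  expect_error(wald_chi2(fit, rbind(c(0, 1), c(0, 2))), "rank deficient")
  expect_error(wald_chi2(fit, "nope"), "unknown coefficient")
})

test_that("Wald slope test has near-nominal type-I error at n = 15", {
  set.seed(10)
  rej <- sapply(1:1000, function(i) {
    d <- sim_reg(b = 1)
    fit <- pgls_fit(d$y, design_matrix(d$x), C15)
    wald_chi2(fit, "logx", r = 1)$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.09)
})

test_that("slope index arithmetic and shallow-slope power", {
  set.seed(30)
  d <- sim_reg(b = 1)
  fit <- pgls_fit(d$y, design_matrix(d$x), C15)
  si <- slope_index(fit, b0 = unname(fit$coef["logx"]))
  expect_equal(si$si, 0)
  si2 <- slope_index(fit, b0 = unname(fit$coef["logx"]) - 0.2)
  expect_equal(si2$si, 0.2, tolerance = 1e-12)

  # planted shallow scaling (b = 0.7) is detected as si < 0 most of the time
  set.seed(31)
  hits <- sapply(1:200, function(i) {
    d <- sim_reg(b = 0.7)
    f <- pgls_fit(d$y, design_matrix(d$x), C15)
    s <- slope_index(f, 1)
    s$si < 0 && s$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("grade shift on identical groups is near zero and valid", {
  set.seed(12)
  d <- sim_reg(b = 1)
  gs <- grade_shift(d$y, d$x, alt_groups, C15)
  expect_true(gs$gsi_valid)
  expect_lt(abs(log(1 + gs$gsi)), 3 * gs$se_gsi_log)   # compatible with 0
  expect_gt(gs$p_slope, 0.05)
})

test_that("planted intercept ratio 2 is recovered as gsi near 1", {
  set.seed(55)
  out <- t(sapply(1:200, function(i) {
    d <- sim_reg(b = 1, group_int = log(2), groups = alt_groups)
    gs <- grade_shift(d$y, d$x, alt_groups, C15)
    c(gsi = gs$gsi, valid = gs$gsi_valid)
  }))
  gsi <- out[out[, "valid"] == 1, "gsi"]
  expect_gt(length(gsi), 150)          # slope gate rarely trips under the null
  mc_se <- stats::sd(gsi) / sqrt(length(gsi))
  expect_lt(abs(mean(gsi) - 1), 2 * mc_se + 0.02)
})

test_that("planted slope differences are detected and invalidate gsi", {
  set.seed(56)
  res <- sapply(1:200, function(i) {
    d <- sim_reg(b = 0.8, group_slope = 0.6, groups = alt_groups)
    gs <- grade_shift(d$y, d$x, alt_groups, C15)
    c(sig = gs$p_slope < 0.05, invalid = !gs$gsi_valid)
  })
  expect_gte(mean(res["sig", ]), 0.8)
  expect_true(all(res["sig", ] == res["invalid", ]))
})

test_that("grade shift requires 3 species per group", {
  d <- sim_reg(b = 1)
  small <- stats::setNames(c(rep("g1", 2), rep("g2", 13)),
                           fixed_tree15$tip.label)
  expect_error(grade_shift(d$y, d$x, small, C15), "at least 3")
})

test_that("leverage screen flags only disproportionate residuals", {
  sp <- paste0("s", 1:15)
  fit <- structure(list(
    wresiduals = stats::setNames(c(rep(0.1, 14), 1.0), sp),
    species = sp), class = "pgls_fit")
  out <- leverage_screen(fit)
  expect_identical(out$species[out$flagged], "s15")

  fit$wresiduals[] <- 0.2              # all equal: nothing flagged
  expect_false(any(leverage_screen(fit)$flagged))

  fit$wresiduals[] <- 0                # degenerate zero-residual fit
  out0 <- leverage_screen(fit)
  expect_false(any(out0$flagged))
  expect_equal(out0$normalized_residual, rep(0, 15))
})

test_that("two-factor PGLS flags confounding and separates the factors", {
  d <- sim_reg(b = 1)
  confounded <- alt_groups
  expect_error(two_factor_pgls(d$y, d$x, confounded, confounded, C15),
               "rank deficient")

  # generated with an activity effect only: migration terms stay quiet
  f2 <- stats::setNames(rep(c("m", "m", "n", "n"), length.out = 15),
                        fixed_tree15$tip.label)
  set.seed(77)
  quiet <- sapply(1:200, function(i) {
    d <- sim_reg(b = 1, group_int = 0.8, groups = alt_groups)
    tf <- two_factor_pgls(d$y, d$x, alt_groups, f2, C15)
    all(tf$tests$p[tf$tests$term %in% c("f2_intercept", "f2_slope")] > 0.05)
  })
  expect_gte(mean(quiet), 0.9)
})

test_that("gsi is invariant to log base and uniform rescaling", {
  set.seed(9)
  d <- sim_reg(b = 1, group_int = log(2), groups = alt_groups)
  gs <- grade_shift(d$y, d$x, alt_groups, C15)
  # base change: divide both axes by log(10); intercept ratio is unchanged
  gs10 <- grade_shift(d$y / log(10), d$x / log(10), alt_groups, C15)
  expect_equal(exp(log(1 + gs10$gsi) * log(10)) - 1, gs$gsi,
               tolerance = 1e-10)
  # uniform rescaling of raw x and y (additive shift on the log scale)
  gsk <- grade_shift(d$y + log(3), d$x + log(7), alt_groups, C15)
  expect_equal(gsk$gsi, gs$gsi, tolerance = 1e-10)
})
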