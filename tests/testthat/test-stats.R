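test_that("the OLS core solves exact and random systems", {
  x <- 1:10
  f <- fit_ols(2 * x, cbind(1, x))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-10)
  fconst <- fit_ols(rep(3, 10), cbind(1, x))
  expect_equal(unname(fconst$coefficients), c(3, 0), tolerance = 1e-10)
  set.seed(1)
  for (i in 1:10) {
    n <- 25
    X <- cbind(1, matrix(stats::rnorm(n * 3), n))
    y <- stats::rnorm(n)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1] # normal equations
    f <- fit_ols(y, X)
    expect_equal(unname(f$coefficients), unname(beta_oracle),
                 tolerance = 1e-8)
    expect_lt(max(abs(t(X) %*% f$residuals)), 1e-8)
  }
  X2 <- cbind(a = rep(1, 10), b = x, c = 2 * x)
  expect_error(fit_ols(stats::rnorm(10), X2), "collinear column.*c")
})

test_that("partial correlation residualizes, tests and matches the precision-matrix oracle", {
  set.seed(2)
  n <- 80
  x <- stats::rnorm(n)
  y <- stats::rnorm(n)
  # no covariates: plain Pearson
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$pr, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$df, n - 2)
  expect_equal(pc0$p, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  # y equal to a covariate: adjustment kills the association
  z <- stats::rnorm(n)
  pcz <- partial_correlation(x, z + 1e-8 * stats::rnorm(n),
                             covariates = cbind(z = z))
  expect_lt(abs(pcz$pr), 0.05)
  # planted partial structure vs inverting the full correlation matrix
  for (i in 1:10) {
    z2 <- matrix(stats::rnorm(n * 2), n)
    xx <- z2[, 1] + 0.5 * stats::rnorm(n)
    yy <- 0.6 * xx + z2[, 2] + stats::rnorm(n)
    pc <- partial_correlation(xx, yy, covariates = z2)
    expect_equal(pc$pr, oracle_partial_cor(xx, yy, z2), tolerance = 1e-10)
  }
  # symmetry and affine invariance
  zc <- matrix(stats::rnorm(n * 2), n)
  a1 <- partial_correlation(x, y, zc)$pr
  expect_equal(partial_correlation(y, x, zc)$pr, a1, tolerance = 1e-12)
  expect_equal(partial_correlation(3 * x - 1, -2 * y + 5, zc)$pr, -a1,
               tolerance = 1e-10)
  expect_error(partial_correlation(rep(1, n), y), "zero residual")
})

test_that("Benjamini-Hochberg adjustment matches worked examples", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r1$p_adjusted, rep(0.04, 4), tolerance = 1e-12)
  r2 <- fdr_bh(c(0.005, 0.03))
  expect_equal(r2$p_adjusted, c(0.01, 0.03), tolerance = 1e-12)
  expect_equal(fdr_bh(0.2)$p_adjusted, 0.2)
  # monotone in ranks
  set.seed(3)
  p <- stats::runif(30)
  adj <- fdr_bh(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_bh(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("one-way ANOVA reduces to the pooled t-test and handles flat data", {
  set.seed(4)
  g2 <- rep(c("a", "b"), each = 12)
  v2 <- stats::rnorm(24) + (g2 == "b") * 0.8
  an <- oneway_anova(v2, g2)
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
  # identical group means => F = 0, p = 1
  flat <- oneway_anova(rep(c(1, 2), 6), rep(c("a", "b"), each = 6))
  expect_equal(flat$F, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1, tolerance = 1e-12)
  expect_error(oneway_anova(1:5, c("a", "a", "a", "a", "b")), "degenerate")
})

test_that("Bonferroni post hoc multiplies by the number of pairs and caps at 1", {
  set.seed(5)
  g <- rep(c("a", "b", "c"), each = 10)
  v <- stats::rnorm(30) + (g == "c") * 2
  ph <- bonferroni_posthoc(v, g)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adjusted >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_adjusted <= 1))
  raw_ab <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)$p.value
  expect_equal(ph$p_adjusted[ph$group1 == "a" & ph$group2 == "b"],
               min(1, raw_ab * 3), tolerance = 1e-12)
  same <- bonferroni_posthoc(rep(c(1, 2, 3), 4), rep(c("a", "b"), each = 6))
  expect_equal(same$p_adjusted, 1)
})

test_that("mediation recovers a noise-free chain exactly and obeys c = c' + ab", {
  x <- 1:20
  m <- 2 * x
  y <- 3 * m
  fit <- mediate(x, m, y, n_boot = 200, rng_seed = 1)
  expect_equal(fit$a, 2, tolerance = 1e-8)
  expect_equal(fit$b, 3, tolerance = 1e-8)
  expect_equal(fit$c, 6, tolerance = 1e-8)
  expect_equal(fit$c_prime, 0, tolerance = 1e-8)
  expect_equal(fit$indirect, 6, tolerance = 1e-8)
  expect_equal(fit$boot_ci, c(6, 6), tolerance = 1e-6)
  expect_true(fit$significant)

  # identity on noisy data, with and without covariates
  set.seed(6)
  for (i in 1:10) {
    n <- 50
    z <- matrix(stats::rnorm(n * 2), n)
    xx <- stats::rnorm(n)
    mm <- 0.5 * xx + stats::rnorm(n)
    yy <- 0.4 * mm + 0.3 * xx + z %*% c(0.2, -0.1) + stats::rnorm(n)
    fit <- mediate(xx, mm, as.numeric(yy), covariates = z, n_boot = 100,
                   rng_seed = i)
    expect_equal(fit$c, fit$c_prime + fit$a * fit$b, tolerance = 1e-8)
  }
})

test_that("the mediation bootstrap is reproducible and tightens with draws", {
  set.seed(7)
  n <- 60
  x <- stats::rnorm(n)
  m <- 0.5 * x + stats::rnorm(n)
  y <- 0.4 * m + stats::rnorm(n)
  f1 <- mediate(x, m, y, n_boot = 500, rng_seed = 42)
  f2 <- mediate(x, m, y, n_boot = 500, rng_seed = 42)
  expect_identical(f1$boot_ci, f2$boot_ci)
  f3 <- mediate(x, m, y, n_boot = 500, rng_seed = 43)
  expect_false(identical(f1$boot_ci, f3$boot_ci))
})

test_that("categorical exposures produce one relative effect per level", {
  set.seed(8)
  n <- 90
  g <- factor(rep(c("B", "P", "R"), each = n / 3))
  m <- 0.5 * (g == "P") + 1.0 * (g == "R") + stats::rnorm(n, 0, 0.3)
  y <- 0.6 * m + stats::rnorm(n, 0, 0.3)
  fits <- mediate(g, m, y, n_boot = 300, rng_seed = 9)
  expect_named(fits, c("P", "R"))
  expect_equal(fits$P$c, fits$P$c_prime + fits$P$a * fits$P$b,
               tolerance = 1e-8)
  expect_gt(fits$R$a, fits$P$a) # larger planted contrast for level R
  expect_true(fits$R$significant)
})

test_that("association screens run per family with exposure-specific engines", {
  co <- simulate_cohort(sim_config(n_subjects = 60L, n_taxa = 30L,
                                   depth = 5000L), rng_seed = 12)
  df <- co$cohort
  set.seed(13)
  df$met1 <- stats::rnorm(60)
  df$met2 <- df$shannon * 0.8 + stats::rnorm(60, 0, 0.3)
  scr <- association_screen(df, c("met1", "met2"), "shannon")
  expect_equal(nrow(scr), 2)
  expect_true(all(c("estimate", "p", "p_adjusted", "significant")
                  %in% names(scr)))
  expect_true(scr$significant[scr$metric == "met2"])
  expect_true(all(scr$p_adjusted >= scr$p - 1e-15))

  scr_ent <- association_screen(df, c("met1", "met2"), "enterotype")
  expect_equal(nrow(scr_ent), 2)
  expect_type(attr(scr_ent, "posthoc"), "list")

  expect_error(association_screen(df, "nope", "shannon"), "unknown column")
})
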