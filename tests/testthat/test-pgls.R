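test_that("GLS with identity covariance reproduces ordinary least squares", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n)
    g <- gls_fit(X, y, diag(n))
    ref <- lm(y ~ X[, 2] + X[, 3])
    expect_equal(unname(g$beta), unname(coef(ref)), tolerance = 1e-10)
    expect_equal(unname(g$se), unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)
    expect_equal(unname(g$p_value), unname(summary(ref)$coefficients[, 4]), tolerance = 1e-10)
  }
})

test_that("GLS maximizes the multivariate-normal likelihood on a toy problem", {
  # independent oracle: direct numeric maximization over (beta, log sigma2)
  set.seed(2)
  tr <- rand_coal_tree(4, 8)
  C0 <- mrca_depth_matrix(tr)
  X <- cbind(1, c(0.2, -1, 0.5, 1.3))
  y <- c(3.1, 1.2, 2.0, 4.4)
  g <- gls_fit(X, y, C0)
  nll <- function(par) {
    -dmvn_log(y, as.numeric(X %*% par[1:2]), exp(par[3]) * C0)
  }
  opt <- optim(c(0, 0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(g$beta), opt$par[1:2], tolerance = 1e-5)
  expect_equal(g$sigma2, exp(opt$par[3]), tolerance = 1e-5)
  expect_equal(g$loglik, -opt$value, tolerance = 1e-6)
})

test_that("a perfect fit is flagged as degenerate instead of reporting infinite likelihood blindly", {
  X <- cbind(1, 1:6)
  y <- as.numeric(X %*% c(2, 0.5))
  g <- gls_fit(X, y, diag(6))
  expect_true(g$degenerate)
  expect_equal(unname(g$beta), c(2, 0.5), tolerance = 1e-10)
  expect_error(gls_fit(cbind(1, 1:6, 2 * (1:6)), y, diag(6)), "rank")
})

test_that("BM fit agrees with an established GLS implementation", {
  st <- fixture_study()
  d <- prepare_analysis(st$morph)
  f <- pgls_fit(d, st$tree, mantle_formula, "BM")
  dd <- as.data.frame(d)
  rownames(dd) <- dd$species
  ref <- nlme::gls(mantle_kgs ~ wing_loading_std + abs_latitude, data = dd,
                   correlation = ape::corBrownian(1, st$tree, form = ~species),
                   method = "ML")
  expect_equal(unname(f$fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("lambda endpoints coincide with the NP and BM models", {
  st <- fixture_study()
  d <- prepare_analysis(st$morph)
  np <- pgls_fit(d, st$tree, mantle_formula, "NP")
  bm <- pgls_fit(d, st$tree, mantle_formula, "BM")
  X <- np$X; y <- np$y
  tmat <- bm$tmat
  at0 <- gls_fit(X, y, lambda_transform(tmat, 0))
  at1 <- gls_fit(X, y, lambda_transform(tmat, 1))
  expect_equal(at0$beta, np$fit$beta, tolerance = 1e-8)
  expect_equal(at0$loglik, np$loglik, tolerance = 1e-8)
  expect_equal(at1$beta, bm$fit$beta, tolerance = 1e-8)
  expect_equal(at1$loglik, bm$loglik, tolerance = 1e-8)
  # nesting: the profiled lambda fit can never do worse than BM
  lam <- pgls_fit(d, st$tree, mantle_formula, "LAMBDA")
  expect_gte(lam$loglik, bm$loglik - 1e-8)
  expect_gte(lam$loglik, np$loglik - 1e-8)
})

test_that("the large-alpha OU limit reproduces the non-phylogenetic coefficients", {
  st <- fixture_study()
  d <- prepare_analysis(st$morph)
  np <- pgls_fit(d, st$tree, mantle_formula, "NP")
  h <- tree_height(st$tree)
  big <- gls_fit(np$X, np$y,
                 larimorph:::pgls_structure("OU", 1e3 / h, np$tmat, np$dmat))
  expect_equal(big$beta, np$fit$beta, tolerance = 1e-4)
})

test_that("the OU optimizer beats a dense grid over the concentrated likelihood", {
  st <- fixture_study()
  d <- prepare_analysis(st$morph)
  ou <- pgls_fit(d, st$tree, mantle_formula, "OU")
  h <- tree_height(st$tree)
  grid <- exp(seq(log(1e-8 / h), log(1e3 / h), length.out = 100))
  grid_ll <- vapply(grid, ou$profile_ll, numeric(1))
  expect_gte(ou$loglik, max(grid_ll) - 1e-6)
  expect_equal(ou$aic, 2 * ou$k - 2 * ou$loglik)
  expect_equal(ou$k, 5)  # 3 coefficients + sigma2 + alpha
})

test_that("likelihood-ratio tests recover the printed model-selection p-values", {
  # log-likelihoods as printed for the four-model mantle comparison
  ou_np <- lrt(-128.21, -125.15)
  expect_equal(ou_np$statistic, 6.12, tolerance = 1e-8)
  expect_equal(round(ou_np$p_value, 3), 0.013)
  lam_np <- lrt(-128.21, -127.09)
  expect_equal(lam_np$statistic, 2.24, tolerance = 1e-8)
  expect_equal(round(lam_np$p_value, 3), 0.134)
  same <- lrt(-100, -100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("half-life is ln(2) over the selection strength", {
  expect_equal(round(half_life(27.13), 3), 0.026)
  expect_equal(half_life(log(2)), 1)
  expect_lt(half_life(1e6), 1e-5)
  expect_error(half_life(0), "alpha")
})

test_that("lambda profile CI brackets the MLE with the 1.92 likelihood drop", {
  # strong phylogenetic signal: Brownian traits on a 50-tip tree
  st <- fixture_study()
  tr <- st$tree
  X <- cbind("(Intercept)" = rep(1, 50))
  y <- simulate_traits(tr, X, "BM", list(beta = 5, sigma2 = 300), seed = 4)
  d <- tibble::tibble(species = tr$tip.label, trait = as.numeric(y))
  f <- pgls_fit(d, tr, trait ~ 1, "LAMBDA")
  ci <- lambda_profile_ci(f)
  expect_gt(ci$lower, 0)
  expect_lte(ci$lower, f$param)
  expect_gte(ci$upper, f$param)
  # the profile drops by qchisq(.95, 1)/2 at an interior endpoint
  drop <- f$loglik - f$profile_ll(ci$lower)
  expect_equal(drop, qchisq(0.95, 1) / 2, tolerance = 0.01)
})

test_that("lambda likelihood-ratio test holds its size under non-phylogenetic data", {
  st <- fixture_study()
  tr <- st$tree
  tmat <- mrca_depth_matrix(tr)
  depths <- diag(tmat)
  dmat <- outer(depths, depths, "+") - 2 * tmat
  X <- cbind(1, rnorm(50))
  set.seed(505)
  p_vals <- replicate(500, {
    y <- rnorm(50)
    np <- larimorph:::fit_pgls_core(X, y, tmat, dmat, "NP")
    lam <- larimorph:::fit_pgls_core(X, y, tmat, dmat, "LAMBDA")
    stat <- max(0, 2 * (lam$loglik - np$loglik))
    pchisq(stat, 1, lower.tail = FALSE)
  })
  rate <- mean(p_vals < 0.05)
  # boundary at lambda = 0 makes the plain chi-square test conservative
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("OU regression recovers the generating wing-loading effect with small bias", {
  st <- fixture_study()
  tr <- st$tree
  d0 <- prepare_analysis(st$morph)
  X <- cbind(1, d0$wing_loading_std, d0$abs_latitude)
  beta_true <- c(10.4, 1.2, -0.07)
  tmat <- mrca_depth_matrix(tr)
  depths <- diag(tmat)
  dmat <- outer(depths, depths, "+") - 2 * tmat
  est <- vapply(1:200, function(i) {
    y <- simulate_traits(tr, X, "OU",
                         list(beta = beta_true, sigma2 = 595.77, alpha = 27.13),
                         seed = 7000 + i)
    larimorph:::fit_pgls_core(X, as.numeric(y), tmat, dmat, "OU")$fit$beta[2]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.2), 0.15)
})

test_that("OLS summary and Pearson correlation match closed forms", {
  ex <- suppressWarnings(ols_fit(c(0, 1, 2, 3), c(1, 3, 5, 7)))  # lm warns on a perfect fit
  expect_equal(ex$slope, 2)
  expect_equal(ex$r2, 1)
  flat <- ols_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0, tolerance = 1e-12)
  expect_error(ols_fit(rep(1, 5), rnorm(5)), "constant")
  x <- rnorm(20)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(rep(1, 4), rnorm(4)), "Constant")
})

test_that("tidy and glance expose the fit in broom style", {
  st <- fixture_study()
  d <- prepare_analysis(st$morph)
  f <- pgls_fit(d, st$tree, mantle_formula, "OU")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(f)
  expect_equal(gl$model, "OU")
  expect_equal(gl$AIC, f$aic)
})
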