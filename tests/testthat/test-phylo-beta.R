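test_that("squeeze maps only the boundary values inward", {
  expect_equal(squeeze(0), 1e-4)
  expect_equal(squeeze(1), 0.9999)
  expect_equal(squeeze(0.84), 0.84)
  expect_equal(squeeze(c(0, 0.3, 1, NA)), c(1e-4, 0.3, 0.9999, NA))
  expect_error(squeeze(1.2), "\\[0, 1\\]")
  expect_error(squeeze(-0.1), "\\[0, 1\\]")
})

test_that("with no random effect the fit matches an independent beta-regression ML", {
  set.seed(31)
  n <- 30
  X <- cbind(1, rnorm(n), runif(n, 0, 60))
  beta_true <- c(1.2, 0.4, -0.03)
  mu <- plogis(as.numeric(X %*% beta_true))
  y <- squeeze(rbeta(n, mu * 25, (1 - mu) * 25))
  C <- diag(n)
  fit <- beta_laplace_ml(X, y, C, sigma2_phylo = 0)
  # oracle: direct numeric ML of the plain beta likelihood, different
  # optimizer route and start
  nll <- function(par) {
    m <- plogis(as.numeric(X %*% par[1:3]))
    -sum(dbeta(y, m * exp(par[4]), (1 - m) * exp(par[4]), log = TRUE))
  }
  opt <- optim(c(0, 0, 0, log(10)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14, ndeps = rep(1e-6, 4)))
  expect_equal(fit$coefficients$estimate, opt$par[1:3], tolerance = 1e-4)
  expect_equal(fit$phi, exp(opt$par[4]), tolerance = 1e-4)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("the Laplace marginal likelihood is exact when the random effect vanishes", {
  set.seed(32)
  n <- 20
  X <- cbind(1, rnorm(n))
  y <- squeeze(rbeta(n, 8, 3))
  C <- phylo_corr(rand_coal_tree(n, 5))
  fit <- beta_laplace_ml(X, y, C, sigma2_phylo = 0)
  mu <- plogis(as.numeric(X %*% fit$coefficients$estimate))
  plain <- sum(dbeta(y, mu * fit$phi, (1 - mu) * fit$phi, log = TRUE))
  expect_identical(fit$loglik, -(-plain))
})

test_that("identical responses concentrate the fit at the observed logit", {
  n <- 12
  X <- cbind("(Intercept)" = rep(1, n))
  y <- rep(0.7, n)
  fit <- beta_laplace_ml(X, y, diag(n), sigma2_phylo = NULL)
  expect_equal(fit$coefficients$estimate[1], qlogis(0.7), tolerance = 1e-3)
  expect_gt(fit$phi, 100)
  expect_lt(fit$sigma2_phylo, 1e-3)
})

test_that("predictions invert the logit exactly and agree with the ratio scale", {
  b <- c(1.65, 0.34, -0.05)
  p <- predict_proportion(b, wl_std = 1.3, abs_lat = 22)
  expect_equal(qlogis(p), b[1] + b[2] * 1.3 + b[3] * 22, tolerance = 1e-10)
  # ratio-to-proportion at baseline: r / (1 + r) equals the prediction
  r <- coef_to_ratio(b[1])
  expect_equal(r / (1 + r), predict_proportion(b, 0, 0), tolerance = 1e-12)
  expect_equal(coef_to_ratio(0), 1)
  # monotone in a positive coefficient's predictor
  expect_true(all(diff(predict_proportion(b, seq(-2, 2, 0.5), 10)) > 0))
  expect_true(all(diff(predict_proportion(b, 0, c(0, 20, 40))) < 0))
})

test_that("a phylogenetic fit on generator output recovers plausible structure", {
  st <- fixture_study()
  d <- prepare_analysis(st$morph, c("wing_loading", "abs_latitude", "wingtip_black"))
  fit <- fit_phylo_beta(d, st$tree, wingtip_black ~ wing_loading_std + abs_latitude)
  expect_true(fit$converged)
  expect_gt(fit$phi, 0)
  expect_gte(fit$sigma2_phylo, 0)
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(tidy(fit)$ratio, exp(tidy(fit)$estimate))
  # latitude effect is strongly negative by construction
  expect_lt(tidy(fit)$estimate[3], 0)
})

test_that("quantile residuals are uniform under the fitted model and detect gross misfit", {
  set.seed(33)
  n <- 30
  tr <- rand_coal_tree(n, 12)
  X <- cbind(1, rnorm(n))
  y <- squeeze(simulate_beta_traits(tr, X,
                                    list(beta = c(1.2, 0.3), phi = 25, sigma2_phylo = 0.3),
                                    seed = 90))
  fit <- beta_laplace_ml(X, y, phylo_corr(tr), sigma2_phylo = NULL)
  qr <- quantile_residuals(fit, n_sim = 250, seed = 2)
  expect_true(all(qr$residual > 0 & qr$residual < 1))
  # self-consistency: new data from the fitted model gives uniform residuals
  ks_ok <- vapply(1:100, function(s) {
    y_new <- squeeze(simulate_beta_traits(
      tr, X, list(beta = fit$coefficients$estimate, phi = fit$phi,
                  sigma2_phylo = fit$sigma2_phylo), seed = 4000 + s))
    r <- quantile_residuals(fit, n_sim = 250, seed = s, y = y_new)
    attr(r, "ks_p_value") > 0.01
  }, logical(1))
  expect_gte(mean(ks_ok), 0.95)
  # shifting the data up concentrates residual quantiles near 1
  y_shift <- squeeze(pmin(fit$y + 0.3, 1))
  r_shift <- quantile_residuals(fit, n_sim = 250, seed = 3, y = y_shift)
  expect_gt(median(r_shift$residual), 0.9)
  expect_warning(quantile_residuals(fit, n_sim = 50, seed = 1), "coarse")
})
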