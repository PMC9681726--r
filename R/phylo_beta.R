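#' Squeeze boundary proportions into the open interval
#'
#' The beta likelihood is undefined at exactly 0 or 1, so species with no
#' black on the wingtip are assigned 1e-4 and fully black wingtips 0.9999;
#' interior values pass through unchanged.
#'
#' @param p Proportions in \[0, 1\].
#' @return Proportions in \[1e-4, 0.9999\].
#' @export
squeeze <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("Proportions must lie in [0, 1].", call. = FALSE)
  }
  out <- p
  out[!is.na(p) & p == 0] <- 1e-4
  out[!is.na(p) & p == 1] <- 0.9999
  out
}

#' Exponentiate a logit-scale coefficient into a ratio
#'
#' Analogous to an odds ratio: the multiplicative change in the ratio of
#' black to non-black wingtip area per unit increase in the predictor.
#'
#' @param b Coefficient(s) on the logit scale.
#' @return `exp(b)`.
#' @export
coef_to_ratio <- function(b) exp(b)

# beta log-likelihood and derivatives with respect to the linear predictor
beta_eta_derivs <- function(eta, y, phi) {
  # keep mu strictly inside (0, 1) when the optimizer probes extreme eta
  eta <- pmin(pmax(eta, -30), 30)
  mu <- plogis(eta)
  a <- mu * phi
  b <- (1 - mu) * phi
  w <- mu * (1 - mu)
  ll <- sum(dbeta(y, a, b, log = TRUE))
  ytil <- log(y) - log1p(-y)
  mutil <- digamma(a) - digamma(b)
  score <- phi * w * (ytil - mutil)
  fisher <- -phi^2 * w^2 * (trigamma(a) + trigamma(b))          # always < 0
  obs <- phi * w * (1 - 2 * mu) * (ytil - mutil) + fisher        # observed
  list(ll = ll, score = score, obs = obs, fisher = fisher)
}

# Laplace-approximate marginal log-likelihood of the phylogenetic beta model
# at fixed (beta, phi, s2). C_chol is chol(C). Returns -Inf on failure.
beta_laplace_ll <- function(beta, phi, s2, X, y, C_chol) {
  n <- length(y)
  eta0 <- as.numeric(X %*% beta)
  if (s2 <= 0) {
    d <- beta_eta_derivs(eta0, y, phi)
    return(list(ll = d$ll, u = numeric(n)))
  }
  Ci <- chol2inv(C_chol)
  Sinv <- Ci / s2
  logdetS <- n * log(s2) + chol_logdet(C_chol)
  u <- numeric(n)
  g <- function(u) {
    d <- beta_eta_derivs(eta0 + u, y, phi)
    d$ll - 0.5 * sum(u * (Sinv %*% u))
  }
  g_cur <- g(u)
  for (it in seq_len(100L)) {
    d <- beta_eta_derivs(eta0 + u, y, phi)
    grad <- d$score - as.numeric(Sinv %*% u)
    H <- Sinv - diag(d$fisher, n)          # Fisher step: guaranteed PD
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(list(ll = -Inf, u = u))
    t_step <- 1
    repeat {
      u_new <- u + t_step * step
      g_new <- g(u_new)
      if (is.finite(g_new) && g_new >= g_cur - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-8) { u_new <- u; g_new <- g_cur; break }
    }
    done <- abs(g_new - g_cur) < 1e-10
    u <- u_new; g_cur <- g_new
    if (done) break
  }
  d <- beta_eta_derivs(eta0 + u, y, phi)
  H_obs <- Sinv - diag(d$obs, n)
  ch <- tryCatch(chol(H_obs), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(Sinv - diag(d$fisher, n))
  ll <- d$ll - 0.5 * sum(u * (Sinv %*% u)) - 0.5 * logdetS - 0.5 * chol_logdet(ch)
  list(ll = ll, u = u)
}

#' Maximum-likelihood phylogenetic beta regression (matrix interface)
#'
#' Fits `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = x_i' beta + u_i` and `u ~ MVN(0, sigma2_phylo * C)` by
#' maximizing the Laplace-approximate marginal likelihood (inner Newton
#' optimization of the random effect, outer Nelder-Mead over
#' `(beta, log phi, log sigma2_phylo)`). When `sigma2_phylo` is fixed at 0
#' the marginal likelihood is the plain beta-regression likelihood, with no
#' approximation.
#'
#' @param X Design matrix.
#' @param y Response proportions strictly inside (0, 1) (see [squeeze()]).
#' @param C Phylogenetic correlation matrix with unit diagonal (see
#'   [phylo_corr()]).
#' @param sigma2_phylo `NULL` to estimate the phylogenetic variance, or a
#'   fixed non-negative value.
#' @param control List of optimizer settings (`maxit`, `reltol`).
#' @return A list of class `"phylo_beta_fit"`.
#' @export
beta_laplace_ml <- function(X, y, C, sigma2_phylo = NULL, control = list()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (any(y <= 0 | y >= 1)) {
    stop("Responses must lie strictly in (0, 1); apply squeeze() first.", call. = FALSE)
  }
  C_chol <- chol_or_stop(C, "phylogenetic correlation")
  estimate_s2 <- is.null(sigma2_phylo)
  maxit <- control$maxit %||% 2000L
  reltol <- control$reltol %||% 1e-10

  # starting values: logit-scale least squares and moment-matched precision
  beta0 <- tryCatch(as.numeric(solve(crossprod(X), crossprod(X, qlogis(y)))),
                    error = function(e) c(qlogis(mean(y)), rep(0, p - 1L)))
  mu0 <- plogis(as.numeric(X %*% beta0))
  v <- var(y - mu0)
  phi0 <- min(200, max(2, mean(mu0 * (1 - mu0)) / max(v, 1e-6) - 1))

  nll <- function(theta) {
    beta <- theta[seq_len(p)]
    # cap phi (and floor s2) so a degenerate likelihood that is unbounded in
    # the precision direction flattens out instead of derailing the simplex
    phi <- exp(min(theta[p + 1L], 20))
    s2 <- if (estimate_s2) exp(max(theta[p + 2L], -25)) else sigma2_phylo
    ll <- beta_laplace_ll(beta, phi, s2, X, y, C_chol)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  theta0 <- c(beta0, log(phi0), if (estimate_s2) log(0.2))
  opt <- optim(theta0, nll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  # quasi-Newton polish: the simplex stops short on flat likelihood surfaces
  polish <- tryCatch(
    optim(opt$par, nll, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14,
                         ndeps = rep(1e-6, length(opt$par)))),
    error = function(e) NULL)
  converged <- opt$convergence == 0
  if (!is.null(polish) && polish$value <= opt$value) {
    converged <- converged || polish$convergence == 0
    opt <- polish
  }
  if (!converged) {
    stop("Phylogenetic beta regression did not converge (optim code ",
         opt$convergence, ", value ", signif(opt$value, 8), ").",
         call. = FALSE)
  }
  theta <- opt$par
  beta <- theta[seq_len(p)]
  phi <- exp(min(theta[p + 1L], 20))
  s2 <- if (estimate_s2) exp(max(theta[p + 2L], -25)) else sigma2_phylo

  H <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[seq_len(p)] > 0)) se <- sqrt(diag(V)[seq_len(p)])
  }
  z <- beta / se
  terms <- colnames(X) %||% paste0("x", seq_len(p))
  inner <- beta_laplace_ll(beta, phi, s2, X, y, C_chol)
  structure(list(
    coefficients = tibble::tibble(
      term = terms, estimate = beta, std_error = se,
      ratio = exp(beta), z = z, p_value = 2 * pnorm(-abs(z))),
    phi = phi, sigma2_phylo = s2, loglik = -opt$value,
    boundary = estimate_s2 && s2 < 1e-6,
    converged = TRUE, n = n, X = X, y = y, C = C, u_hat = inner$u),
    class = "phylo_beta_fit")
}

#' Phylogenetic beta regression of wingtip black proportion
#'
#' Data-first wrapper around [beta_laplace_ml()]: takes a derived species
#' table and a tree, restricts to complete cases, applies the boundary
#' [squeeze()] to the response, and builds the phylogenetic correlation from
#' the pruned tree.
#'
#' @inheritParams pgls_fit
#' @param formula Model formula with a proportion response, e.g.
#'   `wingtip_black ~ wing_loading_std + abs_latitude`.
#' @param sigma2_phylo `NULL` (estimate) or a fixed non-negative value.
#' @return A `"phylo_beta_fit"` object.
#' @export
fit_phylo_beta <- function(data, tree, formula, species_col = "species",
                           sigma2_phylo = NULL) {
  vars <- all.vars(formula)
  keep <- complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  m <- match_species_to_tree(data, tree, species_col)
  data <- m$data; tree <- m$tree
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  y <- squeeze(stats::model.response(mf))
  C <- phylo_corr(tree)
  fit <- beta_laplace_ml(X, y, C, sigma2_phylo = sigma2_phylo)
  fit$formula <- formula
  fit$species <- data[[species_col]]
  fit$tree <- tree
  fit
}

#' @export
print.phylo_beta_fit <- function(x, ...) {
  cat("Phylogenetic beta regression (logit link), n = ", x$n, "\n", sep = "")
  cat("  phi = ", signif(x$phi, 4), ", sigma2_phylo = ", signif(x$sigma2_phylo, 4),
      if (isTRUE(x$boundary)) " [boundary]" else "",
      ", logLik = ", round(x$loglik, 2), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Predicted wingtip black proportion at given covariate values
#'
#' Population-level prediction (random effect at its mean of 0): the
#' inverse logit of `b0 + b_WL * wl_std + b_AL * abs_lat`.
#'
#' @param object A `"phylo_beta_fit"`, or a numeric vector of three
#'   coefficients (intercept, standardized wing loading, absolute latitude)
#'   on the logit scale.
#' @param wl_std Standardized wing loading (SD units from the sample mean).
#' @param abs_lat Absolute latitude in degrees.
#' @return Predicted proportion(s) in (0, 1).
#' @export
predict_proportion <- function(object, wl_std = 0, abs_lat = 0) {
  b <- if (inherits(object, "phylo_beta_fit")) object$coefficients$estimate else as.numeric(object)
  if (length(b) != 3L) stop("Expected three coefficients: intercept, wing loading, latitude.", call. = FALSE)
  plogis(b[1] + b[2] * wl_std + b[3] * abs_lat)
}

#' Simulated quantile residuals for a phylogenetic beta regression
#'
#' For each observation, the empirical quantile of the observed value among
#' `n_sim` draws from its fitted predictive distribution (random effect
#' integrated by sampling). Under a correctly specified model these are
#' approximately uniform on (0, 1); a Kolmogorov-Smirnov uniformity p-value
#' is attached as attribute `"ks_p_value"`.
#'
#' @param fit A converged `"phylo_beta_fit"`.
#' @param n_sim Number of predictive draws (default 250; < 100 warns).
#' @param seed Integer seed for the predictive simulation.
#' @param y Observations to locate within the predictive draws; defaults to
#'   the data the model was fitted to (supplying new data diagnoses how it
#'   would misfit this model).
#' @return A tibble with `observation` and `residual` columns.
#' @export
quantile_residuals <- function(fit, n_sim = 250L, seed = 1L, y = NULL) {
  if (n_sim < 100L) warning("n_sim < 100 gives coarse residual quantiles.", call. = FALSE)
  set.seed(seed)
  n <- fit$n
  y <- y %||% fit$y
  stopifnot(length(y) == n)
  beta <- fit$coefficients$estimate
  eta0 <- as.numeric(fit$X %*% beta)
  U <- if (fit$sigma2_phylo > 0) chol(fit$sigma2_phylo * fit$C) else NULL
  sims <- matrix(NA_real_, n, n_sim)
  for (s in seq_len(n_sim)) {
    u <- if (is.null(U)) 0 else as.numeric(crossprod(U, rnorm(n)))
    mu <- plogis(eta0 + u)
    sims[, s] <- rbeta(n, mu * fit$phi, (1 - mu) * fit$phi)
  }
  res <- vapply(seq_len(n), function(i) {
    below <- sum(sims[i, ] < y[i])
    ties <- sum(sims[i, ] == y[i])
    (below + runif(1) * (ties + 1)) / (n_sim + 1)
  }, numeric(1))
  out <- tibble::tibble(observation = seq_len(n), residual = res)
  attr(out, "ks_p_value") <- suppressWarnings(ks.test(res, "punif")$p.value)
  out
}
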