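#' Generalized least squares under a fixed covariance structure
#'
#' Maximum-likelihood GLS of `y` on `X` with residual covariance
#' `sigma2 * C0`. The coefficient estimate is
#' `(X' C0^-1 X)^-1 X' C0^-1 y`; the rate is profiled out as
#' `sigma2_ml = r' C0^-1 r / n`. Reported standard errors use the
#' `n - p` denominator and p-values come from the t distribution with
#' `n - p` degrees of freedom.
#'
#' @param X Design matrix (full column rank).
#' @param y Response vector aligned to the rows of `X`.
#' @param C0 Positive-definite covariance structure (identity for ordinary
#'   least squares).
#' @param structure_name Label used in error messages when `C0` fails to
#'   factorize.
#' @return A list with `beta`, `se`, `t_stat`, `p_value`, `sigma2` (ML),
#'   `sigma2_adj`, `loglik`, `n`, `p`, and a `degenerate` flag set when the
#'   fit is exact (residual quadratic form numerically zero, log-likelihood
#'   unbounded).
#' @export
gls_fit <- function(X, y, C0, structure_name = "covariance") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("`y` length must match rows of `X`.", call. = FALSE)
  if (qr(X)$rank < p) stop("Design matrix is rank deficient.", call. = FALSE)
  U <- chol_or_stop(C0, structure_name)
  # whiten: solve U' Z = X etc., so Z' Z = X' C0^-1 X
  Zx <- forwardsolve(t(U), X)
  zy <- forwardsolve(t(U), y)
  XtCiX <- crossprod(Zx)
  beta <- solve(XtCiX, crossprod(Zx, zy))
  r <- zy - Zx %*% beta
  q <- sum(r^2)
  logdetC <- chol_logdet(U)
  scale_y <- max(sum(zy^2), 1)
  degenerate <- q < 1e-12 * scale_y
  sigma2_ml <- q / n
  loglik <- if (degenerate) Inf else {
    -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetC + n)
  }
  sigma2_adj <- if (n > p) q / (n - p) else NA_real_
  vc <- sigma2_adj * solve(XtCiX)
  se <- sqrt(diag(vc))
  tval <- as.numeric(beta) / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  list(beta = setNames(as.numeric(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       t_stat = setNames(tval, colnames(X)),
       p_value = setNames(pval, colnames(X)),
       sigma2 = sigma2_ml, sigma2_adj = sigma2_adj,
       loglik = loglik, n = n, p = p, degenerate = degenerate)
}

# Covariance structure for one model at a given scalar parameter.
# tmat: MRCA depths; dmat: patristic distances (both in tip order).
pgls_structure <- function(model, param, tmat, dmat) {
  switch(model,
    NP = diag(nrow(tmat)),
    BM = tmat,
    OU = exp(-param * dmat) * (-expm1(-2 * param * tmat)) / (2 * param),
    LAMBDA = lambda_transform(tmat, param),
    stop("Unknown model: ", model, call. = FALSE)
  )
}

# Core four-model fit on precomputed matrices (used by pgls_fit and the
# adequacy harness, which refits thousands of simulated traits).
fit_pgls_core <- function(X, y, tmat, dmat, model, grid_size = 50L) {
  model <- match.arg(model, c("NP", "BM", "OU", "LAMBDA"))
  height <- max(diag(tmat))
  profile_ll <- function(param) {
    gls_fit(X, y, pgls_structure(model, param, tmat, dmat),
            structure_name = model)$loglik
  }
  param <- NULL
  boundary <- FALSE
  if (model %in% c("NP", "BM")) {
    fit <- gls_fit(X, y, pgls_structure(model, NA, tmat, dmat), structure_name = model)
  } else if (model == "OU") {
    # the small-alpha floor makes BM the attainable boundary of the OU search
    lo <- log(1e-8 / height); hi <- log(1e3 / height)
    grid <- seq(lo, hi, length.out = grid_size)
    ll <- vapply(grid, function(g) profile_ll(exp(g)), numeric(1))
    i <- which.max(ll)
    bl <- grid[max(1L, i - 1L)]; bu <- grid[min(grid_size, i + 1L)]
    opt <- optimize(function(g) profile_ll(exp(g)), c(bl, bu),
                    maximum = TRUE, tol = 1e-8)
    # keep whichever of the refined optimum and grid maximum is higher
    if (opt$objective >= ll[i]) {
      param <- exp(opt$maximum); best_ll <- opt$objective
    } else {
      param <- exp(grid[i]); best_ll <- ll[i]
    }
    boundary <- (log(param) - lo) < 1e-4 || (hi - log(param)) < 1e-4
    fit <- gls_fit(X, y, pgls_structure("OU", param, tmat, dmat), structure_name = "OU")
  } else { # LAMBDA
    opt <- optimize(profile_ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    ll <- vapply(cand, profile_ll, numeric(1))
    param <- cand[which.max(ll)]
    boundary <- param %in% c(0, 1)
    fit <- gls_fit(X, y, pgls_structure("LAMBDA", param, tmat, dmat),
                   structure_name = "LAMBDA")
  }
  k <- fit$p + 1L + as.integer(model %in% c("OU", "LAMBDA"))
  list(model = model, fit = fit, param = param, boundary = boundary,
       loglik = fit$loglik, aic = 2 * k - 2 * fit$loglik, k = k,
       profile_ll = profile_ll, height = height)
}

#' Fit a phylogenetic regression under one evolutionary model
#'
#' Fits the regression given by `formula` by maximum likelihood with residual
#' covariance determined by `model`: `"NP"` (non-phylogenetic, identity),
#' `"BM"` (Brownian motion, shared-path covariance), `"OU"`
#' (Ornstein-Uhlenbeck, selection strength `alpha` profiled over
#' `[1e-6/height, 1e3/height]` on the log scale), or `"LAMBDA"` (Pagel's
#' lambda profiled over `[0, 1]`). ML (not REML) is used throughout so that
#' log-likelihoods are comparable across models in likelihood-ratio tests.
#'
#' @param data A data frame with one row per species, containing the model
#'   variables and a species-name column matching the tree's tip labels
#'   (after underscore/space normalization). Rows with missing model
#'   variables are dropped (complete-case per analysis).
#' @param tree A rooted, time-calibrated "phylo" object.
#' @param formula Model formula, e.g. `mantle_kgs ~ wing_loading_std +
#'   abs_latitude`.
#' @param model One of `"NP"`, `"BM"`, `"OU"`, `"LAMBDA"`.
#' @param species_col Name of the species column. Default `"species"`.
#' @return An object of class `"pgls_fit"`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()] for tabular summaries.
#' @export
pgls_fit <- function(data, tree, formula, model = c("OU", "NP", "BM", "LAMBDA"),
                     species_col = "species") {
  model <- match.arg(model)
  vars <- all.vars(formula)
  keep <- complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  m <- match_species_to_tree(data, tree, species_col)
  data <- m$data; tree <- m$tree
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  y <- stats::model.response(mf)
  tmat <- mrca_depth_matrix(tree)
  depths <- diag(tmat)
  dmat <- outer(depths, depths, "+") - 2 * tmat
  core <- fit_pgls_core(X, y, tmat, dmat, model)
  structure(
    c(core,
      list(formula = formula, data = data, tree = tree, X = X, y = y,
           tmat = tmat, dmat = dmat, species = data[[species_col]])),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic regression (", x$model, " model), n = ", x$fit$n, "\n", sep = "")
  if (!is.null(x$param)) {
    lab <- if (x$model == "OU") "alpha" else "lambda"
    cat("  ", lab, " = ", signif(x$param, 4),
        if (x$boundary) "  [boundary]" else "", "\n", sep = "")
  }
  cat("  sigma2 = ", signif(x$fit$sigma2, 4),
      ", logLik = ", round(x$loglik, 2), ", AIC = ", round(x$aic, 2), "\n", sep = "")
  print(tidy.pgls_fit(x))
  invisible(x)
}

#' Likelihood-ratio test between nested phylogenetic regressions
#'
#' @param restricted,general Fitted `"pgls_fit"` objects on the same data;
#'   `general` must have more estimated parameters.
#' @return A tibble with `statistic` (2 * delta log-likelihood, clipped at
#'   0), `df` and `p_value` (chi-square upper tail).
#' @export
lrt <- function(restricted, general) {
  rl <- if (inherits(restricted, "pgls_fit")) restricted$loglik else restricted
  gl <- if (inherits(general, "pgls_fit")) general$loglik else general
  rk <- if (inherits(restricted, "pgls_fit")) restricted$k else NULL
  gk <- if (inherits(general, "pgls_fit")) general$k else NULL
  if (inherits(restricted, "pgls_fit") && inherits(general, "pgls_fit")) {
    if (restricted$fit$n != general$fit$n) {
      stop("Fits use different sample sizes; LRT requires the same data.", call. = FALSE)
    }
    if (rk >= gk) stop("`general` must have more parameters than `restricted`.", call. = FALSE)
  }
  df <- if (!is.null(rk)) gk - rk else 1L
  stat <- max(0, 2 * (gl - rl))
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Phylogenetic half-life of an OU process
#'
#' Time for the expected trait value to move halfway to the optimum:
#' `ln(2) / alpha`.
#'
#' @param alpha Selection strength (> 0), or a fitted OU `"pgls_fit"`.
#' @return Half-life in tree time units.
#' @export
half_life <- function(alpha) {
  if (inherits(alpha, "pgls_fit")) {
    if (alpha$model != "OU") stop("Half-life is defined for OU fits only.", call. = FALSE)
    alpha <- alpha$param
  }
  if (any(alpha <= 0)) stop("`alpha` must be > 0.", call. = FALSE)
  log(2) / alpha
}

#' Profile confidence interval for Pagel's lambda
#'
#' Endpoints where the profile log-likelihood drops `qchisq(level, 1) / 2`
#' (1.92 at 95%) below its maximum, clipped to \[0, 1\].
#'
#' @param fit A `"pgls_fit"` with `model = "LAMBDA"`.
#' @param level Confidence level, default 0.95.
#' @return A tibble with `lower` and `upper`.
#' @export
lambda_profile_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "pgls_fit"), fit$model == "LAMBDA")
  drop <- qchisq(level, df = 1) / 2
  target <- fit$loglik - drop
  f <- function(l) fit$profile_ll(l) - target
  grid <- seq(0, 1, length.out = 101)
  vals <- vapply(grid, f, numeric(1))
  if (all(vals > 0)) {
    warning("Profile log-likelihood is flat; returning the full [0, 1] interval.",
            call. = FALSE)
    return(tibble::tibble(lower = 0, upper = 1))
  }
  lhat <- fit$param
  lower <- if (f(0) >= 0) 0 else uniroot(f, c(0, lhat), tol = 1e-6)$root
  upper <- if (f(1) >= 0) 1 else uniroot(f, c(lhat, 1), tol = 1e-6)$root
  tibble::tibble(lower = lower, upper = upper)
}

#' Fit and compare the four evolutionary models
#'
#' Fits NP, BM, OU and lambda regressions to the same data and summarises
#' them with likelihood-ratio tests of each extra-parameter model (OU,
#' lambda) against each restricted model (NP, BM).
#'
#' @inheritParams pgls_fit
#' @return A list of class `"pgls_comparison"` with `fits` (named list of
#'   `"pgls_fit"`) and `table` (one row per model: parameter, sigma2,
#'   log-likelihood, AIC, and LRT p-values against NP and BM).
#' @export
pgls_compare <- function(data, tree, formula, species_col = "species") {
  models <- c("OU", "LAMBDA", "NP", "BM")
  fits <- lapply(models, function(m) pgls_fit(data, tree, formula, m, species_col))
  names(fits) <- models
  tab <- purrr::map_dfr(models, function(m) {
    f <- fits[[m]]
    tibble::tibble(
      model = m,
      param = if (is.null(f$param)) NA_real_ else f$param,
      sigma2 = f$fit$sigma2,
      loglik = f$loglik,
      aic = f$aic,
      lrt_p_np = if (m %in% c("OU", "LAMBDA")) lrt(fits$NP, f)$p_value else NA_real_,
      lrt_p_bm = if (m %in% c("OU", "LAMBDA")) lrt(fits$BM, f)$p_value else NA_real_
    )
  })
  structure(list(fits = fits, table = tab, formula = formula),
            class = "pgls_comparison")
}

#' @export
print.pgls_comparison <- function(x, ...) {
  cat("Four-model phylogenetic regression comparison\n")
  print(x$table)
  invisible(x)
}

#' Ordinary least-squares slope summary
#'
#' Simple linear regression (via [stats::lm()]) reported as a one-row tibble,
#' as used for the aspect-ratio-on-wing-loading analysis.
#'
#' @param x Predictor vector (non-constant, n >= 3).
#' @param y Response vector.
#' @return A tibble with `intercept`, `slope`, `se` (slope SE), `r2`,
#'   `p_value` (two-sided t test on the slope).
#' @export
ols_fit <- function(x, y) {
  if (length(x) < 3L) stop("Need at least 3 observations.", call. = FALSE)
  if (sd(x) == 0) stop("`x` is constant.", call. = FALSE)
  m <- lm(y ~ x)
  s <- summary(m)
  tibble::tibble(intercept = coef(m)[[1]], slope = coef(m)[[2]],
                 se = s$coefficients[2, 2], r2 = s$r.squared,
                 p_value = s$coefficients[2, 4])
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) stop("Constant input has no defined correlation.", call. = FALSE)
  cor(x, y)
}
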