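#' Generator configuration for synthetic gull data
#'
#' Default parameter values mirror the magnitudes estimated for real gulls:
#' a 50-tip tree of height 0.21 time units, an OU regression of mantle
#' darkness on standardized wing loading and absolute latitude with
#' coefficients (10.38, 1.22, -0.07), selection strength 27.13 and rate
#' 595.77 (stationary SD about 3.3 grey-scale units), and a phylogenetic
#' logit-beta model for wingtip black proportion with coefficients
#' (1.65, 0.34, -0.05), precision 30 and phylogenetic variance 0.5.
#'
#' @param n_species Number of species (>= 3).
#' @param tree_height Tree height in time units.
#' @param beta_mantle Mantle regression coefficients (intercept, WL, AL).
#' @param alpha OU selection strength, per tree-time unit.
#' @param sigma2 OU evolutionary rate.
#' @param beta_wingtip Wingtip logit-scale coefficients (intercept, WL, AL).
#' @param phi Beta precision.
#' @param sigma2_phylo Phylogenetic random-effect variance for wingtips.
#' @param seed Integer root seed.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_species = 50L, tree_height = 0.21,
                             beta_mantle = c(10.38, 1.22, -0.07),
                             alpha = 27.13, sigma2 = 595.77,
                             beta_wingtip = c(1.65, 0.34, -0.05),
                             phi = 30, sigma2_phylo = 0.5, seed = 1L) {
  stopifnot(n_species >= 3L, tree_height > 0, phi > 0, sigma2 >= 0,
            alpha > 0, sigma2_phylo >= 0)
  structure(list(n_species = as.integer(n_species), tree_height = tree_height,
                 beta_mantle = beta_mantle, alpha = alpha, sigma2 = sigma2,
                 beta_wingtip = beta_wingtip, phi = phi,
                 sigma2_phylo = sigma2_phylo, seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree rescaled so every root-to-tip path equals `height`, with tips
#' labelled `sp001 ... spN`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param height Tree height in time units.
#' @param seed Integer seed.
#' @return A "phylo" object.
#' @export
simulate_tree <- function(n_tips = 50L, height = 0.21, seed = 1L) {
  stopifnot(n_tips >= 3L, height > 0)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length * (height / tree_height(tree))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Simulate a trait on a tree under BM or OU
#'
#' Exact multivariate-normal draw with mean `X beta` and the model's
#' covariance (Brownian: `sigma2 * t_ij`; OU: the fixed-root covariance of
#' [ou_cov()]); no Euler discretization.
#'
#' @param tree A rooted "phylo" object.
#' @param X Design matrix with rows in tip order.
#' @param model `"BM"` or `"OU"`.
#' @param params List with `beta`, `sigma2`, and `alpha` (OU only).
#' @param seed Integer seed.
#' @return A trait vector named by tip label.
#' @export
simulate_traits <- function(tree, X, model = c("BM", "OU"), params, seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  n <- length(tree$tip.label)
  stopifnot(nrow(X) == n)
  mu <- as.numeric(X %*% params$beta)
  set.seed(seed)
  if (params$sigma2 == 0) return(setNames(mu, tree$tip.label))
  V <- if (model == "BM") params$sigma2 * mrca_depth_matrix(tree)
       else ou_cov(tree, params$alpha, params$sigma2)
  U <- chol_or_stop(V, model)
  setNames(mu + as.numeric(crossprod(U, rnorm(n))), tree$tip.label)
}

#' Simulate proportions from the phylogenetic logit-beta model
#'
#' Draws `u ~ MVN(0, sigma2_phylo * C)` with `C` the unit-diagonal
#' phylogenetic correlation, then `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)`
#' with `logit(mu_i) = x_i' beta + u_i`.
#'
#' @inheritParams simulate_traits
#' @param params List with `beta`, `phi`, `sigma2_phylo`.
#' @return A proportion vector in (0, 1), named by tip label.
#' @export
simulate_beta_traits <- function(tree, X, params, seed = 1L) {
  X <- as.matrix(X)
  n <- length(tree$tip.label)
  stopifnot(nrow(X) == n)
  set.seed(seed)
  eta <- as.numeric(X %*% params$beta)
  if (params$sigma2_phylo > 0) {
    U <- chol_or_stop(params$sigma2_phylo * phylo_corr(tree), "phylogenetic correlation")
    eta <- eta + as.numeric(crossprod(U, rnorm(n)))
  }
  mu <- plogis(eta)
  setNames(rbeta(n, mu * params$phi, (1 - mu) * params$phi), tree$tip.label)
}

#' Simulate a raw species measurement table
#'
#' Emulates the structure of a field-measurement table: body masses
#' log-uniform on \[90, 2000\] g; wingspans allometric (proportional to
#' mass^(1/3), multiplicative noise) within \[550, 1800\] mm and reported as
#' a +/- 3% range; hand length a fraction 0.32-0.40 of wingspan; first
#' secondary length a fraction 0.38-0.50 of hand length (so derived wing
#' loading lands in roughly 0.002-0.007 g mm^-2 and aspect ratio in 8-12);
#' range-centroid latitudes uniform on \[-70, 70\] degrees, independent of
#' the tree. Mantle darkness is drawn from the OU regression on
#' (standardized wing loading, absolute latitude) and clipped to the 0-19
#' grey scale; wingtip black proportion is drawn from the phylogenetic
#' logit-beta model and rounded at 1e-4, so values may hit exactly 0 or 1 as
#' in real scoring.
#'
#' @param tree A "phylo" object (typically from [simulate_tree()]).
#' @param config A [generator_config()].
#' @return A tibble of raw species records, one row per tip.
#' @export
simulate_species_table <- function(tree, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- length(tree$tip.label)
  set.seed(config$seed)
  mass <- exp(runif(n, log(90), log(2000)))
  eps <- pmin(pmax(rnorm(n, 0, 0.03), -0.06), 0.06)
  wingspan <- pmin(pmax(140 * mass^(1 / 3) * exp(eps), 550), 1800)
  h_frac <- runif(n, 0.32, 0.40)
  s_frac <- runif(n, 0.38, 0.50)
  H <- h_frac * wingspan
  S <- s_frac * H
  lat <- runif(n, -70, 70)
  area <- S * (wingspan - H)
  if (any(area <= 0)) stop("Generator produced non-positive wing area.", call. = FALSE)
  wl <- mass / area
  X <- cbind(1, z_standardize(wl), abs(lat))
  mantle <- simulate_traits(tree, X, "OU",
                            list(beta = config$beta_mantle, sigma2 = config$sigma2,
                                 alpha = config$alpha),
                            seed = config$seed + 1L)
  n_clip <- sum(mantle < 0 | mantle > 19)
  if (n_clip > 0) {
    message(n_clip, " mantle value(s) clipped to the [0, 19] grey scale.")
    mantle <- pmin(pmax(mantle, 0), 19)
  }
  wingtip <- simulate_beta_traits(tree, X,
                                  list(beta = config$beta_wingtip, phi = config$phi,
                                       sigma2_phylo = config$sigma2_phylo),
                                  seed = config$seed + 2L)
  wingtip <- round(wingtip, 4)
  tibble::tibble(
    species = tree$tip.label,
    hand_length = H,
    secondary_length = S,
    wingspan_min = wingspan * 0.97,
    wingspan_max = wingspan * 1.03,
    body_mass = mass,
    latitude = lat,
    mantle_kgs = as.numeric(mantle),
    wingtip_black = as.numeric(wingtip)
  )
}
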