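#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a phylogenetic regression fit
#'
#' @param x A `"pgls_fit"`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic` (t), `p.value`.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(term = names(x$fit$beta),
                 estimate = as.numeric(x$fit$beta),
                 std.error = as.numeric(x$fit$se),
                 statistic = as.numeric(x$fit$t_stat),
                 p.value = as.numeric(x$fit$p_value))
}

#' One-row summary of a phylogenetic regression fit
#'
#' @param x A `"pgls_fit"`.
#' @param ... Unused.
#' @return A tibble with `model`, `param` (alpha or lambda, NA for NP/BM),
#'   `sigma2`, `logLik`, `AIC`, `nobs`, `k`, `boundary`.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 param = if (is.null(x$param)) NA_real_ else x$param,
                 sigma2 = x$fit$sigma2,
                 logLik = x$loglik, AIC = x$aic,
                 nobs = x$fit$n, k = x$k, boundary = isTRUE(x$boundary))
}

#' Tidy a phylogenetic beta regression fit
#'
#' @param x A `"phylo_beta_fit"`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `ratio` (exponentiated estimate), `statistic` (Wald z), `p.value`.
#' @method tidy phylo_beta_fit
#' @export
tidy.phylo_beta_fit <- function(x, ...) {
  dplyr::transmute(x$coefficients,
                   term = .data$term, estimate = .data$estimate,
                   std.error = .data$std_error, ratio = .data$ratio,
                   statistic = .data$z, p.value = .data$p_value)
}

#' One-row summary of a phylogenetic beta regression fit
#'
#' @param x A `"phylo_beta_fit"`.
#' @param ... Unused.
#' @return A tibble with `phi`, `sigma2_phylo`, `logLik`, `nobs`,
#'   `boundary`, `converged`.
#' @method glance phylo_beta_fit
#' @export
glance.phylo_beta_fit <- function(x, ...) {
  tibble::tibble(phi = x$phi, sigma2_phylo = x$sigma2_phylo,
                 logLik = x$loglik, nobs = x$n,
                 boundary = isTRUE(x$boundary), converged = isTRUE(x$converged))
}

#' @importFrom rlang .data
NULL
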