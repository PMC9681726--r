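#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dbeta lm logLik median model.matrix optim
#'   optimHess optimize pchisq plogis pnorm pt qchisq qlogis quantile rbeta
#'   rnorm runif sd setNames uniroot var complete.cases as.formula terms
#'   model.frame ks.test
#' @importFrom utils packageVersion head tail
NULL

# logit helpers used across the beta-regression surface
logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cholesky with a diagnostic error naming the structure; no automatic jitter.
chol_or_stop <- function(C, structure_name = "covariance") {
  out <- tryCatch(chol(C), error = function(e) e)
  if (inherits(out, "error")) {
    stop("Cholesky factorization failed for the ", structure_name,
         " structure; the matrix is not positive definite.", call. = FALSE)
  }
  out
}

# log-determinant from an upper-triangular Cholesky factor
chol_logdet <- function(U) 2 * sum(log(diag(U)))

# solve C x = b given U = chol(C)
chol_solve <- function(U, b) backsolve(U, forwardsolve(t(U), b))

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number.", call. = FALSE)
  }
}

# underscore/space normalization used when matching CSV species to tip labels
normalize_label <- function(x) gsub("[ _]+", "_", trimws(x))
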