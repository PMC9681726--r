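#' Read a Newick tree
#'
#' Parses a Newick string or file into an `ape` "phylo" tree. Branch lengths
#' are mandatory because every downstream covariance structure is built from
#' them.
#'
#' @param x A Newick string or a path to a Newick file.
#' @return A "phylo" object.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_path <- !grepl("\\(", x) && file.exists(x)
  text <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "") else x
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                       ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(bal < 0) || tail(bal, 1) != 0L) {
    pos <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop("Malformed Newick: unbalanced parentheses near character ", pos, ".", call. = FALSE)
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree)) stop("Malformed Newick: could not parse tree.", call. = FALSE)
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length) || length(tree$edge.length) != n_edge ||
      anyNA(tree$edge.length)) {
    stop("Tree has missing branch lengths; lengths are required on every edge.", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("Tip labels must be unique.", call. = FALSE)
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree A "phylo" object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Prune a tree to a set of tips
#'
#' Drops all tips outside `keep`; unary internal nodes left behind are
#' collapsed with their branch lengths summed, so path lengths between every
#' retained pair are unchanged.
#'
#' If the kept tips all fall inside one clade the collapsed basal path is
#' retained as a root edge, so root-to-MRCA depths keep referring to the
#' original root.
#'
#' @param tree A "phylo" object.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The induced "phylo" tree on `keep`.
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("Tip label(s) not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) {
    stop("Need at least 2 tips to retain a tree.", call. = FALSE)
  }
  out <- ape::keep.tip(tree, keep)
  if (length(keep) < length(tree$tip.label)) {
    stem <- ape::node.depth.edgelength(tree)[ape::getMRCA(tree, keep)]
    if (stem > 0) out$root.edge <- (out$root.edge %||% 0) + stem
  }
  out
}

#' Shared-path (MRCA depth) matrix
#'
#' Entry (i, j) is the distance from the root to the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip depths. Under
#' Brownian motion, trait covariance between species is proportional to this
#' matrix.
#'
#' @param tree A rooted "phylo" object with branch lengths.
#' @return An n x n symmetric matrix with tip labels as dimnames.
#' @export
mrca_depth_matrix <- function(tree) {
  C <- ape::vcv.phylo(tree)
  # a retained root edge is shared history common to every tip pair
  if (!is.null(tree$root.edge)) C <- C + tree$root.edge
  C
}

#' Patristic distance matrix and tree height
#'
#' @param tree A rooted "phylo" object.
#' @return `patristic_matrix()`: pairwise path lengths between tips;
#'   `tree_height()`: the maximum root-to-tip distance, in tree time units.
#' @export
patristic_matrix <- function(tree) {
  as.matrix(stats::cophenetic(tree))[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' @rdname patristic_matrix
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]) +
    (tree$root.edge %||% 0)
}

#' Ornstein-Uhlenbeck trait covariance on a tree (fixed-root form)
#'
#' Covariance of tip trait values when the trait follows an OU process with
#' selection strength `alpha` and rate `sigma2`, started at the root value:
#' `V_ij = sigma2 / (2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))`
#' where `t_ij` is the root-to-MRCA depth and `d_ij` the patristic distance.
#' As `alpha -> 0` this approaches the Brownian-motion covariance
#' `sigma2 * t_ij`.
#'
#' @param tree A rooted "phylo" object; a warning is issued if not
#'   ultrametric.
#' @param alpha Selection strength, per tree-time unit; must be > 0.
#' @param sigma2 Evolutionary rate (variance accumulated per time unit).
#' @return An n x n positive-definite covariance matrix.
#' @export
ou_cov <- function(tree, alpha, sigma2 = 1) {
  stopifnot_scalar(alpha, "alpha")
  if (alpha <= 0) {
    stop("`alpha` must be > 0; Brownian motion is the alpha -> 0 limit, not a valid OU input.",
         call. = FALSE)
  }
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("Tree is not ultrametric; OU covariance uses MRCA depths as defined.",
            call. = FALSE)
  }
  tmat <- mrca_depth_matrix(tree)
  depths <- diag(tmat)
  dmat <- outer(depths, depths, "+") - 2 * tmat
  sigma2 / (2 * alpha) * exp(-alpha * dmat) * (-expm1(-2 * alpha * tmat))
}

#' Pagel's lambda transform of a Brownian covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries by `lambda`, leaving
#' the diagonal unchanged: `lambda = 1` is Brownian motion, `lambda = 0` a
#' star phylogeny.
#'
#' @param C A covariance matrix from [mrca_depth_matrix()].
#' @param lambda Signal multiplier in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot_scalar(lambda, "lambda")
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1].", call. = FALSE)
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

#' Phylogenetic correlation matrix
#'
#' The MRCA-depth matrix scaled by the tree height, giving a unit diagonal
#' on an ultrametric tree (general trees are normalized by cov2cor), as used
#' for the phylogenetic random effect of the wingtip beta regression.
#'
#' @param tree A rooted "phylo" object.
#' @return A correlation-scale matrix with unit diagonal.
#' @export
phylo_corr <- function(tree) {
  C <- mrca_depth_matrix(tree) / tree_height(tree)
  if (max(abs(diag(C) - 1)) > 1e-8) C <- stats::cov2cor(C)
  C
}

# Match data species to tree tips after underscore/space normalization.
# Returns the data reordered to tip order, with the pruned tree attached.
match_species_to_tree <- function(data, tree, species_col = "species") {
  sp <- normalize_label(data[[species_col]])
  tips <- normalize_label(tree$tip.label)
  unmatched <- data[[species_col]][!sp %in% tips]
  if (length(unmatched)) {
    stop("Species not found among tree tips: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sp)) stop("Duplicated species names in data.", call. = FALSE)
  if (length(sp) < length(tips)) {
    tree <- prune_tree(tree, tree$tip.label[tips %in% sp])
    tips <- normalize_label(tree$tip.label)
  }
  data <- data[match(tips, sp), , drop = FALSE]
  list(data = data, tree = tree)
}
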