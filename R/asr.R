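#' Joint maximum-likelihood ancestral states under Brownian motion
#'
#' Internal-node states are the joint ML estimates for a Brownian trait:
#' the minimizers of `sum over edges of (state change)^2 / branch length`.
#' This is a sparse quadratic problem whose optimum solves a graph-Laplacian
#' linear system with edge weights `1 / length`; each internal state is the
#' inverse-length-weighted average of its neighbours at the optimum. Tip
#' states are fixed at the observations.
#'
#' @param tree A rooted "phylo" object with strictly positive branch
#'   lengths.
#' @param tip_values Numeric vector of trait values, either named by tip
#'   label or in `tree$tip.label` order.
#' @return An object of class `"asr_result"` with `node_states` (named by
#'   internal node number), `tip_states`, and the tree.
#' @export
asr_bm <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (!is.null(names(tip_values))) {
    missing <- setdiff(tree$tip.label, names(tip_values))
    if (length(missing)) stop("No trait value for tip(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    tip_values <- tip_values[tree$tip.label]
  }
  if (length(tip_values) != n) stop("Need exactly one value per tip.", call. = FALSE)
  if (any(tree$edge.length <= 0)) {
    stop("Zero or negative branch length found; joint ML states are undefined ",
         "across a zero-length edge (jittering the tree is the caller's decision).",
         call. = FALSE)
  }
  w <- 1 / tree$edge.length
  nn <- n + m
  # graph Laplacian over all nodes, partitioned into internal (unknown) rows
  L <- matrix(0, nn, nn)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, i] <- L[i, i] + w[e]; L[j, j] <- L[j, j] + w[e]
    L[i, j] <- L[i, j] - w[e]; L[j, i] <- L[j, i] - w[e]
  }
  int <- (n + 1):nn
  states <- solve(L[int, int, drop = FALSE],
                  -L[int, seq_len(n), drop = FALSE] %*% tip_values)
  structure(list(
    node_states = setNames(as.numeric(states), as.character(int)),
    tip_states = setNames(as.numeric(tip_values), tree$tip.label),
    tree = tree), class = "asr_result")
}

#' Interpolate reconstructed states along branches
#'
#' Linear interpolation between each edge's parent and child states at equal
#' spacing, for gradient rendering of the trait on the tree.
#'
#' @param asr An `"asr_result"`.
#' @param resolution Segments per edge (>= 1); `resolution = 1` gives the
#'   two endpoints only.
#' @return A tibble with `edge`, `parent`, `child`, `position` (0 at the
#'   parent to 1 at the child) and `value`.
#' @export
interpolate_branches <- function(asr, resolution = 20L) {
  stopifnot(inherits(asr, "asr_result"), resolution >= 1L)
  tree <- asr$tree
  n <- length(tree$tip.label)
  state_of <- function(node) {
    ifelse(node <= n, asr$tip_states[node], asr$node_states[as.character(node)])
  }
  purrr::map_dfr(seq_len(nrow(tree$edge)), function(e) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sp <- state_of(pa); sc <- state_of(ch)
    pos <- seq(0, 1, length.out = resolution + 1L)
    tibble::tibble(edge = e, parent = pa, child = ch, position = pos,
                   value = sp + pos * (sc - sp))
  })
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Ancestral state reconstruction (joint ML, Brownian motion)\n")
  cat("  ", length(x$tip_states), " tips, ", length(x$node_states),
      " internal nodes; root state = ",
      signif(x$node_states[[1]], 4), "\n", sep = "")
  invisible(x)
}

#' Tidy ancestral states into a tibble
#'
#' @param x An `"asr_result"`.
#' @param ... Unused.
#' @return A tibble with `node`, `label` (tip label or NA), `type`
#'   (tip/internal) and `state`.
#' @method tidy asr_result
#' @export
tidy.asr_result <- function(x, ...) {
  n <- length(x$tip_states)
  dplyr::bind_rows(
    tibble::tibble(node = seq_len(n), label = names(x$tip_states),
                   type = "tip", state = as.numeric(x$tip_states)),
    tibble::tibble(node = as.integer(names(x$node_states)), label = NA_character_,
                   type = "internal", state = as.numeric(x$node_states))
  )
}

#' Write reconstructed states as an annotated Newick tree
#'
#' Internal-node states are stored as node labels, so the file round-trips
#' through standard Newick readers.
#'
#' @param asr An `"asr_result"`.
#' @param path Output file path, or `NULL` to return the string.
#' @param digits Significant digits for the node annotations.
#' @return The Newick string (invisibly when written).
#' @export
write_asr_newick <- function(asr, path = NULL, digits = 6) {
  tree <- asr$tree
  tree$node.label <- signif(as.numeric(asr$node_states), digits)
  write_newick(tree, path)
}
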