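#' Plot a gradient-coloured ancestral-state tree
#'
#' Rectangular cladogram with branches coloured by the interpolated
#' reconstructed trait value, the continuous-trait analogue of a painted
#' tree.
#'
#' @param object An `"asr_result"`.
#' @param resolution Interpolation segments per edge.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asr_result
#' @export
autoplot.asr_result <- function(object, resolution = 20L, ...) {
  tree <- object$tree
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  # tip y-positions in plotting order, internal nodes midway between children
  yy <- numeric(n + tree$Nnode)
  ord <- tree$edge[ape::postorder(tree), ]
  tr2 <- ape::reorder.phylo(tree, "cladewise")
  tips_in_order <- tr2$edge[tr2$edge[, 2] <= n, 2]
  yy[tips_in_order] <- seq_len(n)
  for (e in seq_len(nrow(ord))) {
    pa <- ord[e, 1]
    kids <- tree$edge[tree$edge[, 1] == pa, 2]
    yy[pa] <- mean(yy[kids])
  }
  seg <- interpolate_branches(object, resolution)
  seg <- dplyr::group_by(seg, .data$edge) |>
    dplyr::mutate(
      x = depth[.data$parent[1]] +
        .data$position * (depth[.data$child[1]] - depth[.data$parent[1]]),
      xend = dplyr::lead(.data$x),
      vmid = (.data$value + dplyr::lead(.data$value)) / 2,
      y = yy[.data$child[1]]
    ) |>
    dplyr::filter(!is.na(.data$xend)) |>
    dplyr::ungroup()
  vert <- tibble::tibble(
    x = depth[tree$edge[, 1]],
    y = yy[tree$edge[, 1]],
    yend = yy[tree$edge[, 2]],
    value = object$node_states[as.character(tree$edge[, 1])]
  )
  tips <- tibble::tibble(x = depth[seq_len(n)], y = yy[seq_len(n)],
                         label = tree$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = vert,
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$y,
                   yend = .data$yend, colour = .data$value)) +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y, colour = .data$vmid), linewidth = 1) +
    ggplot2::geom_text(data = tips,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = -0.1, size = 2.5) +
    ggplot2::scale_colour_viridis_c(name = "state") +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.2))) +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Plot simulated delta-AIC distributions from the adequacy check
#'
#' Histograms of `AIC_BM - AIC_OU` under the BM and OU generators with the
#' observed difference marked.
#'
#' @param object An `"adequacy_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adequacy_result
#' @export
autoplot.adequacy_result <- function(object, ...) {
  tidy.adequacy_result(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$delta_aic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_delta_aic,
                        colour = "firebrick", linetype = 2) +
    ggplot2::facet_wrap(~ .data$generator, scales = "free") +
    ggplot2::labs(x = expression(AIC[BM] - AIC[OU]), y = "replicates") +
    ggplot2::theme_minimal()
}

#' Scatterplot of aspect ratio against standardized wing loading
#'
#' With the ordinary least-squares line and its standard-error band.
#'
#' @param data A derived-morphology tibble with `wing_loading_std` and
#'   `aspect_ratio`.
#' @return A ggplot object.
#' @export
plot_aspect_ratio <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$wing_loading_std,
                                     y = .data$aspect_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = "standardized wing loading (SD)", y = "aspect ratio") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
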