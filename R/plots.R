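# ggplot2 visualisations: bootstrap densitograms and the painted tree.

#' @importFrom ggplot2 autoplot ggplot aes geom_density geom_vline facet_wrap
#'   labs theme_minimal geom_segment scale_colour_manual geom_text
NULL

#' @export
ggplot2::autoplot

#' Densitogram of bootstrapped regime optima
#'
#' Mirrors the familiar presentation of bootstrap optimum distributions:
#' one density per regime on the back-transformed (Mbp) scale with a dashed
#' line at the fitted optimum.
#'
#' @param object An [parametric_bootstrap_theta()] result.
#' @param scale `"mbp"` (back-transformed) or `"log10"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ou_bootstrap <- function(object, scale = c("mbp", "log10"), ...) {
  scale <- match.arg(scale)
  fit <- attr(object, "fit")
  vcol <- if (scale == "mbp") "theta_mbp" else "theta"
  opt <- tibble(regime = names(fit$params$theta),
                value = if (scale == "mbp") 10^unname(fit$params$theta)
                        else unname(fit$params$theta))
  ggplot(object, aes(x = .data[[vcol]], fill = .data$regime,
                     colour = .data$regime)) +
    geom_density(alpha = 0.4) +
    geom_vline(data = opt, aes(xintercept = .data$value, colour = .data$regime),
               linetype = "dashed") +
    (if (scale == "mbp") ggplot2::scale_x_log10() else NULL) +
    labs(x = if (scale == "mbp") "optimum (Mbp)" else "optimum (log10 Mbp)",
         y = "bootstrap density") +
    theme_minimal()
}

#' Plot a regime-painted tree
#'
#' Simple rectangular layout with branches coloured by regime (green LS,
#' black CC, red CS by default, matching the field's convention).
#'
#' @param object A [paint_regimes()] result.
#' @param colours Named colours per regime.
#' @param show_labels Draw tip labels (off by default; trees are large).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.regime_painting <- function(object,
                                     colours = c(LS = "#2e7d32", CC = "#212121",
                                                 CS = "#c62828"),
                                     show_labels = FALSE, ...) {
  tree <- painting_tree(object)
  n_tip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  yord <- numeric(n_tip + tree$Nnode)
  yord[seq_len(n_tip)] <- match(seq_len(n_tip),
                                tree$edge[tree$edge[, 2] <= n_tip, 2])
  for (e in rev(preorder_edges(tree))) {
    par <- tree$edge[e, 1]
    kids <- tree$edge[tree$edge[, 1] == par, 2]
    yord[par] <- mean(yord[kids])
  }
  seg <- tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 2]],
    y = yord[tree$edge[, 2]], yend = yord[tree$edge[, 2]],
    regime = object$regime)
  vert <- tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 1]],
    y = yord[tree$edge[, 1]], yend = yord[tree$edge[, 2]],
    regime = object$regime)
  p <- ggplot() +
    geom_segment(data = vert, aes(x = .data$x, xend = .data$xend,
                                  y = .data$y, yend = .data$yend,
                                  colour = .data$regime)) +
    geom_segment(data = seg, aes(x = .data$x, xend = .data$xend,
                                 y = .data$y, yend = .data$yend,
                                 colour = .data$regime)) +
    scale_colour_manual(values = colours) +
    labs(x = "relative time", y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (show_labels) {
    tips <- tibble(x = depth[seq_len(n_tip)], y = yord[seq_len(n_tip)],
                   label = tree$tip.label)
    p <- p + geom_text(data = tips, aes(x = .data$x, y = .data$y,
                                        label = .data$label),
                       hjust = -0.05, size = 2)
  }
  p
}
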