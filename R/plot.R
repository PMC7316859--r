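#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# hclust -> segment table for ggplot dendrograms (leaves at x = 1..n, y = 0)
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  seg <- vector("list", nrow(hc$merge))
  pos <- function(v) if (v < 0) c(leaf_x[[as.character(-v)]], 0)
                     else c(node_x[v], node_y[v])
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    seg[[i]] <- tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[i], node_y[i]),
      yend = c(node_y[i], node_y[i], b[2])
    )
  }
  dplyr::bind_rows(seg)
}

#' Dendrogram plot of a domain clustering
#'
#' @param object A `domain_clust` from [cluster_rows()].
#' @param label_size Leaf label text size (set 0 to hide labels).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.domain_clust <- function(object, label_size = 2.5, ...) {
  hc <- object$hclust
  seg <- hclust_segments(hc)
  leaves <- tibble(x = seq_along(hc$order), label = hc$labels[hc$order])
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_y_continuous(name = paste0(object$metric, " distance (",
                                              object$linkage, " linkage)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
  if (label_size > 0)
    p <- p + ggplot2::geom_text(data = leaves,
                                ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                                angle = 90, hjust = 1.05, size = label_size)
  p
}

#' Domain-neighborhood track plot
#'
#' One horizontal track per neighborhood; each tile is a member domain at its
#' signed ordered-domain distance from the center (position 0), colored by
#' clan (falling back to profile where clan is missing).
#'
#' @param neighborhoods Long tibble from [build_neighborhoods()].
#' @param key `"clan"` (default) or `"profile"` fill.
#' @return A ggplot.
#' @export
plot_neighborhood_tracks <- function(neighborhoods, key = c("clan", "profile")) {
  key <- match.arg(key)
  nb <- neighborhoods
  nb$fill_key <- if (key == "clan") dplyr::coalesce(nb$clan, nb$profile) else nb$profile
  ggplot2::ggplot(nb, ggplot2::aes(x = .data$signed_distance,
                                   y = .data$neighborhood,
                                   fill = .data$fill_key)) +
    ggplot2::geom_tile(color = "grey30", height = 0.8, width = 0.95) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "ordered-domain distance from center", y = NULL,
                  fill = key) +
    ggplot2::theme_minimal()
}

#' Mosaic-style plot of domains co-occurring with the center domain
#'
#' Bars are proportional to the summed inverse-square distance of each domain
#' from the domain of interest over all neighborhoods, so conserved partners
#' have the largest blocks.
#'
#' @param weights Tibble from [mosaic_weights()].
#' @param top Show only the `top` heaviest keys (default 20).
#' @return A ggplot.
#' @export
plot_mosaic <- function(weights, top = 20) {
  w <- head(weights, top)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$weight,
                                  y = stats::reorder(.data$key, .data$weight))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "summed inverse-square distance weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a neighborhood feature matrix
#'
#' @param m Feature matrix tibble from [build_feature_matrix()].
#' @return A ggplot with rows x keys tiles shaded by weight.
#' @export
plot_feature_matrix <- function(m) {
  long <- tidyr::pivot_longer(m, -"row", names_to = "key", values_to = "weight")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$key, y = .data$row,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "1/d²") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Scaled contingency heatmap of clusters vs taxonomy families
#'
#' @param mat Matrix from [contingency_scaled()].
#' @return A ggplot.
#' @export
plot_contingency <- function(mat) {
  long <- tibble(
    cluster = rep(rownames(mat), times = ncol(mat)),
    family = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$cluster,
                                     fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10", limits = c(0, 1)) +
    ggplot2::labs(x = "taxonomy family", y = "cluster",
                  fill = "count / row max") +
    ggplot2::theme_minimal()
}
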