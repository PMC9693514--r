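#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

dendro_segments <- function(x) {
  n <- length(x$labels)
  pos <- stats::setNames(seq_len(n), x$order)   # leaf -> display position
  xs <- numeric(nrow(x$merge))
  ys <- x$height
  seg <- NULL
  coord <- function(node) {
    if (node < 0) c(pos[[as.character(-node)]], 0) else c(xs[node], ys[node])
  }
  for (s in seq_len(nrow(x$merge))) {
    a <- coord(x$merge[s, 1]); b <- coord(x$merge[s, 2])
    xs[s] <- (a[1] + b[1]) / 2
    seg <- rbind(seg,
                 c(a[1], a[2], a[1], ys[s]),
                 c(b[1], b[2], b[1], ys[s]),
                 c(a[1], ys[s], b[1], ys[s]))
  }
  tibble::tibble(x = seg[, 1], y = seg[, 2], xend = seg[, 3], yend = seg[, 4])
}

#' Dendrogram of a Ward clustering
#'
#' @param object A `ward_clust`.
#' @param labels Draw leaf labels, default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ward_clust
#' @export
autoplot.ward_clust <- function(object, labels = TRUE, ...) {
  seg <- dendro_segments(object)
  leaf <- tibble::tibble(x = seq_along(object$order),
                         label = object$labels[object$order])
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::labs(y = "within-cluster SSE increase", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
  if (labels) {
    p <- p + ggplot2::scale_x_continuous(breaks = leaf$x, labels = leaf$label) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                         vjust = 0.5, size = 6))
  } else {
    p <- p + ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
  p
}

#' Two-way clustered trait heatmap
#'
#' Species-by-trait heatmap on the 0-1 scale, rows and columns ordered by
#' the two Ward dendrograms.
#'
#' @param two_way Result of [two_way_cluster()].
#' @return A ggplot.
#' @export
plot_trait_heatmap <- function(two_way) {
  mat <- two_way$matrix
  df <- tibble::as_tibble(mat, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "trait", values_to = "value") |>
    dplyr::mutate(species = factor(.data$species, levels = rownames(mat)),
                  trait = factor(.data$trait, levels = colnames(mat)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$species,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "scaled\nvalue") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplots with compact letters for a group comparison
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot; groups sharing a letter are not significantly
#'   different at the comparison's alpha.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  if (is.null(object$data)) rlang::abort("comparison carries no raw data")
  top <- max(object$data$value, na.rm = TRUE)
  pad <- 0.05 * diff(range(object$data$value, na.rm = TRUE) + c(0, 1e-9))
  lab <- dplyr::mutate(object$summary, y = top + pad)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$group, y = .data$y,
                                    label = .data$letters)) +
    ggplot2::labs(x = NULL, y = object$variable) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' Spearman rho as a tile map; non-significant pairs are crossed out.
#'
#' @param object A `brom_cor`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot brom_cor
#' @export
autoplot.brom_cor <- function(object, ...) {
  traits <- rownames(object$rho)
  df <- tibble::as_tibble(object$rho, rownames = "trait_a") |>
    tidyr::pivot_longer(-"trait_a", names_to = "trait_b", values_to = "rho") |>
    dplyr::mutate(
      trait_a = factor(.data$trait_a, levels = traits),
      trait_b = factor(.data$trait_b, levels = traits),
      ns = !object$significant[cbind(as.character(.data$trait_a),
                                     as.character(.data$trait_b))] &
        .data$trait_a != .data$trait_b
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait_a, y = .data$trait_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$ns), shape = 4,
                        size = 1.5, colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
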