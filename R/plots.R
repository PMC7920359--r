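# ggplot2 figures: the per-position fraction profile (one line per
# nucleotide with the criterion corridors drawn as horizontal bounds)
# and the annotated pairwise-distance heatmap.

#' Plot a per-position nucleotide fraction profile
#'
#' One series per nucleotide across barcode positions, with the corridor
#' bounds of each supplied criterion drawn as horizontal lines (solid
#' for the first, dashed for the second). A perfectly balanced set shows
#' four overlapping flat series at 0.25.
#'
#' @param fm A `bc_fractions` object.
#' @param criteria Optional `bc_criterion` or list of them; bounds are
#'   drawn for each.
#' @param path Optional output file; when given, the figure is saved
#'   there (format by extension: pdf/png/svg).
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_fraction_profile <- function(fm, criteria = default_criteria(),
                                  path = NULL, width = 7, height = 4) {
  stopifnot(inherits(fm, "bc_fractions"))
  if (inherits(criteria, "bc_criterion")) criteria <- list(criteria)
  p <- ggplot2::ggplot(
    fm,
    ggplot2::aes(x = .data$position, y = .data$fraction,
                 colour = .data$base)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = seq_len(attr(fm, "L"))) +
    ggplot2::coord_cartesian(ylim = c(0, max(0.5, max(fm$fraction)))) +
    ggplot2::labs(
      x = "barcode position", y = "nucleotide fraction", colour = NULL
    ) +
    ggplot2::theme_minimal()
  lt <- c("solid", "dashed", "dotted", "dotdash")
  for (i in seq_along(criteria)) {
    cr <- criteria[[i]]
    p <- p + ggplot2::geom_hline(
      yintercept = c(cr$lower, cr$upper),
      linetype = lt[(i - 1) %% length(lt) + 1], colour = "grey40"
    )
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' @export
autoplot.bc_fractions <- function(object, ...) {
  plot_fraction_profile(object, ...)
}

#' Plot a pairwise-distance heatmap
#'
#' Tile heatmap of the Hamming distance matrix with the integer
#' distance annotated in each cell; the larger the number, the less
#' likely two samples merge during demultiplexing.
#'
#' @param dm A `bc_distmat`.
#' @param path Optional output file (saved when given).
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_distance_heatmap <- function(dm, path = NULL, width = 7, height = 6) {
  stopifnot(inherits(dm, "bc_distmat"))
  df <- tidy_distmat(dm)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$id1, y = .data$id2, fill = .data$distance)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$distance), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mismatches") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' @export
autoplot.bc_distmat <- function(object, ...) {
  plot_distance_heatmap(object, ...)
}

# Long form of a distance matrix, all ordered pairs (including the
# diagonal), factor levels in panel order.
tidy_distmat <- function(dm) {
  n <- length(dm$ids)
  tibble::tibble(
    id1 = factor(rep(dm$ids, times = n), levels = dm$ids),
    id2 = factor(rep(dm$ids, each = n), levels = rev(dm$ids)),
    distance = as.integer(dm$d)
  )
}
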