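#' Plot windowed diversity along the genome
#'
#' @param windows Tibble from [nucleotide_diversity()] or
#'   [diversity_by_group()] (a `group` column is mapped to colour).
#' @return A ggplot.
#' @export
plot_diversity <- function(windows) {
  mid <- (windows$start + windows$end) / 2
  p <- ggplot2::ggplot(dplyr::mutate(windows, mid = mid / 1000),
                       ggplot2::aes(x = .data$mid, y = .data$pi))
  if ("group" %in% names(windows)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "position (kb)", y = expression(pi ~ "per site")) +
    ggplot2::theme_minimal()
}

#' Plot a diversity-reduction scan with its candidate regions
#'
#' @param ratios Tibble from [diversity_ratio_scan()].
#' @param regions Optional tibble from [candidate_regions()]; drawn as
#'   shaded spans with the cutoff as a dashed line.
#' @return A ggplot.
#' @export
plot_ratio_scan <- function(ratios, regions = NULL) {
  p <- ggplot2::ggplot(
    dplyr::mutate(ratios, mid = (.data$start + .data$end) / 2000),
    ggplot2::aes(x = .data$mid, y = .data$ratio)) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::labs(x = "position (kb)", y = expression(pi[w] / pi[c])) +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    p <- p +
      ggplot2::geom_rect(
        data = regions, inherit.aes = FALSE, alpha = 0.2, fill = "red",
        ggplot2::aes(xmin = .data$start / 1000, xmax = .data$end / 1000,
                     ymin = -Inf, ymax = Inf)) +
      ggplot2::geom_hline(yintercept = attr(regions, "cutoff"),
                          linetype = "dashed")
  }
  p
}

#' Plot ordination coordinates
#'
#' @param object A `cp_ordination`.
#' @param pm Optional population map; points are coloured by group.
#' @param ... Unused.
#' @return A ggplot of the first two axes.
#' @method autoplot cp_ordination
#' @export
autoplot.cp_ordination <- function(object, pm = NULL, ...) {
  d <- object$coordinates
  if (!is.null(pm)) d <- dplyr::left_join(d, pop_map(pm), by = "sample")
  lab <- function(i) {
    if (!is.null(object$explained)) {
      sprintf("axis %d (%.1f%%)", i, 100 * object$explained[i])
    } else sprintf("axis %d", i)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    (if (!is.null(pm)) ggplot2::geom_point(ggplot2::aes(colour = .data$group))
     else ggplot2::geom_point()) +
    ggplot2::labs(x = lab(1), y = lab(2), title = object$method) +
    ggplot2::theme_minimal()
}

#' Plot a TCS haplotype network
#'
#' Fruchterman-Reingold layout; sampled haplotypes are sized by member
#' count, inferred intermediates drawn as small open points.
#'
#' @param object A `tcs_network`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcs_network
#' @export
autoplot.tcs_network <- function(object, seed = 1, ...) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(object$graph)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(object$edges,
                            dplyr::select(nodes, from = "node", x1 = "x", y1 = "y"),
                            by = "from")
  edges <- dplyr::left_join(edges,
                            dplyr::select(nodes, to = "node", x2 = "x", y2 = "y"),
                            by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size,
                                     shape = .data$type)) +
    ggplot2::scale_shape_manual(values = c(sampled = 16, inferred = 1)) +
    ggplot2::theme_void()
}

#' Heatmap of the joint allele-frequency table
#'
#' @param tab Tibble from [joint_frequency_table()].
#' @return A ggplot.
#' @export
plot_joint_frequency <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin_i, y = .data$bin_j,
                                    fill = log10(.data$n + 1))) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "indica frequency", y = "japonica frequency",
                  fill = "log10(n+1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-locus standardised heterozygosity differences
#'
#' @param object A `cp_bottleneck`.
#' @param ... Unused.
#' @return A ggplot of DH per locus, excess loci highlighted.
#' @method autoplot cp_bottleneck
#' @export
autoplot.cp_bottleneck <- function(object, ...) {
  ggplot2::ggplot(object$loci,
                  ggplot2::aes(x = .data$pos / 1000, y = .data$DH,
                               colour = .data$excess)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "position (kb)", y = "DH",
                  title = sprintf("%s, %s model", object$group, object$model)) +
    ggplot2::theme_minimal()
}
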