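#' Draw a genetic linkage map chart
#'
#' Classic vertical-bar map figure: one bar per linkage group with markers
#' as ticks at their cM positions and labels alongside. Requires ggplot2.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param labelSize marker label text size.
#' @return a ggplot object.
#' @export
plotGeneticMap <- function(map, labelSize = 2.2) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotGeneticMap requires the 'ggplot2' package")
  tb <- mapTable(map)
  ends <- do.call(rbind, lapply(split(tb, tb$group), function(d)
    data.frame(group = d$group[1], top = min(d$position),
               bottom = max(d$position))))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ends,
                          ggplot2::aes(x = .data$group, xend = .data$group,
                                       y = .data$top, yend = .data$bottom),
                          linewidth = 2, colour = "grey70", lineend = "round") +
    ggplot2::geom_segment(data = tb,
                          ggplot2::aes(x = .data$group - 0.12,
                                       xend = .data$group + 0.12,
                                       y = .data$position,
                                       yend = .data$position)) +
    ggplot2::geom_text(data = tb,
                       ggplot2::aes(x = .data$group + 0.18,
                                    y = .data$position,
                                    label = .data$marker),
                       hjust = 0, size = labelSize) +
    ggplot2::scale_x_continuous(breaks = unique(tb$group),
                                labels = sprintf("LG%d", unique(tb$group)),
                                limits = c(0.5, max(tb$group) + 0.9)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (cM)") +
    ggplot2::theme_minimal()
}
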