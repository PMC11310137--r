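#' Plot screened alignment blocks
#'
#' Draws each alignment block as a query-interval segment per scaffold,
#' coloured by its screening status, so chain structure and flagged
#' off-target blocks are visible at a glance.
#'
#' @param screen An `hb_screen` object.
#' @return A ggplot object.
#' @export
plot_screen <- function(screen) {
  blocks <- screen$blocks
  ggplot2::ggplot(blocks,
                  ggplot2::aes(x = .data$qstart, xend = .data$qend,
                               y = .data$qname, yend = .data$qname,
                               colour = .data$status)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "scaffold position (bp)", y = NULL,
                  colour = "block status",
                  title = "Screened alignment blocks") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hb_screen <- function(object, ...) plot_screen(object)

#' Plot the edit-length profile of a mixing run
#'
#' Event-length histogram split by edit status; the correction threshold
#' separates applied events from skipped structural-scale events.
#'
#' @param mix An `hb_mix` object, or an edit tibble with a `status` column.
#' @return A ggplot object.
#' @export
plot_edit_profile <- function(mix) {
  edits <- if (inherits(mix, "hb_mix")) mix$edits else mix
  thr <- if (inherits(mix, "hb_mix")) mix$mix_cfg$indel_threshold else NULL
  p <- ggplot2::ggplot(edits, ggplot2::aes(x = .data$length,
                                           fill = .data$status)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "event length (bp)", y = "events",
                  fill = "status", title = "Edit events by length") +
    ggplot2::theme_minimal()
  if (!is.null(thr))
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed")
  p
}

#' @export
autoplot.hb_mix <- function(object, ...) plot_edit_profile(object)

#' Plot phase blocks along assembly sequences
#'
#' @param pb A [phase_blocks()] result.
#' @return A ggplot object.
#' @export
plot_phase_blocks <- function(pb) {
  ggplot2::ggplot(pb$blocks,
                  ggplot2::aes(x = .data$start, xend = .data$end,
                               y = .data$name, yend = .data$name,
                               colour = .data$hap)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "haplotype",
                  title = "Hapmer phase blocks") +
    ggplot2::theme_minimal()
}
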