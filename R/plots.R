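# ggplot2 visualisations for the main result types.

#' @export
autoplot.dg_sweep <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cutoff, y = .data$n_scaffolds)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$target[1], ymax = object$target[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_cutoff,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "binding-score cutoff (kcal/mol)",
                  y = "selected scaffolds",
                  title = "Cutoff sweep toward the scaffold target band")
}

#' @export
autoplot.embedding_map <- function(object, ...) {
  pts <- object$points
  labs <- sort(unique(pts$label))
  cols <- setNames(c("#4daf4a", "#f781bf", "#999999")[seq_along(labs)], labs)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "t-SNE 1 (normalized)", y = "t-SNE 2 (normalized)",
                  colour = NULL, title = "Chemical-space map")
}

#' Plot the buffered-disc overlap of an embedding
#'
#' Renders the two buffered collections (green / pink) and their overlap
#' (light brown) by rasterizing the disc unions.
#'
#' @param map An `embedding_map`.
#' @param resolution Raster resolution (per axis) used for display.
#' @return A ggplot object.
#' @export
plot_overlap <- function(map, resolution = 300) {
  labs <- sort(unique(map$points$label))
  stopifnot(length(labs) == 2)
  ga <- disc_union_mask(map$points[map$points$label == labs[1], ],
                        map$radius, resolution)
  gb <- disc_union_mask(map$points[map$points$label == labs[2], ],
                        map$radius, resolution)
  lo <- -2 * map$radius; hi <- 1 + 2 * map$radius
  ax <- seq(lo, hi, length.out = resolution)
  df <- expand.grid(x = ax, y = ax)
  region <- rep(NA_character_, nrow(df))
  region[as.vector(ga)] <- labs[1]
  region[as.vector(gb)] <- labs[2]
  region[as.vector(ga & gb)] <- "overlap"
  df$region <- region
  df <- df[!is.na(df$region), ]
  cols <- setNames(c("#4daf4a", "#f781bf", "#c8a165"),
                   c(labs, "overlap"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Buffered chemical-space overlap")
}

#' @export
autoplot.pipeline_report <- function(object, ...) {
  df <- tibble::tibble(stage = factor(names(object$stage_counts),
                                      levels = names(object$stage_counts)),
                       count = as.integer(object$stage_counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "records (log scale)",
                  title = "Triage funnel") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
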