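# Lightweight ggplot2 helpers for the 2D maps and quartile summaries.
# ggplot2 is a suggested dependency; these fail informatively without it.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Plot an unfolded 2D map colored by a field
#'
#' @param unfolded an `unfolded_map`.
#' @param field numeric vector or [scalar_field()] per vertex; when NULL
#'   and regions are assigned, colors show the 24 regions.
#' @param point_size plotted point size.
#' @return a ggplot object.
#' @export
plot_unfolded <- function(unfolded, field = NULL, point_size = 0.4) {
  need_ggplot()
  df <- data.frame(u = unfolded$uv[, 1], v = unfolded$uv[, 2])
  if (is.null(field) && !is.null(unfolded$region)) {
    df$value <- unfolded$region
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v,
                                          colour = .data$value)) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::labs(colour = "region")
  } else {
    df$value <- as.numeric(field)
    nm <- if (inherits(field, "scalar_field")) attr(field, "name") else "value"
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v,
                                          colour = .data$value)) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::labs(colour = nm)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot per-quartile response distributions
#'
#' Boxplot-style summary of a response across the four TAWSS quartiles,
#' mirroring a per-case quartile chart.
#'
#' @param case_table a [case_vertex_table()] output.
#' @param response column name, e.g. `"bv"`.
#' @return a ggplot object.
#' @export
plot_quartiles <- function(case_table, response = "bv") {
  need_ggplot()
  stopifnot(response %in% names(case_table), "quartile" %in% names(case_table))
  df <- data.frame(q = factor(paste0("Q", case_table$quartile),
                              levels = paste0("Q", 1:4)),
                   y = case_table[[response]])
  df <- df[stats::complete.cases(df), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$q, .data$y)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, notch = TRUE) +
    ggplot2::labs(x = "TAWSS quartile", y = response) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
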