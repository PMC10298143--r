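#' Plot read coverage across the mitochondrial genome
#'
#' @param track A tibble from [total_coverage_track()], or a
#'   `mito_basecounts` object.
#' @param value Which depth to draw: `"mean"` per cell (default) or
#'   `"sum"` over cells.
#' @return A ggplot object.
#' @export
plot_coverage <- function(track, value = c("mean", "sum")) {
  value <- match.arg(value)
  if (inherits(track, "mito_basecounts")) track <- total_coverage_track(track)
  ycol <- if (value == "mean") "mean_depth" else "sum_depth"
  ylab <- if (value == "mean") "Mean depth per cell" else "Total depth"
  ggplot2::ggplot(track, ggplot2::aes(x = .data$position, y = .data[[ycol]])) +
    ggplot2::geom_area(fill = "grey70", colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(
      x = paste0("Position on ", attr(track, "contig") %||% "mitochondrial contig", " (bp)"),
      y = ylab
    ) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D cell embedding
#'
#' @param object A `mito_embedding` tibble from [embed_cells()].
#' @param labels Optional cell-to-donor labels (data frame with
#'   `cell_id`, `donor_id`) used to colour cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mito_embedding
#' @export
autoplot.mito_embedding <- function(object, labels = NULL, ...) {
  d <- object
  if (!is.null(labels)) {
    d <- dplyr::left_join(d, labels, by = "cell_id")
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$tsne1, y = .data$tsne2,
      colour = .data$donor_id
    ))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$tsne1, y = .data$tsne2))
  }
  p + ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "Donor") +
    ggplot2::theme_minimal()
}

#' Per-donor allele-frequency distributions of selected variants
#'
#' The standard view of a heteroplasmy call: per-cell AFs of each
#' variant, grouped by donor.
#'
#' @param af A `mito_af` object.
#' @param sites Variant labels (character or tibble with `label`).
#' @param labels Cell-to-donor labels (data frame or TSV path).
#' @return A ggplot object (one facet per variant).
#' @export
plot_donor_af <- function(af, sites, labels) {
  if (is.data.frame(sites)) sites <- sites$label
  if (is.character(labels) && length(labels) == 1L) labels <- read_donor_labels(labels)
  x <- af_values(af, sites)
  d <- tibble(
    label = rep(sites, times = ncol(x)),
    cell_id = rep(colnames(x), each = length(sites)),
    allele_frequency = as.vector(x)
  ) |>
    dplyr::filter(!is.na(.data$allele_frequency)) |>
    dplyr::inner_join(labels, by = "cell_id")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$donor_id, y = .data$allele_frequency,
    colour = .data$donor_id
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Donor", y = "Alternative allele frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
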