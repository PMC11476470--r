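#' PAE heatmap for a confidence bundle
#'
#' Token-pair predicted-aligned-error heatmap (green = low error, white =
#' high, matching the usual AlphaFold presentation), with chain boundaries
#' drawn so inter-chain blocks are easy to read.
#'
#' @param object A [confidence_bundle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confidence_bundle <- function(object, ...) {
  n <- length(object$chain_ids)
  df <- tidyr::expand_grid(aligned = seq_len(n), scored = seq_len(n))
  df$pae <- as.vector(t(object$pae))  # row-major: aligned runs slow
  boundaries <- cumsum(rle(object$chain_ids)$lengths)
  boundaries <- boundaries[-length(boundaries)] + 0.5
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scored, y = .data$aligned,
                                   fill = .data$pae)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#0a7d3b", high = "white",
                                 limits = c(0, 31.75), name = "PAE (Å)") +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_hline(yintercept = boundaries, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = boundaries, linewidth = 0.2) +
    ggplot2::labs(x = "Scored residue", y = "Aligned residue") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.confidence_bundle
#' @param bundle A [confidence_bundle()].
#' @param region Region to summarise (default: all residues).
#' @export
plot_plddt_bands <- function(bundle, region = NULL) {
  if (is.null(region)) {
    region <- chain_region(bundle$chain_ids, bundle$res_ids)
  }
  bands <- plddt_bands(bundle, region)
  cols <- c("0-50" = "#d73027", "50-60" = "#fee08b", "60-80" = "#66bd63",
            "80-90" = "#4fc3f7", ">90" = "#1a41d8")
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$band, y = .data$n,
                                      fill = .data$band)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = "pLDDT band", y = "Residues") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
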