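#' Render a power heatmap and its numeric matrix
#'
#' One row per method, one cell per ranking position, colored from orange
#' (low power) through white to blue (high power) over [0, 100]. The exact
#' numeric matrix is always written as a TSV -- the TSV, not the image, is
#' the testable surface; the PNG is presentation only.
#'
#' @param curves A methods x positions matrix of power percentages (one
#'   element of [power_curves()]), or a named list of equal-length numeric
#'   curves.
#' @param tsv_path Path for the tab-delimited numeric matrix.
#' @param png_path Optional path for a PNG rendering.
#' @param main Plot title.
#' @return The curve matrix, invisibly.
#' @export
render_heatmap <- function(curves, tsv_path, png_path = NULL, main = "") {
  if (is.list(curves) && !is.matrix(curves)) {
    lens <- lengths(curves)
    if (length(unique(lens)) != 1L) {
      abort_shape("all methods must share the same number of ranking positions")
    }
    curves <- do.call(rbind, curves)
  }
  if (!is.matrix(curves) || !is.numeric(curves)) {
    abort_shape("`curves` must be a numeric matrix or list of equal-length curves")
  }
  if (any(!is.finite(curves)) || any(curves < 0 | curves > 100)) {
    abort_invalid("power percentages must lie in [0, 100]")
  }
  if (is.null(colnames(curves))) colnames(curves) <- seq_len(ncol(curves))
  utils::write.table(
    data.frame(method = rownames(curves) %||% paste0("method", seq_len(nrow(curves))),
               curves, check.names = FALSE),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 1000, height = 80 + 40 * nrow(curves))
    on.exit(grDevices::dev.off())
    pal <- grDevices::colorRampPalette(c("#E66101", "#FFFFFF", "#0571B0"))(101)
    op <- graphics::par(mar = c(4, 10, 3, 1))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    graphics::image(x = seq_len(ncol(curves)), y = seq_len(nrow(curves)),
                    z = t(curves[rev(seq_len(nrow(curves))), , drop = FALSE]),
                    zlim = c(0, 100), col = pal, axes = FALSE,
                    xlab = "ranking position", ylab = "", main = main)
    graphics::axis(1)
    graphics::axis(2, at = seq_len(nrow(curves)),
                   labels = rev(rownames(curves)), las = 2, tick = FALSE)
  }
  invisible(curves)
}
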