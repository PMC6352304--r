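#' Plot a similarity matrix as a heatmap
#'
#' Base-graphics heatmap with a diverging palette anchored at the
#' delineation threshold: pairs above the threshold (candidate conspecific
#' pairs) show in reds, pairs below in blues.
#'
#' @param x A `wgp_similarity` matrix.
#' @param threshold Anchor of the palette (percent).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @importFrom graphics image axis box
#' @importFrom grDevices colorRampPalette
#' @method plot wgp_similarity
#' @export
plot.wgp_similarity <- function(x, threshold = 96, ...) {
  m <- unclass(x)
  n <- nrow(m)
  cuts <- c(seq(min(m, 0), threshold, length.out = 33),
            seq(threshold, 100, length.out = 33)[-1])
  pal <- c(colorRampPalette(c("#2166AC", "#D1E5F0"))(32),
           colorRampPalette(c("#FDDBC7", "#B2182B"))(32))
  image(seq_len(n), seq_len(n), m[, n:1, drop = FALSE],
        col = pal, breaks = cuts, axes = FALSE, xlab = "", ylab = "", ...)
  axis(1, at = seq_len(n), labels = rownames(m), las = 2, cex.axis = 0.6)
  axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
       cex.axis = 0.6)
  box()
  invisible(x)
}

#' Plot an ROC sweep
#'
#' Sensitivity against 100 - specificity along the threshold grid.
#'
#' @param x A `wgp_roc` data.frame from [roc_sweep()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @importFrom graphics plot.default lines points
#' @method plot wgp_roc
#' @export
plot.wgp_roc <- function(x, ...) {
  xx <- 100 - x$specificity
  plot.default(xx, x$sensitivity, type = "b", pch = 16,
               xlab = "100 - specificity (%)", ylab = "sensitivity (%)",
               ...)
  invisible(x)
}
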