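# Simple base-graphics renderings of the standard MR displays.

#' Forest plot of odds ratios across traits or methods
#'
#' @param labels row labels.
#' @param or,lo,hi odds ratios with 95% confidence bounds.
#' @param xlab x-axis label.
#' @param main title.
#' @return invisibly NULL; draws on the current device.
#' @export
plotForest <- function(labels, or, lo, hi,
                       xlab = "Odds ratio (95% CI)", main = "") {
  n <- length(labels)
  y <- rev(seq_len(n))
  xr <- range(c(lo, hi, 1), finite = TRUE)
  graphics::par(mar = c(4, 10, 2, 2))
  graphics::plot(or, y, pch = 15, xlim = xr, ylim = c(0.5, n + 0.5),
                 yaxt = "n", ylab = "", xlab = xlab, main = main, log = "x")
  graphics::segments(lo, y, hi, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = labels, las = 1, cex.axis = 0.8)
  invisible(NULL)
}

#' Scatter plot of per-variant effects with the fitted slope
#'
#' Draws the SNP-outcome coefficients against the SNP-exposure coefficients
#' with 95% error bars on the outcome side and the causal-slope line through
#' the origin.
#'
#' @param variants per-variant table from [variantEffectTable()].
#' @param main title.
#' @return invisibly NULL; draws on the current device.
#' @export
plotScatter <- function(variants, main = "") {
  graphics::par(mar = c(4, 4, 2, 2))
  graphics::plot(variants$beta_exposure, variants$beta_outcome,
                 pch = 1, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome (log OR)", main = main)
  graphics::segments(variants$beta_exposure, variants$ci_low,
                     variants$beta_exposure, variants$ci_high)
  graphics::abline(a = 0, b = variants$slope[1], col = "red")
  graphics::abline(h = 0, lty = 3, col = "grey60")
  invisible(NULL)
}
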