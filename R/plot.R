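#' Display a slice with optional mask overlays
#'
#' Base-graphics viewer: grayscale HU image with mask boundaries drawn on
#' top.
#'
#' @param image HU matrix.
#' @param masks optional named list of 0/1 matrices to outline.
#' @param main plot title.
#' @param cols outline colors, recycled over masks.
#' @return Invisibly, `NULL`.
#' @export
plot_slice <- function(image, masks = list(), main = "",
                       cols = c("red", "cyan", "yellow", "green")) {
  rng <- range(image)
  z <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  # image() draws column-major from bottom; transpose/flip for raster order
  graphics::image(t(z[nrow(z):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, main = main, useRaster = TRUE)
  n <- nrow(image); m <- ncol(image)
  for (i in seq_along(masks)) {
    b <- which(extract_boundary(masks[[i]]) == 1L, arr.ind = TRUE)
    if (nrow(b) == 0L) next
    graphics::points((b[, 2] - 0.5) / m, 1 - (b[, 1] - 0.5) / n,
                     pch = ".", cex = 1.5,
                     col = cols[(i - 1L) %% length(cols) + 1L])
  }
  invisible(NULL)
}

#' Plot the block grid and defective-block flags over a mask
#'
#' @param mask the lung mask the statistics were computed on.
#' @param stats a [detect_defective_blocks()] result.
#' @return Invisibly, `NULL`.
#' @export
plot_fractal_stats <- function(mask, stats) {
  plot_slice(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
             main = "boundary blocks (red = defective)")
  g <- stats$grid
  n <- nrow(mask); m <- ncol(mask)
  xs <- (g$col_breaks - 1) / m
  ys <- 1 - (g$row_breaks - 1) / n
  graphics::abline(v = xs, h = ys, col = "gray60", lty = 3)
  for (bi in seq_len(g$n_rows)) {
    for (bj in seq_len(g$n_cols)) {
      if (!stats$is_defective[bi, bj]) next
      graphics::rect(xs[bj], ys[bi + 1], xs[bj + 1], ys[bi],
                     border = "red", lwd = 2)
    }
  }
  invisible(NULL)
}
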