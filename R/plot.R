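# Quick-look plots for detection results (base graphics).

#' Display a detection result over its source image
#'
#' @param x an `axon_detection`, `puncta_detection` or `cell_detection`.
#' @param image optional background image (2-D matrix) to draw under the
#'   detection overlay.
#' @param ... passed to [graphics::image()].
#' @name plot-detections
NULL

show_background <- function(image, dim_hw) {
  if (is.null(image)) image <- matrix(0, dim_hw[1], dim_hw[2])
  graphics::image(
    t(image)[, rev(seq_len(nrow(image)))],
    col = grDevices::gray.colors(256, start = 0, end = 1),
    axes = FALSE, useRaster = TRUE, asp = nrow(image) / ncol(image)
  )
  invisible(dim(image))
}

#' @rdname plot-detections
#' @export
plot.axon_detection <- function(x, image = NULL, ...) {
  d <- dim(x$mask)
  show_background(if (is.null(image)) x$mask * 1 else image, d)
  sk <- which(x$skeleton, arr.ind = TRUE)
  if (nrow(sk))
    graphics::points((sk[, 2] - 1) / (d[2] - 1),
                     1 - (sk[, 1] - 1) / (d[1] - 1),
                     pch = ".", col = "red")
  invisible(x)
}

#' @rdname plot-detections
#' @export
plot.puncta_detection <- function(x, image = NULL, ...) {
  if (is.null(image)) stop("supply the image the puncta were detected on")
  d <- dim(image)
  show_background(image, d)
  if (x$count)
    graphics::points(x$centers_px$x / (d[2] - 1),
                     1 - x$centers_px$y / (d[1] - 1),
                     col = "green", cex = 0.8)
  invisible(x)
}

#' @rdname plot-detections
#' @export
plot.cell_detection <- function(x, image = NULL, ...) {
  if (is.null(image)) stop("supply the image the cells were detected on")
  d <- dim(image)
  show_background(image, d)
  if (x$count)
    graphics::points(x$components$x / (d[2] - 1),
                     1 - x$components$y / (d[1] - 1),
                     col = "cyan", cex = 1.2)
  invisible(x)
}
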