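#' Single-channel image stack with physical calibration
#'
#' The unit every detector consumes after projection: a 3-D intensity
#' volume (rows = y, columns = x, slices = z) together with the lateral
#' pixel size and the axial step, both in micrometres.
#'
#' @param data numeric matrix (promoted to one plane) or 3-D array of
#'   nonnegative intensities, indexed `[y, x, z]`.
#' @param pixel_size_um lateral calibration, micrometres per pixel.
#' @param z_step_um axial spacing between planes in micrometres.
#' @return an object of class `image_stack`.
#' @examples
#' st <- image_stack(array(runif(4 * 4 * 3), c(4, 4, 3)), pixel_size_um = 0.62)
#' dim(st$data)
#' @export
image_stack <- function(data, pixel_size_um, z_step_um = 1) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (z_step_um <= 0) stop("z_step_um must be positive")
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d plane(s), %.3g um/px, dz = %.3g um\n",
    d[1], d[2], d[3], x$pixel_size_um, x$z_step_um
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Maximum-intensity projection of a stack
#'
#' Collapses a Z-stack to a single plane by the per-pixel maximum across
#' planes, the standard reduction applied before 2-D quantification.
#'
#' @param stack an [image_stack] (a bare matrix or 3-D array is accepted).
#' @return a numeric matrix with attribute `pixel_size_um` carried over
#'   when the input is an `image_stack`.
#' @export
max_project <- function(stack) {
  px <- NULL
  if (inherits(stack, "image_stack")) {
    px <- stack$pixel_size_um
    stack <- stack$data
  }
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 1L) stop("stack must contain at least one plane")
  out <- stack[, , 1L]
  if (d[3] > 1L) for (k in 2:d[3]) out <- pmax(out, stack[, , k])
  if (!is.null(px)) attr(out, "pixel_size_um") <- px
  out
}
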