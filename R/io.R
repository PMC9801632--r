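# File interchange: multi-page float TIFF stacks, ROI polygons as JSON,
# CSV tables stamped with the configuration hash.

# Intensities are divided by this before writing (the TIFF writer stores
# [0, 1] floats) and multiplied back on reading; exact for the simulator's
# dynamic range at 32-bit float precision.
INTENSITY_SCALE <- 65536

#' Write an image stack as a multi-page 32-bit float TIFF
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  planes <- lapply(seq_len(dim(stack$data)[3]),
                   function(z) stack$data[, , z] / INTENSITY_SCALE)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF back into an image stack
#'
#' @param path TIFF file written by [write_image_stack()] (or any
#'   single-channel multi-page TIFF; values are rescaled by the package's
#'   fixed intensity scale).
#' @param pixel_size_um,z_step_um calibration to attach (TIFF pages carry
#'   no physical units here).
#' @return an [image_stack].
#' @export
read_image_stack <- function(path, pixel_size_um, z_step_um = 1) {
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop("failed to read TIFF '", path, "': ",
                             conditionMessage(e))
  )
  if (is.matrix(planes)) planes <- list(planes)
  arr <- array(0, c(dim(planes[[1]]), length(planes)))
  for (z in seq_along(planes)) arr[, , z] <- planes[[z]] * INTENSITY_SCALE
  image_stack(arr, pixel_size_um, z_step_um)
}

#' Write an ROI polygon as JSON
#'
#' Schema: `{region, bregma_um, vertices_px: [[x, y], ...]}` with 0-based
#' pixel coordinates.
#'
#' @param polygon n x 2 vertex matrix (x, y).
#' @param region region label.
#' @param bregma_um anterior-posterior coordinate of the section (um).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(polygon, region, bregma_um, path) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2)
  obj <- list(region = region, bregma_um = bregma_um,
              vertices_px = unname(polygon))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI polygon from JSON
#'
#' @param path JSON file in the schema of [write_roi()].
#' @return list with `region`, `bregma_um` and `vertices_px` (matrix).
#' @export
read_roi <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("failed to read ROI JSON '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(obj$vertices_px)) stop("ROI JSON '", path, "' has no vertices_px")
  v <- obj$vertices_px
  if (!is.matrix(v)) v <- do.call(rbind, v)
  list(region = obj$region, bregma_um = obj$bregma_um,
       vertices_px = unname(as.matrix(v)))
}

#' Per-section files written by the cohort generator
#' @noRd
write_section_files <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- sprintf("%s_%s_%02d", rec$mouse_id, rec$region, rec$section_index)
  if (!is.null(rec$red))
    write_image_stack(rec$red, file.path(dir, paste0(base, "_red.tif")))
  if (!is.null(rec$green))
    write_image_stack(rec$green, file.path(dir, paste0(base, "_green.tif")))
  write_roi(rec$roi_px, rec$region, rec$bregma_um,
            file.path(dir, paste0(base, "_roi.json")))
  truth <- rec$truth
  jsonlite::write_json(
    list(region = truth$region_label,
         total_axon_length_um = truth$total_axon_length_um,
         n_boutons = if (is.null(truth$boutons)) 0L else nrow(truth$boutons),
         n_somata = if (is.null(truth$somata)) 0L else nrow(truth$somata),
         bouton_centers_um = if (!is.null(truth$boutons))
           unname(as.matrix(truth$boutons[, c("x_um", "y_um")])),
         soma_table = truth$somata),
    file.path(dir, paste0(base, "_truth.json")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(base)
}

#' Write a table as CSV stamped with the producing config hash
#' @noRd
write_table_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline (skipping the hash stamp)
#'
#' @param path CSV file whose first line is a `# config_hash:` comment.
#' @return data frame; the hash is attached as attribute `config_hash`.
#' @export
read_pipeline_table <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- sub("^# config_hash:\\s*", "", first)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- hash
  df
}
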