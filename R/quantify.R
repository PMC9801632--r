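# Quantification: ROI handling, matched-section bookkeeping, cell-count
# normalized densities, and inter-region log2 intensity ratios.

#' Zero pixels outside an ROI polygon
#'
#' Pixels whose centers fall outside the polygon are set to zero, the
#' convention used before automated quantification of a hand-drawn region
#' contour.  Coordinates are 0-based pixel indices; a pixel belongs to the
#' ROI when its center is inside the polygon (even-odd rule), which makes
#' areas bit-reproducible.
#'
#' @param image 2-D numeric matrix.
#' @param polygon n x 2 matrix of vertices (x = column, y = row, 0-based).
#' @param pixel_size_um lateral calibration used for the reported area.
#' @return list with `image` (masked copy), `mask` (logical matrix) and
#'   `area_um2` (ROI area inside the frame).
#' @export
apply_roi <- function(image, polygon, pixel_size_um) {
  stopifnot(is.matrix(image))
  mask <- polygon_mask(polygon, dim(image))
  out <- image
  out[!mask] <- 0
  list(image = out, mask = mask,
       area_um2 = sum(mask) * pixel_size_um^2)
}

#' Section positions usable for comparison across all mice
#'
#' Serial sections are matched by ordinal position; a position missing for
#' any mouse is dropped for every mouse, so all per-mouse totals are built
#' from an identical set of anatomical locations.
#'
#' @param manifest data frame with at least `mouse_id`, `section_index`
#'   and optionally `region` (only the given region is considered).
#' @param region region label to match within (default `"BLA"`).
#' @return sorted integer vector of section positions present for every
#'   mouse; errors when no position is shared.
#' @export
match_sections <- function(manifest, region = "BLA") {
  m <- manifest
  if (!is.null(m$region)) m <- m[m$region == region, , drop = FALSE]
  if (nrow(m) == 0L) stop("manifest contains no sections for region ", region)
  by_mouse <- split(m$section_index, m$mouse_id)
  common <- sort(Reduce(intersect, by_mouse))
  if (length(common) == 0L)
    stop("no section position is present for every mouse")
  as.integer(common)
}

#' Per-mouse totals and cell-count-normalized densities
#'
#' Axon density is the total number of skeleton pixels summed over matched
#' sections divided by the number of red-labeled cells at the injection
#' site; bouton density is the summed bouton count divided by the number
#' of green-labeled cells.  The region size is approximated by summing the
#' ROI cross-sectional areas over the same sections.
#'
#' @param section_table data frame with one row per matched section of one
#'   mouse: columns `axon_pixels`, `bouton_count`, `roi_area_um2` (missing
#'   measures may be NA).
#' @param vta_counts named vector or list with `tdtomato` and `sypgfp`
#'   labeled-cell counts for this mouse.
#' @return one-row data frame (`axon_pixels_total`, `bouton_count_total`,
#'   `tdtomato_cells_vta`, `sypgfp_cells_vta`, `bla_area_total_um2`,
#'   `axon_density`, `bouton_density`).
#' @export
summarize_mouse <- function(section_table, vta_counts) {
  td <- as.numeric(vta_counts[["tdtomato"]])
  sg <- as.numeric(vta_counts[["sypgfp"]])
  ax <- sum(section_table$axon_pixels)
  bt <- sum(section_table$bouton_count)
  if ((!is.na(ax) && td <= 0) || (!is.na(bt) && sg <= 0))
    stop("density undefined: zero labeled cells at the injection site")
  data.frame(
    axon_pixels_total = ax,
    bouton_count_total = bt,
    tdtomato_cells_vta = td,
    sypgfp_cells_vta = sg,
    bla_area_total_um2 = sum(section_table$roi_area_um2),
    axon_density = ax / td,
    bouton_density = bt / sg
  )
}

#' Express per-mouse values as percentages of the male-group mean
#'
#' @param values numeric vector, one value per mouse.
#' @param sex character vector (`"male"`/`"female"`) aligned with `values`.
#' @return numeric vector of percentages; the male group always averages
#'   exactly 100.
#' @export
percent_of_male_mean <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  if (!any(sex == "male")) stop("at least one male value is required")
  ref <- mean(values[sex == "male"])
  if (!is.finite(ref) || ref == 0) stop("male group mean is zero")
  100 * values / ref
}

#' Inter-region labeling intensity as log2 ratios against the NAC average
#'
#' Each mouse's per-region mean intensity is first normalized to its own
#' injection-site (VTA) mean intensity, controlling for viral expression
#' differences between brains; the normalized values are then divided by
#' the cohort-average (geometric mean) normalized NAC intensity and
#' expressed as log2 ratios.  The geometric mean is the natural average on
#' a log scale and makes the NAC values average exactly zero across mice
#' by construction.
#'
#' @param region_table data frame with `mouse_id`, `region`,
#'   `mean_intensity` (mean raw pixel value in the region ROI).
#' @param vta_table data frame with `mouse_id`, `vta_mean_intensity`.
#' @return `region_table` with added columns `vta_mean_intensity`,
#'   `ratio_vs_vta` and `log2_ratio_vs_nac`.
#' @export
log2_region_ratio <- function(region_table, vta_table) {
  stopifnot(all(c("mouse_id", "region", "mean_intensity") %in%
                  names(region_table)),
            all(c("mouse_id", "vta_mean_intensity") %in% names(vta_table)))
  if (any(region_table$mean_intensity <= 0) ||
      any(vta_table$vta_mean_intensity <= 0))
    stop("all intensities must be positive")
  out <- merge(region_table, vta_table, by = "mouse_id", sort = FALSE)
  out$ratio_vs_vta <- out$mean_intensity / out$vta_mean_intensity
  nac <- out$ratio_vs_vta[out$region == "NAC"]
  if (length(nac) == 0L) stop("no NAC rows to normalize against")
  out$log2_ratio_vs_nac <- log2(out$ratio_vs_vta) - mean(log2(nac))
  out
}

#' Mean intensity inside an ROI mask
#' @param image 2-D numeric matrix.
#' @param mask logical matrix.
#' @return mean of the pixels where `mask` is TRUE.
#' @export
roi_mean_intensity <- function(image, mask) {
  if (!any(mask)) stop("empty ROI")
  mean(image[mask])
}
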