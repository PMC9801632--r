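# End-to-end orchestration: simulate a cohort, detect structures on every
# section, quantify cell-count-normalized densities, and compare sexes.

#' Pipeline configuration
#'
#' Bundles the simulator configuration, cohort design and detection
#' parameters under a magnification mode.  The mode preset fixes the
#' pixel size (0.62 um at 10x, 0.25 um at 25x) and the 5 SD / 7 SD
#' detection thresholds unless explicitly overridden.
#'
#' @param mode `"10x"` or `"25x"`.
#' @param cohort a [cohort_spec].
#' @param sim optional [simulation_config]; default is built for the mode.
#' @param detect optional list of [detection_params] (`axon`, `bouton`,
#'   `cell`); default is [detection_preset()] for the mode.
#' @param measures which densities to compute (`"axon"`, `"bouton"`).
#' @param seed master seed; overrides the seeds inside `sim` and `cohort`.
#' @param out_dir optional directory for CSV outputs (and, with
#'   `write_images = TRUE`, per-section TIFF/JSON files).
#' @param write_images write per-section image and truth files too.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("10x", "25x"),
                            cohort = cohort_spec(),
                            sim = NULL,
                            detect = NULL,
                            measures = c("axon", "bouton"),
                            seed = 1L,
                            out_dir = NULL,
                            write_images = FALSE) {
  mode <- match.arg(mode)
  measures <- match.arg(measures, several.ok = TRUE)
  preset <- detection_preset(mode)
  if (is.null(sim)) sim <- simulation_config(pixel_size_um = preset$pixel_size_um)
  if (is.null(detect)) detect <- preset[c("axon", "bouton", "cell")]
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(sim, "simulation_config"),
            all(vapply(detect, inherits, logical(1), "detection_params")))
  sim$seed <- as.integer(seed)
  cohort$seed <- as.integer(seed)
  structure(
    list(mode = mode, cohort = cohort, sim = sim, detect = detect,
         measures = measures, seed = as.integer(seed), out_dir = out_dir,
         write_images = isTRUE(write_images)),
    class = "pipeline_config"
  )
}

#' Hash of a configuration object
#'
#' MD5 over the canonical JSON serialization; stamped into every output
#' table so results can be traced to the configuration that produced them.
#'
#' @param config any serializable configuration object.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config, digits = 15), tmp)
  unname(tools::md5sum(tmp))
}

#' Measure one rendered section (internal pipeline stage)
#' @noRd
measure_section <- function(rec, detect, measures) {
  px <- rec$pixel_size_um
  ref <- if (!is.null(rec$red)) rec$red else rec$green
  proj_ref <- max_project(ref)
  roi <- apply_roi(proj_ref, rec$roi_px, px)
  row <- data.frame(
    mouse_id = rec$mouse_id, sex = rec$sex, region = rec$region,
    section_index = rec$section_index, bregma_um = rec$bregma_um,
    roi_area_um2 = roi$area_um2,
    axon_pixels = NA_real_, bouton_count = NA_real_,
    cells_red = NA_real_, cells_green = NA_real_,
    stringsAsFactors = FALSE
  )
  if (rec$region == "VTA") {
    if (!is.null(rec$red)) {
      red_m <- apply_roi(max_project(rec$red), rec$roi_px, px)
      row$cells_red <- detect_cells(red_m$image, red_m$mask, detect$cell, px)$count
    }
    if (!is.null(rec$green)) {
      green_m <- if (is.null(rec$red)) roi
      else apply_roi(max_project(rec$green), rec$roi_px, px)
      row$cells_green <- detect_cells(green_m$image, green_m$mask,
                                      detect$cell, px)$count
    }
    return(row)
  }
  if ("axon" %in% measures && !is.null(rec$red)) {
    row$axon_pixels <-
      detect_axons(roi$image, roi$mask, detect$axon, px)$axon_pixel_count
  }
  if ("bouton" %in% measures && !is.null(rec$green)) {
    green_m <- if (is.null(rec$red)) roi
    else apply_roi(max_project(rec$green), rec$roi_px, px)
    row$bouton_count <-
      detect_boutons(green_m$image, green_m$mask, detect$bouton, px)$count
  }
  row
}

#' Run the full simulate-detect-quantify-compare pipeline
#'
#' Generates the cohort section by section (bounded memory), detects the
#' requested structures on each max-projected, ROI-masked section, counts
#' labeled cells at the injection site per channel, forms per-mouse
#' densities normalized by those counts over matched sections, expresses
#' them as percentages of the male-group mean, and runs the between-sex
#' comparisons.  Fully deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config].
#' @return object of class `axodens_pipeline`: `sections` (per-section
#'   measurements), `mouse_summary`, `stats` (list of `stat_result`),
#'   `manifest`, `matched_positions`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config[c("mode", "cohort", "sim", "detect",
                               "measures", "seed")])
  channels <- c(if ("axon" %in% config$measures) "red",
                if ("bouton" %in% config$measures) "green")
  cohort <- generate_cohort(
    config$cohort, config$sim, channels = channels,
    section_fun = function(rec) measure_section(rec, config$detect,
                                                config$measures)
  )
  sections <- do.call(rbind, c(cohort$sections, cohort$vta_sections))
  bla <- sections[sections$region == "BLA", , drop = FALSE]
  vta <- sections[sections$region == "VTA", , drop = FALSE]
  pos <- match_sections(sections, region = "BLA")
  bla <- bla[bla$section_index %in% pos, , drop = FALSE]

  mice <- cohort$mice
  summaries <- lapply(seq_len(nrow(mice)), function(i) {
    id <- mice$mouse_id[i]
    st <- bla[bla$mouse_id == id, , drop = FALSE]
    vt <- vta[vta$mouse_id == id, , drop = FALSE]
    cbind(
      data.frame(mouse_id = id, sex = mice$sex[i],
                 estrous_stage = mice$estrous_stage[i],
                 stringsAsFactors = FALSE),
      summarize_mouse(st, list(tdtomato = sum(vt$cells_red),
                               sypgfp = sum(vt$cells_green)))
    )
  })
  ms <- do.call(rbind, summaries)
  if ("axon" %in% config$measures)
    ms$axon_density_pct_male <- percent_of_male_mean(ms$axon_density, ms$sex)
  if ("bouton" %in% config$measures)
    ms$bouton_density_pct_male <- percent_of_male_mean(ms$bouton_density, ms$sex)
  ms$bla_area_pct_male <- percent_of_male_mean(ms$bla_area_total_um2, ms$sex)

  stats_out <- list()
  male <- ms$sex == "male"
  if (sum(male) >= 2L && sum(!male) >= 2L) {
    if ("axon" %in% config$measures)
      stats_out$axon_density <- two_sample_t(
        ms$axon_density_pct_male[male], ms$axon_density_pct_male[!male])
    if ("bouton" %in% config$measures)
      stats_out$bouton_density <- two_sample_t(
        ms$bouton_density_pct_male[male], ms$bouton_density_pct_male[!male])
    stats_out$bla_size <- two_sample_t(
      ms$bla_area_pct_male[male], ms$bla_area_pct_male[!male])
  }

  bundle <- structure(
    list(sections = sections, mouse_summary = ms, stats = stats_out,
         manifest = cohort$manifest, matched_positions = pos,
         mice_truth = cohort$mice,
         config = config, config_hash = hash),
    class = "axodens_pipeline"
  )
  if (!is.null(config$out_dir)) write_tables(bundle, config$out_dir)
  bundle
}

#' @export
print.axodens_pipeline <- function(x, ...) {
  ms <- x$mouse_summary
  cat(sprintf("<axodens_pipeline> %s mode, %d mice, %d matched sections/mouse\n",
              x$config$mode, nrow(ms), length(x$matched_positions)))
  cat(sprintf("  config hash %s\n", x$config_hash))
  for (sx in c("male", "female")) {
    r <- ms[ms$sex == sx, , drop = FALSE]
    if ("bouton_density_pct_male" %in% names(ms))
      cat(sprintf("  %s bouton density: %.1f%% of male mean (n = %d)\n",
                  sx, mean(r$bouton_density_pct_male), nrow(r)))
  }
  for (nm in names(x$stats)) {
    cat(sprintf("  [%s] ", nm))
    print(x$stats[[nm]])
  }
  invisible(x)
}

#' Write the pipeline's result tables as hash-stamped CSVs
#'
#' Writes `manifest.csv`, `sections.csv`, `mouse_summary.csv` and
#' `stats.csv` into `dir`, each with a `# config_hash:` first line.
#'
#' @param bundle an `axodens_pipeline` result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "axodens_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- bundle$config_hash
  write_table_with_hash(bundle$manifest, file.path(dir, "manifest.csv"), h)
  write_table_with_hash(bundle$sections, file.path(dir, "sections.csv"), h)
  write_table_with_hash(bundle$mouse_summary,
                        file.path(dir, "mouse_summary.csv"), h)
  stats_df <- do.call(rbind, lapply(names(bundle$stats), function(nm) {
    s <- bundle$stats[[nm]]
    data.frame(measure = nm, test = s$test_name,
               statistic = s$statistic,
               df1 = s$df[1], df2 = if (length(s$df) > 1) s$df[2] else NA,
               p_value = s$p_value, effect_size = s$effect_size,
               effect_size_name = s$effect_size_name,
               correction = s$correction, stringsAsFactors = FALSE)
  }))
  write_table_with_hash(stats_df, file.path(dir, "stats.csv"), h)
  invisible(dir)
}
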