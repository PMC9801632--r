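# Whole-cohort simulation: per-mouse labeling efficiency, matched serial
# sections through the target region, and injection-site sections whose
# labeled-cell count scales with the same efficiency multiplier.

#' Cohort design for the simulator
#'
#' Describes a two-sex cohort: group sizes, sex-specific bouton linear
#' densities, a per-mouse lognormal labeling-efficiency multiplier shared
#' by both channels (labeling efficiency is a property of the injection,
#' not of the reporter), serial-section counts and region-dependent axon
#' densities.
#'
#' @param n_mice_per_group named integer vector `c(male = ..., female = ...)`.
#' @param group_bouton_density named vector, boutons per um of axon per sex.
#' @param mouse_effect_cv coefficient of variation of the per-mouse
#'   lognormal labeling multiplier (0 disables it).
#' @param n_sections_per_mouse serial sections through the target region.
#' @param region_axon_density named vector, axons per um^2 of field for
#'   `NAC`, `BLA`, `PFC` (density order NAC > BLA > PFC as in the labeled
#'   brain).
#' @param base_vta_cells mean labeled-soma count at the injection site for
#'   a multiplier of 1.
#' @param vta_image_size_px field size for injection-site sections (soma
#'   packing needs a larger field than the target-region crops).
#' @param estrous_stages stages assigned cyclically to female mice.
#' @param seed master seed for the whole cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice_per_group = c(male = 5L, female = 5L),
                        group_bouton_density = c(male = 0.16, female = 0.08),
                        mouse_effect_cv = 0.2,
                        n_sections_per_mouse = 20L,
                        region_axon_density = c(NAC = 0.004, BLA = 0.0005,
                                                PFC = 0.000125),
                        base_vta_cells = 150L,
                        vta_image_size_px = c(1024L, 1024L),
                        estrous_stages = "estrus",
                        seed = 1L) {
  stopifnot(
    all(c("male", "female") %in% names(n_mice_per_group)),
    all(n_mice_per_group >= 1L),
    all(c("male", "female") %in% names(group_bouton_density)),
    all(group_bouton_density >= 0),
    mouse_effect_cv >= 0, n_sections_per_mouse >= 1L,
    all(region_axon_density >= 0), base_vta_cells >= 1L,
    all(estrous_stages %in% c("proestrus", "estrus", "metestrus", "diestrus"))
  )
  structure(
    list(
      n_mice_per_group = n_mice_per_group,
      group_bouton_density = group_bouton_density,
      mouse_effect_cv = mouse_effect_cv,
      n_sections_per_mouse = as.integer(n_sections_per_mouse),
      region_axon_density = region_axon_density,
      base_vta_cells = as.integer(base_vta_cells),
      vta_image_size_px = as.integer(vta_image_size_px),
      estrous_stages = estrous_stages,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Simulate a full cohort of sectioned, imaged brains
#'
#' For every mouse: one labeling multiplier is drawn and applied to both
#' channels; `n_sections_per_mouse` target-region (BLA) sections are
#' generated with axon counts Poisson around
#' `region density x field area x multiplier` and sex-specific bouton
#' densities; injection-site (VTA) sections carry
#' `round(base_vta_cells x multiplier)` labeled somata.  Section bregma
#' coordinates span -3.0 to -1.0 mm (BLA) and -3.6 to -3.1 mm (VTA).
#'
#' When `section_fun` is supplied it is applied to each section record as
#' soon as it is rendered and only its value is kept, so arbitrarily large
#' cohorts can be processed in bounded memory.
#'
#' @param spec a [cohort_spec].
#' @param config a [simulation_config] used for the target-region sections;
#'   the injection-site sections reuse it with `spec$vta_image_size_px`.
#' @param section_fun optional function applied to each section record.
#' @param out_dir optional directory; when given, per-section TIFFs, ground
#'   truth JSON sidecars and `manifest.csv` are written there.
#' @param channels channels to render (subset of `c("red", "green")`);
#'   restricting to one channel roughly halves the rendering cost.
#' @return list with `mice` (per-mouse table including the multiplier and
#'   exact ground-truth totals), `manifest`, `sections` and `vta_sections`
#'   (records or `section_fun` values), `spec`, `config`.
#'
#' Section records are lists with fields `mouse_id`, `sex`,
#' `estrous_stage`, `region`, `section_index`, `bregma_um`, `red`, `green`
#' ([image_stack]s), `roi_px` (polygon), `truth` ([ground_truth]) and
#' `pixel_size_um`.
#' @export
generate_cohort <- function(spec, config, section_fun = NULL, out_dir = NULL,
                            channels = c("red", "green")) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(config, "simulation_config"))
  channels <- match.arg(channels, c("red", "green"), several.ok = TRUE)
  n_m <- spec$n_mice_per_group[["male"]]
  n_f <- spec$n_mice_per_group[["female"]]
  mouse_id <- c(sprintf("m%02d", seq_len(n_m)), sprintf("f%02d", seq_len(n_f)))
  sex <- c(rep("male", n_m), rep("female", n_f))
  n_mice <- length(mouse_id)
  estrous <- rep(NA_character_, n_mice)
  estrous[sex == "female"] <- rep(spec$estrous_stages, length.out = n_f)
  ns <- spec$n_sections_per_mouse
  n_vta <- 1L

  seeds <- derive_seeds(spec$seed, n_mice * (ns + n_vta) + 1L)
  mult <- with_seed(seeds[length(seeds)], {
    if (spec$mouse_effect_cv == 0) rep(1, n_mice)
    else {
      s <- sqrt(log(1 + spec$mouse_effect_cv^2))
      exp(stats::rnorm(n_mice, -s^2 / 2, s))
    }
  })

  field_area_um2 <- prod(config$image_size_px) * config$pixel_size_um^2
  bla_bregma <- seq(-3000, -1000, length.out = ns)
  vta_bregma <- seq(-3600, -3100, length.out = n_vta)

  vta_config <- config
  vta_config$image_size_px <- spec$vta_image_size_px

  sections <- vector("list", n_mice * ns)
  vta_sections <- vector("list", n_mice * n_vta)
  manifest <- vector("list", n_mice * (ns + n_vta))
  true_len <- true_btn <- true_cells <- numeric(n_mice)

  si <- 0L; vi <- 0L; mi <- 0L
  for (m in seq_len(n_mice)) {
    dens_b <- spec$group_bouton_density[[sex[m]]]
    lambda_ax <- spec$region_axon_density[["BLA"]] * field_area_um2 * mult[m]
    for (s in seq_len(ns)) {
      sd_seed <- seeds[(m - 1L) * (ns + n_vta) + s]
      cfg <- config
      cfg$n_axons <- with_seed(sd_seed, stats::rpois(1L, lambda_ax))
      ax <- generate_axon_paths(cfg, seed = sd_seed + 1L)
      btn <- place_boutons(ax, dens_b, seed = sd_seed + 2L)
      truth <- ground_truth(ax$paths, ax$path_axon, boutons = btn,
                            region_label = "BLA")
      imgs <- render_section(truth, cfg, channels = channels,
                             seed = sd_seed + 3L)
      roi <- make_roi_polygon(cfg$image_size_px, sd_seed + 4L)
      rec <- list(
        mouse_id = mouse_id[m], sex = sex[m], estrous_stage = estrous[m],
        region = "BLA", section_index = s, bregma_um = bla_bregma[s],
        red = imgs$red, green = imgs$green, roi_px = roi, truth = truth,
        pixel_size_um = cfg$pixel_size_um
      )
      true_len[m] <- true_len[m] + truth$total_axon_length_um
      true_btn[m] <- true_btn[m] + nrow(btn)
      si <- si + 1L
      if (!is.null(out_dir)) write_section_files(rec, out_dir)
      sections[[si]] <- if (is.null(section_fun)) rec else section_fun(rec)
      mi <- mi + 1L
      manifest[[mi]] <- data.frame(
        mouse_id = mouse_id[m], sex = sex[m], estrous_stage = estrous[m],
        region = "BLA", section_index = s, bregma_um = bla_bregma[s],
        stringsAsFactors = FALSE
      )
    }
    for (v in seq_len(n_vta)) {
      sd_seed <- seeds[(m - 1L) * (ns + n_vta) + ns + v]
      n_cells <- max(1L, round(spec$base_vta_cells * mult[m] / n_vta))
      vta <- generate_vta_section(n_cells, vta_config, seed = sd_seed,
                                  channels = channels)
      roi <- make_roi_polygon(vta_config$image_size_px, sd_seed + 1L,
                              radius_frac = 0.48, jitter = c(0.97, 1))
      rec <- list(
        mouse_id = mouse_id[m], sex = sex[m], estrous_stage = estrous[m],
        region = "VTA", section_index = v, bregma_um = vta_bregma[v],
        red = vta$red, green = vta$green, roi_px = roi, truth = vta$truth,
        pixel_size_um = vta_config$pixel_size_um
      )
      true_cells[m] <- true_cells[m] + n_cells
      vi <- vi + 1L
      if (!is.null(out_dir)) write_section_files(rec, out_dir)
      vta_sections[[vi]] <- if (is.null(section_fun)) rec else section_fun(rec)
      mi <- mi + 1L
      manifest[[mi]] <- data.frame(
        mouse_id = mouse_id[m], sex = sex[m], estrous_stage = estrous[m],
        region = "VTA", section_index = v, bregma_um = vta_bregma[v],
        stringsAsFactors = FALSE
      )
    }
  }

  mice <- data.frame(
    mouse_id = mouse_id, sex = sex, estrous_stage = estrous,
    multiplier = mult,
    bouton_rate_per_um = spec$group_bouton_density[sex],
    true_axon_length_um = true_len,
    true_bouton_count = true_btn,
    true_vta_cells = true_cells,
    stringsAsFactors = FALSE
  )
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  list(mice = mice, manifest = manifest, sections = sections,
       vta_sections = vta_sections, spec = spec, config = config)
}
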