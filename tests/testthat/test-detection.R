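# Detectors: background estimation, ridge/LoG responses, thresholds,
# skeleton contract, oracle equivalence, and accuracy against simulator
# ground truth.

test_that("sigma-clipped background estimation is accurate and robust", {
  img <- matrix(100, 64, 64)
  bg <- estimate_background(img)
  expect_equal(unname(bg), c(100, 0))

  set.seed(42)
  img <- matrix(rnorm(512^2, 50, 5), 512, 512)
  bg <- estimate_background(img)
  expect_lt(abs(bg[["mean"]] - 50) / 50, 0.02)
  expect_lt(abs(bg[["sd"]] - 5) / 5, 0.02)

  # 1% extreme bright contamination barely moves the estimate
  idx <- sample(length(img), round(0.01 * length(img)))
  img[idx] <- 10000
  bg <- estimate_background(img)
  expect_lt(abs(bg[["mean"]] - 50) / 50, 0.05)
  expect_lt(abs(bg[["sd"]] - 5) / 5, 0.05)

  expect_error(estimate_background(img, matrix(FALSE, 512, 512)), "empty ROI")
})

test_that("axon detector recovers a straight bar length and rejects pure noise", {
  # noiseless 3-px-wide bar of length 150 px
  img <- matrix(0, 60, 180)
  img[30:32, 16:165] <- 100
  roi <- matrix(TRUE, 60, 180)
  det <- detect_axons(img, roi, detection_params(threshold_sd = 5),
                      pixel_size_um = 1)
  expect_lt(abs(det$axon_pixel_count - 150), 3.5)
  expect_true(all(det$mask[!roi] == FALSE))

  # pure noise: false-positive skeleton below 0.1% of ROI pixels
  set.seed(1)
  noise <- matrix(rnorm(256^2, 20, 3), 256, 256)
  roi <- matrix(TRUE, 256, 256)
  det <- detect_axons(noise, roi, detection_params(threshold_sd = 5),
                      pixel_size_um = 0.62)
  expect_lt(det$axon_pixel_count, 0.001 * sum(roi))
})

test_that("detected skeleton length tracks simulator ground truth", {
  cfg <- simulation_config(image_size_px = c(256L, 256L), pixel_size_um = 0.62,
                           z_planes = 3L, n_axons = 12L,
                           bouton_linear_density_per_um = 0, seed = 31L)
  ax <- generate_axon_paths(cfg)
  truth <- ground_truth(ax$paths, ax$path_axon)
  img <- max_project(render_section(truth, cfg, channels = "red")$red)
  roi <- matrix(TRUE, 256, 256)
  det <- detect_axons(img, roi, detection_params(threshold_sd = 5), 0.62)
  est_um <- det$axon_pixel_count * 0.62
  expect_lt(abs(est_um - truth$total_axon_length_um) /
              truth$total_axon_length_um, 0.15)
})

test_that("skeletons are one pixel wide (no 2x2 foreground block)", {
  for (seed in c(31L, 32L, 33L)) {
    cfg <- simulation_config(image_size_px = c(128L, 128L), pixel_size_um = 0.62,
                             z_planes = 2L, n_axons = 8L, seed = seed)
    ax <- generate_axon_paths(cfg)
    truth <- ground_truth(ax$paths, ax$path_axon)
    img <- max_project(render_section(truth, cfg, channels = "red")$red)
    det <- detect_axons(img, matrix(TRUE, 128, 128),
                        detection_params(threshold_sd = 5), 0.62)
    sk <- det$skeleton
    blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    expect_false(any(blocks))
    expect_true(all(det$skeleton <= det$mask))
  }
})

test_that("bouton detector resolves spots and splits touching pairs", {
  px <- 0.25
  cfg <- simulation_config(image_size_px = c(96L, 96L), pixel_size_um = px,
                           z_planes = 1L, psf_sigma_um = 0.4,
                           background_mean = 5, background_sd = 1,
                           noise_model = "gaussian", seed = 3L)
  pp <- detection_params(threshold_sd = 7)
  roi <- matrix(TRUE, 96, 96)
  sigma_px <- pp$log_sigma_um / px

  one <- data.frame(x_um = 12.1, y_um = 11.3, path = NA_integer_)
  img <- max_project(render_section(ground_truth(boutons = one), cfg)$green)
  det <- detect_boutons(img, roi, pp, px)
  expect_identical(det$count, 1L)
  expect_lt(abs(det$centers_px$x - one$x_um / px), 1.01)
  expect_lt(abs(det$centers_px$y - one$y_um / px), 1.01)

  # two spots 4 sigma apart resolve; 0.5 sigma apart merge
  sep4 <- 4 * sigma_px * px
  two_far <- data.frame(x_um = c(10, 10 + sep4), y_um = c(10, 10),
                        path = NA_integer_)
  img <- max_project(render_section(ground_truth(boutons = two_far), cfg)$green)
  expect_identical(detect_boutons(img, roi, pp, px)$count, 2L)

  two_near <- data.frame(x_um = c(10, 10 + 0.5 * sigma_px * px),
                         y_um = c(10, 10), path = NA_integer_)
  img <- max_project(render_section(ground_truth(boutons = two_near), cfg)$green)
  expect_identical(detect_boutons(img, roi, pp, px)$count, 1L)
})

test_that("bouton counts match ground truth within 10% at working SNR", {
  cfg <- hires_config(bouton_amplitude = 200, psf_sigma_um = 0.4)
  # 28 parallel axons 112 um long, 4 um apart: ~3100 um of axon, so the
  # bouton spacing stays well above the 1 um resolution/separation limit
  truth <- parallel_line_truth(28L, 112, 4, 0.06, seed = 17L)
  expect_gt(nrow(truth$boutons), 150)
  img <- max_project(render_section(truth, cfg, channels = "green")$green)
  roi <- matrix(TRUE, 512, 512)
  det <- detect_boutons(img, roi, detection_params(threshold_sd = 7), 0.25)
  expect_lt(abs(det$count - nrow(truth$boutons)) / nrow(truth$boutons), 0.10)
})

test_that("bouton and cell detection achieve recall and precision >= 0.9", {
  cfg <- hires_config(bouton_amplitude = 250, psf_sigma_um = 0.6)
  truth <- parallel_line_truth(16L, 112, 7, 0.08, seed = 23L)
  img <- max_project(render_section(truth, cfg, channels = "green")$green)
  det <- detect_boutons(img, matrix(TRUE, 512, 512),
                        detection_params(threshold_sd = 7), 0.25)
  tx <- truth$boutons$x_um / 0.25
  ty <- truth$boutons$y_um / 0.25
  d2 <- outer(det$centers_px$x, tx, "-")^2 + outer(det$centers_px$y, ty, "-")^2
  recall <- mean(sqrt(apply(d2, 2, min)) < 3)
  precision <- mean(sqrt(apply(d2, 1, min)) < 3)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)

  vcfg <- simulation_config(image_size_px = c(256L, 256L), pixel_size_um = 0.62,
                            z_planes = 3L, seed = 5L)
  vta <- generate_vta_section(20L, vcfg, seed = 6L)
  det <- detect_cells(max_project(vta$red), matrix(TRUE, 256, 256),
                      detection_params(threshold_sd = 3), 0.62)
  sx <- vta$truth$somata$x_um / 0.62
  sy <- vta$truth$somata$y_um / 0.62
  d2 <- outer(det$components$x, sx, "-")^2 + outer(det$components$y, sy, "-")^2
  expect_gte(mean(sqrt(apply(d2, 2, min)) < 5), 0.9)  # recall
  expect_gte(mean(sqrt(apply(d2, 1, min)) < 5), 0.9)  # precision
})

test_that("cell detector applies the area gate", {
  px <- 0.62
  cfg <- simulation_config(image_size_px = c(128L, 128L), pixel_size_um = px,
                           z_planes = 1L, background_sd = 1,
                           noise_model = "gaussian", seed = 9L)
  roi <- matrix(TRUE, 128, 128)
  pp <- detection_params(threshold_sd = 3)

  mk <- function(area) ground_truth(
    somata = data.frame(x_um = 40, y_um = 38, area_um2 = area),
    region_label = "VTA")
  img <- max_project(render_section(mk(100), cfg)$red)
  expect_identical(detect_cells(img, roi, pp, px)$count, 1L)

  # 30 um^2 is below the 49 um^2 limit: removed
  img <- max_project(render_section(mk(30), cfg)$red)
  expect_identical(detect_cells(img, roi, pp, px)$count, 0L)

  # 12 separated discs are each found once with matching centers
  vcfg <- simulation_config(image_size_px = c(256L, 256L), pixel_size_um = px,
                            z_planes = 1L, background_sd = 1,
                            noise_model = "gaussian", seed = 10L)
  vta <- generate_vta_section(12L, vcfg, seed = 11L)
  det <- detect_cells(max_project(vta$red), matrix(TRUE, 256, 256), pp, px)
  expect_identical(det$count, 12L)
  sx <- vta$truth$somata$x_um / px; sy <- vta$truth$somata$y_um / px
  d2 <- outer(det$components$x, sx, "-")^2 + outer(det$components$y, sy, "-")^2
  expect_true(all(sqrt(apply(d2, 2, min)) < 5))
})

test_that("raising the threshold never increases any detection count", {
  cfg <- small_config(n_axons = 10L, seed = 41L)
  ax <- generate_axon_paths(cfg)
  truth <- ground_truth(ax$paths, ax$path_axon,
                        boutons = place_boutons(ax, 0.15, seed = 42L))
  imgs <- render_section(truth, cfg)
  red <- max_project(imgs$red); green <- max_project(imgs$green)
  roi <- matrix(TRUE, 96, 96)
  thresholds <- c(3, 4, 5, 6, 7, 9)
  ax_dets <- lapply(thresholds, function(k)
    detect_axons(red, roi, detection_params(threshold_sd = k), 0.62))
  mask_px <- vapply(ax_dets, function(d) sum(d$mask), numeric(1))
  skel_px <- vapply(ax_dets, function(d) d$axon_pixel_count, numeric(1))
  bt_counts <- vapply(thresholds, function(k)
    detect_boutons(green, roi, detection_params(threshold_sd = k), 0.62)$count,
    numeric(1))
  # the binary mask is strictly nested as the threshold rises; the thinned
  # skeleton tracks it up to small rerouting fluctuations of the medial line
  expect_true(all(diff(mask_px) <= 0))
  expect_true(all(diff(skel_px) <= 0.02 * skel_px[-length(skel_px)] + 1))
  expect_true(all(diff(bt_counts) <= 0))

  vcfg <- simulation_config(image_size_px = c(160L, 160L), pixel_size_um = 0.62,
                            z_planes = 1L, seed = 12L)
  vta <- generate_vta_section(8L, vcfg, seed = 13L)
  vimg <- max_project(vta$red)
  vroi <- matrix(TRUE, 160, 160)
  cell_counts <- vapply(c(2, 3, 5, 8), function(k)
    detect_cells(vimg, vroi, detection_params(threshold_sd = k), 0.62)$count,
    numeric(1))
  expect_true(all(diff(cell_counts) <= 0))
})

test_that("detections are invariant to a global intensity shift", {
  cfg <- small_config(n_axons = 8L, seed = 51L)
  ax <- generate_axon_paths(cfg)
  truth <- ground_truth(ax$paths, ax$path_axon,
                        boutons = place_boutons(ax, 0.12, seed = 52L))
  imgs <- render_section(truth, cfg)
  red <- max_project(imgs$red); green <- max_project(imgs$green)
  roi <- matrix(TRUE, 96, 96)
  pa <- detection_params(threshold_sd = 5)
  a1 <- detect_axons(red, roi, pa, 0.62)
  a2 <- detect_axons(red + 137.5, roi, pa, 0.62)
  expect_identical(a1$skeleton, a2$skeleton)
  b1 <- detect_boutons(green, roi, pa, 0.62)
  b2 <- detect_boutons(green + 137.5, roi, pa, 0.62)
  expect_identical(b1$centers_px, b2$centers_px)
})

test_that("component labeling and maxima splitting match brute-force oracles", {
  set.seed(77)
  for (rep in 1:3) {
    resp <- matrix(rnorm(48 * 48), 48, 48)
    resp <- axodens:::gaussian_blur(resp, 1.2)
    mask <- resp > quantile(resp, 0.9)

    lab_pkg <- axodens:::label_components(mask)
    lab_or <- oracle_label(mask)
    # same partition: label images agree up to renumbering
    expect_identical(lab_pkg > 0, lab_or > 0)
    key <- paste(lab_pkg[mask], lab_or[mask])
    expect_identical(length(unique(key)), length(unique(lab_pkg[mask])))
    expect_identical(length(unique(key)), length(unique(lab_or[mask])))

    for (sep in c(2, 3.5)) {
      got <- axodens:::regional_maxima(resp, mask, sep)
      want <- oracle_maxima(resp, mask, sep)
      expect_identical(got[order(got$x, got$y), , drop = FALSE],
                       want[order(want$x, want$y), , drop = FALSE],
                       ignore_attr = TRUE)
    }
  }
})
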