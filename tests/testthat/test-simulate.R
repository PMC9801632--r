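# Synthetic section simulator: geometry, Poisson bouton statistics,
# image formation, determinism.

test_that("axon path generation handles edge cases and conserves length", {
  cfg <- small_config(n_axons = 0L)
  out <- generate_axon_paths(cfg)
  expect_identical(out$paths, list())
  expect_identical(out$total_length_um, 0)

  expect_error(generate_axon_paths(small_config(), region_size_um = c(0, 50)),
               "positive area")

  # a straight line forced across a 100 um field keeps exactly 100 um
  pts <- cbind(c(-20, 120), c(50, 50))
  clipped <- axodens:::clip_polyline_rect(pts, c(0, 100), c(0, 100))
  expect_length(clipped, 1L)
  expect_equal(axodens:::polyline_length(clipped[[1]]), 100)

  # returned total equals an independent re-summation of segment lengths
  out <- generate_axon_paths(small_config(n_axons = 50L), seed = 3L)
  resum <- sum(vapply(out$paths, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1)))
  expect_equal(out$total_length_um, resum, tolerance = 1e-9)
  expect_length(out$path_axon, length(out$paths))

  # all vertices inside the field
  w <- 96 * 0.62
  for (p in out$paths) {
    expect_true(all(p[, 1] >= -1e-9 & p[, 1] <= w + 1e-9))
    expect_true(all(p[, 2] >= -1e-9 & p[, 2] <= w + 1e-9))
  }
})

test_that("straight-axon mode (infinite heading concentration) gives straight paths", {
  cfg <- small_config(n_axons = 3L, axon_kappa = Inf)
  out <- generate_axon_paths(cfg, seed = 5L)
  for (p in out$paths) {
    # chord length equals arc length for a straight polyline
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    expect_equal(axodens:::polyline_length(p), chord, tolerance = 1e-9)
  }
})

test_that("bouton placement is a Poisson process along the axon arc", {
  path <- list(cbind(c(0, 1000), c(5, 5)))  # one straight 1000 um axon
  expect_identical(nrow(place_boutons(path, 0, seed = 1)), 0L)

  counts <- vapply(1:400, function(s)
    nrow(place_boutons(path, 0.1, seed = s)), numeric(1))
  # mean 100, SE of the mean over 400 draws = sqrt(100)/20 = 0.5
  expect_lt(abs(mean(counts) - 100), 3 * 0.5)
  # Poisson variance ~ mean
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.25)

  # every bouton lies on its axon
  out <- generate_axon_paths(small_config(), seed = 2L)
  btn <- place_boutons(out, 0.2, seed = 9L)
  expect_gt(nrow(btn), 0)
  for (i in seq_len(nrow(btn)))
    expect_lt(oracle_dist_to_paths(btn$x_um[i], btn$y_um[i], out$paths), 1e-6)
})

test_that("rendering: background, bouton placement accuracy, determinism", {
  cfg <- small_config(noise_model = "gaussian", background_sd = 0)
  empty <- ground_truth()
  imgs <- render_section(empty, cfg)
  expect_true(all(imgs$red$data == cfg$background_mean))
  expect_true(all(imgs$green$data == cfg$background_mean))

  # single bouton, no noise: green argmax within 1 px of the true center
  btn <- data.frame(x_um = 31.1, y_um = 24.7, path = NA_integer_)
  tr <- ground_truth(boutons = btn)
  img <- render_section(tr, cfg)$green
  proj <- max_project(img)
  am <- which(proj == max(proj), arr.ind = TRUE)[1, ]
  expect_lt(abs((am["col"] - 1) - btn$x_um / 0.62), 1.01)
  expect_lt(abs((am["row"] - 1) - btn$y_um / 0.62), 1.01)

  # bit-identical re-render under the same seed
  cfg2 <- small_config()
  ax <- generate_axon_paths(cfg2, seed = 4L)
  tr2 <- ground_truth(ax$paths, ax$path_axon,
                      boutons = place_boutons(ax, 0.1, seed = 5L))
  a <- render_section(tr2, cfg2)
  b <- render_section(tr2, cfg2)
  expect_identical(a$red$data, b$red$data)
  expect_identical(a$green$data, b$green$data)

  # PSF wider than the field errors
  tiny <- simulation_config(image_size_px = c(8L, 8L), pixel_size_um = 0.5,
                            psf_sigma_um = 4, z_planes = 1L)
  expect_error(render_section(empty, tiny), "PSF")
})

test_that("noise-free rendering is an exact convolution of the scene", {
  px <- 0.5
  cfg <- simulation_config(image_size_px = c(24L, 24L), pixel_size_um = px,
                           z_planes = 1L, psf_sigma_um = 0.8,
                           background_mean = 7, background_sd = 0,
                           noise_model = "gaussian", bouton_amplitude = 90,
                           bouton_diameter_um = 1.2)
  btn <- data.frame(x_um = c(5.3, 7.9), y_um = c(6.1, 4.2),
                    path = NA_integer_)
  rendered <- max_project(render_section(ground_truth(boutons = btn), cfg)$green)

  # independent scene + direct-summation convolution, replicated borders
  sigma_spot <- cfg$bouton_diameter_um / 2.355 / px
  scene <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24) {
    x <- j - 1; y <- i - 1
    scene[i, j] <- sum(cfg$bouton_amplitude *
      exp(-((x - btn$x_um / px)^2 + (y - btn$y_um / px)^2) / (2 * sigma_spot^2)))
  }
  s_psf <- cfg$psf_sigma_um / px
  r <- max(1L, ceiling(4 * s_psf))
  k1 <- exp(-(-r:r)^2 / (2 * s_psf^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  conv <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(24, max(1, i + di)); jj <- min(24, max(1, j + dj))
      acc <- acc + k2[di + r + 1, dj + r + 1] * scene[ii, jj]
    }
    conv[i, j] <- acc + cfg$background_mean
  }
  expect_equal(rendered, conv, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("injection-site sections place gated, non-overlapping somata", {
  cfg <- simulation_config(image_size_px = c(200L, 200L), pixel_size_um = 0.62,
                           z_planes = 3L, noise_model = "gaussian")
  out0 <- generate_vta_section(0L, cfg, seed = 1L)
  expect_identical(nrow(out0$truth$somata), 0L)

  out <- generate_vta_section(25L, cfg, seed = 2L)
  s <- out$truth$somata
  expect_identical(nrow(s), 25L)
  expect_true(all(s$area_um2 >= 49 & s$area_um2 <= 200))
  r <- sqrt(s$area_um2 / pi)
  d <- as.matrix(dist(cbind(s$x_um, s$y_um)))
  for (i in 1:24) for (j in (i + 1):25)
    expect_gt(d[i, j], r[i] + r[j])

  # impossible packing request errors out
  tiny <- simulation_config(image_size_px = c(40L, 40L), pixel_size_um = 0.62,
                            z_planes = 1L)
  expect_error(generate_vta_section(200L, tiny, seed = 3L), "place")
})

test_that("cohort generation is reproducible and encodes the designed sex effect", {
  spec <- cohort_spec(
    n_mice_per_group = c(male = 2L, female = 2L),
    group_bouton_density = c(male = 0.16, female = 0.08),
    mouse_effect_cv = 0.3, n_sections_per_mouse = 2L,
    base_vta_cells = 12L, vta_image_size_px = c(128L, 128L), seed = 7L)
  cfg <- small_config()
  a <- generate_cohort(spec, cfg)
  b <- generate_cohort(spec, cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$sections[[1]]$red$data, b$sections[[1]]$red$data)
  expect_identical(a$mice, b$mice)

  # designed female:male bouton rate ratio is exactly one half
  rates <- tapply(a$mice$bouton_rate_per_um, a$mice$sex, unique)
  expect_identical(unname(rates[["female"]] / rates[["male"]]), 0.5)

  # with no mouse effect and equal densities the designed ratio is exactly 1
  spec0 <- cohort_spec(
    n_mice_per_group = c(male = 2L, female = 2L),
    group_bouton_density = c(male = 0.1, female = 0.1),
    mouse_effect_cv = 0, n_sections_per_mouse = 1L,
    base_vta_cells = 8L, vta_image_size_px = c(128L, 128L), seed = 3L)
  m0 <- generate_cohort(spec0, cfg)$mice
  expect_true(all(m0$multiplier == 1))
  r0 <- tapply(m0$bouton_rate_per_um, m0$sex, unique)
  expect_identical(unname(r0[["female"]] / r0[["male"]]), 1)

  # manifest covers every mouse and region
  expect_setequal(unique(a$manifest$region), c("BLA", "VTA"))
  expect_identical(nrow(a$manifest), 4L * 3L)  # 2 BLA + 1 VTA per mouse

  # per-mouse multiplier is shared by structures and cells: realized
  # bouton totals track multiplier x rate within Poisson error
  expect_true(all(a$mice$true_vta_cells ==
                    pmax(1, round(12L * a$mice$multiplier))))
})
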