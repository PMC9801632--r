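# Synthetic two-channel section simulator with exact ground truth.
#
# Emulates viral labeling of dopaminergic projections: a red cytosolic
# reporter filling curvilinear axons, a green synaptic-vesicle reporter
# concentrated in ~1 um boutons along them, and labeled somata at the
# injection site.  Every generator is a pure function of (config, seed),
# and returns the geometry it rendered so detectors can be scored against
# exact truth.

#' Simulator configuration
#'
#' Physical and optical parameters of the synthetic microscope.  Defaults
#' describe the wide-field ("10x") acquisition mode: 0.62 um/px, ten
#' 1-um-spaced z planes, moderate labeling density and shot + read noise.
#'
#' @param image_size_px integer pair `c(height, width)` in pixels.
#' @param pixel_size_um lateral calibration (um/pixel); 0.62 for the 10x
#'   mode, 0.25 for the 25x mode.
#' @param z_planes,z_step_um number of z planes and their spacing (um).
#' @param psf_sigma_um Gaussian PSF sigma (um).
#' @param axon_width_um rendered axon tube width (um).
#' @param n_axons number of axons per field.
#' @param axon_intensity peak axon intensity (arbitrary counts).
#' @param axon_step_um,axon_kappa step length and von Mises heading
#'   concentration of the persistent random walk generating axon paths;
#'   larger `axon_kappa` means straighter axons (`Inf` = straight lines).
#' @param bouton_linear_density_per_um mean boutons per um of axon.
#' @param bouton_amplitude peak bouton intensity in the green channel.
#' @param bouton_diameter_um bouton FWHM (um).
#' @param bouton_red_fraction fraction of `axon_intensity` at which boutons
#'   also appear in the red channel (cytosolic fill makes boutons faintly
#'   visible in red, which is what makes single-channel thresholding hard).
#' @param soma_area_range_um2 admissible soma areas `c(low, high)` (um^2).
#' @param soma_intensity rendered soma intensity.
#' @param background_mean,background_sd background level and read-noise SD.
#' @param noise_model `"poisson_gaussian"` (shot + read noise) or
#'   `"gaussian"` (additive only).
#' @param seed integer seed making the scene reproducible.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(image_size_px = c(256L, 256L),
                              pixel_size_um = 0.62,
                              z_planes = 10L,
                              z_step_um = 1,
                              psf_sigma_um = 0.6,
                              axon_width_um = 0.75,
                              n_axons = 30L,
                              axon_intensity = 150,
                              axon_step_um = 2,
                              axon_kappa = 20,
                              bouton_linear_density_per_um = 0.16,
                              bouton_amplitude = 150,
                              bouton_diameter_um = 1,
                              bouton_red_fraction = 0.3,
                              soma_area_range_um2 = c(49, 200),
                              soma_intensity = 120,
                              background_mean = 20,
                              background_sd = 2,
                              noise_model = c("poisson_gaussian", "gaussian"),
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  image_size_px <- as.integer(image_size_px)
  stopifnot(
    length(image_size_px) == 2L, all(image_size_px >= 8L),
    pixel_size_um > 0, z_planes >= 1L, z_step_um > 0, psf_sigma_um > 0,
    axon_width_um > 0, n_axons >= 0L, axon_intensity > 0, axon_step_um > 0,
    axon_kappa > 0, bouton_linear_density_per_um >= 0, bouton_amplitude > 0,
    bouton_diameter_um > 0, bouton_red_fraction >= 0,
    length(soma_area_range_um2) == 2L,
    soma_area_range_um2[1] < soma_area_range_um2[2],
    soma_area_range_um2[1] > 0, soma_intensity > 0,
    background_mean >= 0, background_sd >= 0
  )
  structure(
    list(
      image_size_px = image_size_px, pixel_size_um = pixel_size_um,
      z_planes = as.integer(z_planes), z_step_um = z_step_um,
      psf_sigma_um = psf_sigma_um, axon_width_um = axon_width_um,
      n_axons = as.integer(n_axons), axon_intensity = axon_intensity,
      axon_step_um = axon_step_um, axon_kappa = axon_kappa,
      bouton_linear_density_per_um = bouton_linear_density_per_um,
      bouton_amplitude = bouton_amplitude,
      bouton_diameter_um = bouton_diameter_um,
      bouton_red_fraction = bouton_red_fraction,
      soma_area_range_um2 = soma_area_range_um2,
      soma_intensity = soma_intensity,
      background_mean = background_mean, background_sd = background_sd,
      noise_model = noise_model, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Ground truth for one simulated section
#'
#' Exact geometry the renderer drew: axon polylines (um coordinates), the
#' clipped total arc length, bouton centers, somata, and the region label.
#' Serves as the oracle for every detector.
#'
#' @param axon_paths list of n x 2 matrices (x_um, y_um).
#' @param path_axon integer vector mapping each polyline to its parent axon
#'   (clipping can split one axon into several polylines).
#' @param boutons data frame with `x_um`, `y_um`, `path` (polyline index).
#' @param somata data frame with `x_um`, `y_um`, `area_um2`.
#' @param region_label one of `"BLA"`, `"NAC"`, `"PFC"`, `"VTA"`, `"other"`.
#' @return an object of class `ground_truth`; `total_axon_length_um` is
#'   recomputed from the polylines so it always satisfies the conservation
#'   invariant.
#' @export
ground_truth <- function(axon_paths = list(), path_axon = integer(0),
                         boutons = NULL, somata = NULL,
                         region_label = c("BLA", "NAC", "PFC", "VTA", "other")) {
  region_label <- match.arg(region_label)
  total <- sum(vapply(axon_paths, polyline_length, numeric(1)))
  structure(
    list(
      axon_paths = axon_paths,
      path_axon = as.integer(path_axon),
      total_axon_length_um = total,
      boutons = boutons,
      somata = somata,
      region_label = region_label
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s: %d polyline(s), %.1f um of axon, %d bouton(s), %d soma(ta)\n",
    x$region_label, length(x$axon_paths), x$total_axon_length_um,
    if (is.null(x$boutons)) 0L else nrow(x$boutons),
    if (is.null(x$somata)) 0L else nrow(x$somata)
  ))
  invisible(x)
}

#' von Mises deviates (Best-Fisher rejection sampler)
#' @noRd
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out
}

#' Clip one segment to a rectangle (Liang-Barsky); NULL if fully outside
#' @noRd
clip_segment_rect <- function(p, q, xlim, ylim) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lims <- if (k == 1) xlim else ylim
    for (s in 1:2) {
      if (s == 1) { pk <- -d[k]; qk <- p[k] - lims[1] }
      else        { pk <-  d[k]; qk <- lims[2] - p[k] }
      if (abs(pk) < .Machine$double.eps) {
        if (qk < 0) return(NULL)
      } else {
        t <- qk / pk
        if (pk < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
        else        { if (t < t0) return(NULL); if (t < t1) t1 <- t }
      }
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}

#' Clip a polyline to a rectangle, splitting where it leaves the field
#' @noRd
clip_polyline_rect <- function(pts, xlim, ylim) {
  out <- list()
  cur <- NULL
  for (s in seq_len(nrow(pts) - 1L)) {
    seg <- clip_segment_rect(pts[s, ], pts[s + 1L, ], xlim, ylim)
    if (is.null(seg) || polyline_length(seg) < 1e-12) {
      if (!is.null(cur) && nrow(cur) >= 2L) out[[length(out) + 1L]] <- cur
      cur <- NULL
      next
    }
    if (!is.null(cur) && sum(abs(cur[nrow(cur), ] - seg[1L, ])) < 1e-9) {
      cur <- rbind(cur, seg[2L, ])
    } else {
      if (!is.null(cur) && nrow(cur) >= 2L) out[[length(out) + 1L]] <- cur
      cur <- seg
    }
  }
  if (!is.null(cur) && nrow(cur) >= 2L) out[[length(out) + 1L]] <- cur
  out
}

#' Generate axon centerlines as persistent random walks
#'
#' Axons start uniformly in the field with an isotropic initial heading and
#' take fixed-length steps whose heading increments follow a von Mises
#' distribution (concentration `axon_kappa`); paths are clipped exactly to
#' the field so the returned arc length is the length actually in view.
#'
#' @param config a [simulation_config].
#' @param region_size_um optional `c(width, height)` of the field in um;
#'   defaults to the configured image extent.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `paths` (list of n x 2 um-coordinate matrices),
#'   `path_axon` (parent axon per polyline) and `total_length_um`.
#' @export
generate_axon_paths <- function(config, region_size_um = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(region_size_um))
    region_size_um <- rev(config$image_size_px) * config$pixel_size_um
  if (any(region_size_um <= 0)) stop("region must have positive area")
  w <- region_size_um[1]; h <- region_size_um[2]
  if (config$n_axons == 0L)
    return(list(paths = list(), path_axon = integer(0), total_length_um = 0))
  with_seed(seed, {
    paths <- list()
    path_axon <- integer(0)
    step <- config$axon_step_um
    n_steps <- ceiling(2 * max(w, h) / step)
    for (ax in seq_len(config$n_axons)) {
      start <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
      theta0 <- stats::runif(1, 0, 2 * pi)
      dth <- rvonmises(n_steps, config$axon_kappa)
      theta <- theta0 + cumsum(dth)
      pts <- rbind(
        start,
        cbind(start[1] + cumsum(step * cos(theta)),
              start[2] + cumsum(step * sin(theta)))
      )
      clipped <- clip_polyline_rect(pts, c(0, w), c(0, h))
      for (p in clipped) {
        paths[[length(paths) + 1L]] <- p
        path_axon <- c(path_axon, ax)
      }
    }
    list(
      paths = paths,
      path_axon = path_axon,
      total_length_um = sum(vapply(paths, polyline_length, numeric(1)))
    )
  })
}

#' Place synaptic boutons along axon paths
#'
#' A homogeneous Poisson process along the summed arc length: the count is
#' Poisson with mean `linear_density * total_length` and positions are
#' uniform in arc length, then mapped back onto the polylines.
#'
#' @param paths the list returned by [generate_axon_paths()] (or a bare
#'   list of polyline matrices).
#' @param linear_density mean boutons per um of axon (>= 0).
#' @param seed RNG seed.
#' @return data frame with `x_um`, `y_um`, `path` (index of the polyline
#'   the bouton sits on).
#' @export
place_boutons <- function(paths, linear_density, seed = 1L) {
  if (is.list(paths) && !is.null(paths$paths)) paths <- paths$paths
  stopifnot(linear_density >= 0)
  seg_tab <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (nrow(p) < 2L) return(NULL)
    d <- sqrt(rowSums(diff(p)^2))
    cbind(path = i, seg = seq_along(d), len = d,
          x0 = p[-nrow(p), 1], y0 = p[-nrow(p), 2],
          x1 = p[-1, 1], y1 = p[-1, 2])
  }))
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), path = integer(0))
  if (is.null(seg_tab) || nrow(seg_tab) == 0L) return(empty)
  total <- sum(seg_tab[, "len"])
  if (total <= 0 || linear_density == 0) return(empty)
  with_seed(seed, {
    n <- stats::rpois(1L, linear_density * total)
    if (n == 0L) return(empty)
    s <- sort(stats::runif(n, 0, total))
    ends <- cumsum(seg_tab[, "len"])
    idx <- findInterval(s, ends, left.open = TRUE) + 1L
    idx[idx > nrow(seg_tab)] <- nrow(seg_tab)
    frac <- (s - (ends[idx] - seg_tab[idx, "len"])) / seg_tab[idx, "len"]
    data.frame(
      x_um = seg_tab[idx, "x0"] + frac * (seg_tab[idx, "x1"] - seg_tab[idx, "x0"]),
      y_um = seg_tab[idx, "y0"] + frac * (seg_tab[idx, "y1"] - seg_tab[idx, "y0"]),
      path = as.integer(seg_tab[idx, "path"])
    )
  })
}

# ---- rasterization ------------------------------------------------------

#' Paint tubes of given half-width along polylines into a plane.
#' Coordinates in pixels (0-based centers); values are set with pmax so
#' crossing axons do not add up.  Loops internally so the plane matrix is
#' modified without repeated whole-array copies.
#' @noRd
raster_tubes <- function(plane, paths_px, halfwidth_px, value) {
  h <- nrow(plane); w <- ncol(plane)
  # floor at ~0.71 px so a thin tube still hits an 8-connected pixel chain
  hw <- max(halfwidth_px, 0.71)
  for (pts_px in paths_px) {
    for (s in seq_len(nrow(pts_px) - 1L)) {
      a <- pts_px[s, ]; b <- pts_px[s + 1L, ]
      j0 <- max(0, floor(min(a[1], b[1]) - hw - 1))
      j1 <- min(w - 1, ceiling(max(a[1], b[1]) + hw + 1))
      i0 <- max(0, floor(min(a[2], b[2]) - hw - 1))
      i1 <- min(h - 1, ceiling(max(a[2], b[2]) + hw + 1))
      if (j1 < j0 || i1 < i0) next
      jj <- j0:j1; ii <- i0:i1
      gx <- matrix(jj, length(ii), length(jj), byrow = TRUE)
      gy <- matrix(ii, length(ii), length(jj))
      d <- point_segment_distance(as.vector(gx), as.vector(gy),
                                  a[1], a[2], b[1], b[2])
      hit <- matrix(d <= hw, length(ii), length(jj))
      sub <- plane[ii + 1, jj + 1, drop = FALSE]
      sub[hit] <- pmax(sub[hit], value)
      plane[ii + 1, jj + 1] <- sub
    }
  }
  plane
}

#' Add 2-D Gaussian spots (sub-pixel centers, additive)
#' @noRd
raster_spots <- function(plane, cx, cy, sigma_px, amplitude) {
  h <- nrow(plane); w <- ncol(plane)
  r <- ceiling(4 * sigma_px + 1)
  for (k in seq_along(cx)) {
    j0 <- max(0, floor(cx[k] - r)); j1 <- min(w - 1, ceiling(cx[k] + r))
    i0 <- max(0, floor(cy[k] - r)); i1 <- min(h - 1, ceiling(cy[k] + r))
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    gx <- matrix(jj, length(ii), length(jj), byrow = TRUE)
    gy <- matrix(ii, length(ii), length(jj))
    g <- amplitude * exp(-((gx - cx[k])^2 + (gy - cy[k])^2) / (2 * sigma_px^2))
    plane[ii + 1, jj + 1] <- plane[ii + 1, jj + 1] + g
  }
  plane
}

#' Paint filled discs (pixel-center test)
#' @noRd
raster_discs <- function(plane, cx, cy, radius_px, value) {
  h <- nrow(plane); w <- ncol(plane)
  for (k in seq_along(cx)) {
    r <- radius_px[k]
    j0 <- max(0, floor(cx[k] - r)); j1 <- min(w - 1, ceiling(cx[k] + r))
    i0 <- max(0, floor(cy[k] - r)); i1 <- min(h - 1, ceiling(cy[k] + r))
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    gx <- matrix(jj, length(ii), length(jj), byrow = TRUE)
    gy <- matrix(ii, length(ii), length(jj))
    hit <- (gx - cx[k])^2 + (gy - cy[k])^2 <= r^2
    sub <- plane[ii + 1, jj + 1, drop = FALSE]
    sub[hit] <- pmax(sub[hit], value)
    plane[ii + 1, jj + 1] <- sub
  }
  plane
}

#' PSF blur + background + noise for a scene array
#' @noRd
finish_stack <- function(scene, config) {
  sigma_px <- config$psf_sigma_um / config$pixel_size_um
  r <- kernel_radius(sigma_px)
  if (2L * r + 1L > min(dim(scene)[1:2]))
    stop("PSF kernel wider than the field")
  g <- gaussian_kernel(sigma_px, r)
  poisson <- config$noise_model == "poisson_gaussian"
  out <- scene
  for (z in seq_len(dim(scene)[3])) {
    pl <- conv2_sep(scene[, , z], g, g) + config$background_mean
    out[, , z] <- shot_read_noise(as.numeric(pl), config$background_sd,
                                  poisson)
  }
  out
}

#' Render a two-channel section from ground truth
#'
#' Axon centerlines are rasterized as tubes of `axon_width_um` into the red
#' channel of the plane each axon occupies; boutons become Gaussian spots of
#' FWHM `bouton_diameter_um` in the green channel (and, at
#' `bouton_red_fraction` of the axon intensity, in red); somata become
#' filled discs in both channels.  Each plane is then convolved with the
#' Gaussian PSF, background is added, and noise is applied per
#' `noise_model`.
#'
#' @param truth a [ground_truth].
#' @param config a [simulation_config].
#' @param channels which channels to render (subset of `c("red", "green")`).
#' @param seed RNG seed controlling depth assignment and noise.
#' @return list with elements `red` and `green` ([image_stack] or `NULL`).
#' @export
render_section <- function(truth, config, channels = c("red", "green"),
                           seed = config$seed) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  channels <- match.arg(channels, c("red", "green"), several.ok = TRUE)
  hw_dim <- config$image_size_px
  px <- config$pixel_size_um
  nz <- config$z_planes
  with_seed(seed, {
    n_axons <- if (length(truth$path_axon)) max(truth$path_axon) else 0L
    z_axon <- if (n_axons > 0L) sample.int(nz, n_axons, replace = TRUE)
    z_path <- if (n_axons > 0L) z_axon[truth$path_axon] else integer(0)
    hw_px <- config$axon_width_um / 2 / px

    n_btn <- if (is.null(truth$boutons)) 0L else nrow(truth$boutons)
    z_btn <- integer(0)
    if (n_btn > 0L) {
      z_btn <- integer(n_btn)
      on_path <- !is.na(truth$boutons$path) & n_axons > 0L
      z_btn[on_path] <- z_path[truth$boutons$path[on_path]]
      if (any(!on_path))
        z_btn[!on_path] <- sample.int(nz, sum(!on_path), replace = TRUE)
    }
    n_soma <- if (is.null(truth$somata)) 0L else nrow(truth$somata)
    z_soma <- if (n_soma > 0L) sample.int(nz, n_soma, replace = TRUE)

    sp_sigma <- config$bouton_diameter_um / 2.355 / px
    paint_channel <- function(channel) {
      scene <- array(0, c(hw_dim, nz))
      for (z in seq_len(nz)) {
        plane <- matrix(0, hw_dim[1], hw_dim[2])
        if (channel == "red" && n_axons > 0L) {
          sel <- which(z_path == z)
          if (length(sel))
            plane <- raster_tubes(plane,
                                  lapply(truth$axon_paths[sel], `/`, px),
                                  hw_px, config$axon_intensity)
        }
        if (n_btn > 0L) {
          amp <- if (channel == "green") config$bouton_amplitude
          else config$bouton_red_fraction * config$axon_intensity
          sel <- which(z_btn == z)
          if (length(sel) && amp > 0)
            plane <- raster_spots(plane, truth$boutons$x_um[sel] / px,
                                  truth$boutons$y_um[sel] / px,
                                  sp_sigma, amp)
        }
        if (n_soma > 0L) {
          sel <- which(z_soma == z)
          if (length(sel))
            plane <- raster_discs(plane, truth$somata$x_um[sel] / px,
                                  truth$somata$y_um[sel] / px,
                                  sqrt(truth$somata$area_um2[sel] / pi) / px,
                                  config$soma_intensity)
        }
        scene[, , z] <- plane
      }
      scene
    }
    # per-channel noise seeds drawn up front, so a channel's rendering is
    # identical whether or not the other channel is requested
    ch_seed <- c(red = derive_seeds(seed + 1L, 1L),
                 green = derive_seeds(seed + 2L, 1L))
    out <- list(red = NULL, green = NULL)
    for (ch in c("red", "green")) if (ch %in% channels) {
      scene <- paint_channel(ch)
      out[[ch]] <- image_stack(
        with_seed(ch_seed[[ch]], finish_stack(scene, config)),
        px, config$z_step_um)
    }
    out
  })
}

#' Simulate an injection-site section with labeled somata
#'
#' Places `n_cells` non-overlapping discs with areas drawn uniformly from
#' `config$soma_area_range_um2`, renders them into both channels, and
#' returns the exact truth (centers and areas).
#'
#' @param n_cells number of somata to place.
#' @param config a [simulation_config].
#' @param seed RNG seed.
#' @param channels channels to render (subset of `c("red", "green")`).
#' @return list with `red`, `green` ([image_stack]s or `NULL`) and `truth`
#'   ([ground_truth] with the soma table, region `"VTA"`).
#' @export
generate_vta_section <- function(n_cells, config, seed = config$seed,
                                 channels = c("red", "green")) {
  stopifnot(inherits(config, "simulation_config"), n_cells >= 0)
  px <- config$pixel_size_um
  w_um <- config$image_size_px[2] * px
  h_um <- config$image_size_px[1] * px
  somata <- with_seed(seed, {
    if (n_cells == 0L) {
      data.frame(x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0))
    } else {
      areas <- stats::runif(n_cells, config$soma_area_range_um2[1],
                            config$soma_area_range_um2[2])
      radii <- sqrt(areas / pi)
      xs <- ys <- numeric(n_cells)
      tries <- 0L
      max_tries <- 1000L + 500L * n_cells
      placed <- 0L
      while (placed < n_cells) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("could not place ", n_cells,
               " non-overlapping somata in the field")
        i <- placed + 1L
        x <- stats::runif(1, radii[i], w_um - radii[i])
        y <- stats::runif(1, radii[i], h_um - radii[i])
        ok <- placed == 0L ||
          all(sqrt((xs[seq_len(placed)] - x)^2 +
                   (ys[seq_len(placed)] - y)^2) >
              radii[seq_len(placed)] + radii[i] + 0.5)
        if (ok) {
          xs[i] <- x; ys[i] <- y
          placed <- i
        }
      }
      data.frame(x_um = xs, y_um = ys, area_um2 = areas)
    }
  })
  truth <- ground_truth(somata = somata, region_label = "VTA")
  imgs <- render_section(truth, config, channels = channels, seed = seed + 1L)
  list(red = imgs$red, green = imgs$green, truth = truth)
}

#' Jittered elliptical ROI polygon emulating a hand-drawn region contour
#' @noRd
make_roi_polygon <- function(dim_hw, seed, n_vertices = 24L,
                             radius_frac = 0.42, jitter = c(0.88, 1.04)) {
  with_seed(seed, {
    h <- dim_hw[1]; w <- dim_hw[2]
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    jit <- stats::runif(n_vertices, jitter[1], jitter[2])
    cbind(
      x = (w - 1) / 2 + radius_frac * w * jit * cos(th),
      y = (h - 1) / 2 + radius_frac * h * jit * sin(th)
    )
  })
}
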