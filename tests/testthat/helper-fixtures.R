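# Shared fixtures: small, fast simulator configurations and independent
# oracle helpers used across test files.

# fast 10x-mode config on a small field (overridable defaults)
small_config <- function(...) {
  args <- list(image_size_px = c(96L, 96L), pixel_size_um = 0.62,
               z_planes = 3L, n_axons = 6L, seed = 11L)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# high-magnification config matched to the sensitive acquisition mode
hires_config <- function(...) {
  args <- list(image_size_px = c(512L, 512L), pixel_size_um = 0.25,
               z_planes = 3L, seed = 21L)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# truth made of widely spaced horizontal lines: bouton merging happens
# only along a line, never across lines
parallel_line_truth <- function(n_lines, length_um, spacing_um,
                                density_per_um, seed, margin_um = 8) {
  paths <- lapply(seq_len(n_lines), function(i) {
    y <- margin_um + (i - 1) * spacing_um
    cbind(c(margin_um, margin_um + length_um), c(y, y))
  })
  btn <- place_boutons(paths, density_per_um, seed = seed)
  ground_truth(paths, seq_len(n_lines), boutons = btn)
}

# independent point-to-segment distance (used to check boutons sit on axons)
oracle_point_seg_dist <- function(px, py, a, b) {
  d <- b - a
  t <- ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / sum(d^2)
  t <- min(1, max(0, t))
  sqrt((px - (a[1] + t * d[1]))^2 + (py - (a[2] + t * d[2]))^2)
}

oracle_dist_to_paths <- function(px, py, paths) {
  best <- Inf
  for (p in paths)
    for (s in seq_len(nrow(p) - 1L))
      best <- min(best, oracle_point_seg_dist(px, py, p[s, ], p[s + 1L, ]))
  best
}

# brute-force 8-connected flood fill labeling (independent of EBImage)
oracle_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# brute-force regional maxima with minimum separation, mirroring the
# documented definition: candidates are mask pixels at least as large as
# every response value in the Euclidean disc of radius ceiling(sep/2)
# (with the same 1e-9 tie tolerance), then greedy acceptance in
# decreasing response order subject to the separation
oracle_maxima <- function(resp, mask, sep_px) {
  r <- max(1L, ceiling(sep_px / 2))
  h <- nrow(resp); w <- ncol(resp)
  cand <- NULL
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    is_max <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (di * di + dj * dj > r * r) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w) next
      if (resp[ii, jj] - 1e-9 > resp[i, j]) is_max <- FALSE
    }
    if (is_max) cand <- rbind(cand, c(i, j, resp[i, j]))
  }
  if (is.null(cand)) return(data.frame(x = integer(0), y = integer(0)))
  cand <- cand[order(cand[, 3], decreasing = TRUE), , drop = FALSE]
  keep <- NULL
  for (k in seq_len(nrow(cand))) {
    y <- cand[k, 1] - 1; x <- cand[k, 2] - 1
    if (is.null(keep) ||
        all((keep[, 1] - x)^2 + (keep[, 2] - y)^2 >= sep_px^2))
      keep <- rbind(keep, c(x, y))
  }
  data.frame(x = as.integer(keep[, 1]), y = as.integer(keep[, 2]))
}

# full-frame rectangular ROI polygon for an image of the given size
full_roi <- function(dim_hw) {
  h <- dim_hw[1]; w <- dim_hw[2]
  cbind(c(-0.5, w - 0.5, w - 0.5, -0.5), c(-0.5, -0.5, h - 0.5, h - 0.5))
}
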