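# Internal numerical helpers: filter kernels, convolution, morphological
# thinning, polygon rasterization, seed plumbing.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their `seed` argument and leave the caller's RNG stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive independent sub-seeds from a master seed
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# ---- separable Gaussian-family kernels ---------------------------------

# All kernels are sampled on integer offsets with radius ~4 sigma.  The
# smoothing kernel sums to one; derivative kernels are forced to zero sum
# so a constant image yields exactly zero response (this is what makes the
# detectors invariant to global intensity shifts).

kernel_radius <- function(sigma, min_r = 1L) {
  max(as.integer(min_r), as.integer(ceiling(4 * sigma)))
}

gaussian_kernel <- function(sigma, radius = kernel_radius(sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

gaussian_deriv1_kernel <- function(sigma, radius = kernel_radius(sigma, 2L)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- -(x / sigma^2) * g
  k - mean(k)
}

gaussian_deriv2_kernel <- function(sigma, radius = kernel_radius(sigma, 2L)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

#' 2-D convolution with a separable kernel, replicated borders
#'
#' `ky` runs along rows (y), `kx` along columns (x).
#' @noRd
conv2_sep <- function(img, ky, kx) {
  sep_conv2(img, ky, kx)
}

#' Gaussian blur (isotropic), sigma in pixels
#' @noRd
gaussian_blur <- function(img, sigma) {
  g <- gaussian_kernel(sigma)
  conv2_sep(img, g, g)
}

#' Scale-normalized Laplacian-of-Gaussian response, sign-flipped so bright
#' blobs give positive values.
#' @noRd
log_response <- function(img, sigma) {
  g <- gaussian_kernel(sigma, kernel_radius(sigma, 2L))
  d2 <- gaussian_deriv2_kernel(sigma)
  -(sigma^2) * (conv2_sep(img, d2, g) + conv2_sep(img, g, d2))
}

#' Bright-ridge response: magnitude of the dominant negative eigenvalue of
#' the scale-normalized Hessian, clipped at zero.
#' @noRd
hessian_ridge_response <- function(img, sigma) {
  g <- gaussian_kernel(sigma, kernel_radius(sigma, 2L))
  d1 <- gaussian_deriv1_kernel(sigma)
  d2 <- gaussian_deriv2_kernel(sigma)
  s2 <- sigma^2
  hyy <- s2 * conv2_sep(img, d2, g)
  hxx <- s2 * conv2_sep(img, g, d2)
  hxy <- s2 * conv2_sep(img, d1, d1)
  lam_min <- (hxx + hyy) / 2 - sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  pmax(-lam_min, 0)
}

# ---- binary morphology --------------------------------------------------

#' Shift a logical matrix, padding with FALSE
#' @noRd
shift_mask <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  ri <- seq_len(h) + di
  rj <- seq_len(w) + dj
  oi <- ri >= 1L & ri <= h
  oj <- rj >= 1L & rj <= w
  out[oi, oj] <- m[ri[oi], rj[oj]]
  out
}

# 8-neighborhood in the clockwise order N, NE, E, SE, S, SW, W, NW
neighbors8 <- function(m) {
  list(
    shift_mask(m, -1L,  0L), shift_mask(m, -1L,  1L),
    shift_mask(m,  0L,  1L), shift_mask(m,  1L,  1L),
    shift_mask(m,  1L,  0L), shift_mask(m,  1L, -1L),
    shift_mask(m,  0L, -1L), shift_mask(m, -1L, -1L)
  )
}

#' Zhang-Suen morphological thinning to unit width
#'
#' Vectorized parallel thinning; preserves 8-connectivity of the foreground.
#' @noRd
thin_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbors8(m)
      b <- Reduce(`+`, nb)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in seq_along(nb)) {
        j <- if (i == length(nb)) 1L else i + 1L
        a <- a + (!nb[[i]] & nb[[j]])
      }
      if (step == 1L) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]])
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]])
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- m & b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Is deleting pixel (i, j) topology-preserving (8-simple)?
#'
#' True iff the foreground pixels of the 8-neighborhood form exactly one
#' 8-connected component (checked with true pairwise adjacency, not just
#' ring order) and at least one 4-neighbor is background (no hole is
#' created).
#' @noRd
is_simple_point <- function(m, i, j) {
  h <- nrow(m); w <- ncol(m)
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  at <- function(k) {
    ii <- i + off[k, 1]; jj <- j + off[k, 2]
    ii >= 1L && ii <= h && jj >= 1L && jj <= w && m[ii, jj]
  }
  p <- vapply(1:8, at, logical(1))
  b <- sum(p)
  if (b < 1L || b > 7L) return(FALSE)
  if (p[1] && p[3] && p[5] && p[7]) return(FALSE)  # all 4-neighbors set
  fg <- which(p)
  comp <- integer(length(fg))
  cur <- 0L
  for (s in seq_along(fg)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (t in seq_along(fg)) {
        if (comp[t] == 0L &&
            max(abs(off[fg[a], ] - off[fg[t], ])) <= 1L) {
          comp[t] <- cur
          stack <- c(stack, t)
        }
      }
    }
  }
  cur == 1L
}

#' Remove residual 2x2 foreground blocks left by parallel thinning,
#' deleting only 8-simple pixels so connectivity is preserved.
#' @noRd
squash_blocks <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) return(m)
  repeat {
    blk <- m[-nrow(m), -ncol(m), drop = FALSE] &
      m[-1L, -ncol(m), drop = FALSE] &
      m[-nrow(m), -1L, drop = FALSE] &
      m[-1L, -1L, drop = FALSE]
    idx <- which(blk, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(m)
    removed <- FALSE
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      cand <- rbind(c(i, j), c(i + 1L, j), c(i, j + 1L), c(i + 1L, j + 1L))
      for (k in 1:4) {
        ci <- cand[k, 1L]; cj <- cand[k, 2L]
        if (m[ci, cj] && is_simple_point(m, ci, cj)) {
          m[ci, cj] <- FALSE
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) return(m)
  }
}

#' Shift a numeric matrix, padding with -Inf
#' @noRd
shift_num <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(-Inf, h, w)
  ri <- seq_len(h) + di
  rj <- seq_len(w) + dj
  oi <- ri >= 1L & ri <= h
  oj <- rj >= 1L & rj <= w
  out[oi, oj] <- m[ri[oi], rj[oj]]
  out
}

#' Grayscale max filter over a Euclidean disc of integer radius
#' (offsets with di^2 + dj^2 <= r^2, center included)
#' @noRd
max_filter_disc <- function(m, radius) {
  out <- m
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      if (di == 0L && dj == 0L) next
      if (di * di + dj * dj > radius * radius) next
      out <- pmax(out, shift_num(m, di, dj))
    }
  }
  out
}

#' Connected components of a logical mask (8-connected)
#'
#' EBImage::bwlabel is 4-connected; diagonal-touching labels are merged
#' with a union-find pass so the partition is 8-connected.
#' @noRd
label_components <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1L)),
                nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- NULL
  for (dj in c(-1L, 1L)) {
    a <- lab[-h, , drop = FALSE]
    b <- if (dj == 1L)
      cbind(lab[-1L, -1L, drop = FALSE], 0L)
    else
      cbind(0L, lab[-1L, -w, drop = FALSE])
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # renumber consecutively in order of first appearance
  vals <- root[lab[lab > 0L]]
  out <- lab
  out[lab > 0L] <- match(vals, unique(vals))
  out
}

#' Drop components smaller than `min_px` pixels
#' @noRd
remove_small_components <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_px
  out <- mask
  out[mask] <- keep[lab[mask]]
  out
}

# ---- polygon rasterization ---------------------------------------------

#' Signed polygon area (shoelace); vertices as an n x 2 matrix
#' @noRd
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Rasterize a polygon to a pixel mask (even-odd rule, pixel-center test)
#'
#' Vertices are 0-based pixel coordinates (x = column, y = row); pixel
#' centers sit on integer coordinates.  A pixel is foreground iff its
#' center is strictly inside the polygon.
#' @noRd
polygon_mask <- function(poly, dim_hw) {
  h <- dim_hw[1]; w <- dim_hw[2]
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  if (abs(polygon_area_signed(poly)) < .Machine$double.eps)
    stop("degenerate polygon (zero area)")
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nxt <- c(2:n, 1)
  x2 <- poly[nxt, 1]; y2 <- poly[nxt, 2]
  mask <- matrix(FALSE, h, w)
  for (row in seq_len(h)) {
    y <- row - 1
    cr <- (y1 <= y) != (y2 <= y)
    if (!any(cr)) next
    xc <- sort(x1[cr] + (y - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      lo <- floor(xc[k]) + 1
      hi <- ceiling(xc[k + 1]) - 1
      lo <- max(lo, 0); hi <- min(hi, w - 1)
      if (hi >= lo) mask[row, (lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

#' Distance from points to a segment a-b
#' @noRd
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Total length of a polyline (n x 2 matrix)
#' @noRd
polyline_length <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Minimum distance from a point to any segment of a set of polylines
#' @noRd
min_dist_to_paths <- function(x, y, paths) {
  best <- Inf
  for (p in paths) {
    if (nrow(p) < 2L) next
    for (s in seq_len(nrow(p) - 1L)) {
      d <- point_segment_distance(x, y, p[s, 1], p[s, 2], p[s + 1, 1], p[s + 1, 2])
      if (d < best) best <- d
    }
  }
  best
}
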