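# Per-cell shape and intensity features from labelled binary masks.
#
# Conventions (all stated because the downstream tolerances depend on them):
# foreground is 8-connected, background 4-connected; the perimeter is a
# corner-corrected chain-code estimate; the distance transform is the exact
# Euclidean distance to the nearest background pixel centre, and the median
# radius subtracts half a pixel so a boundary pixel sits at depth ~0.5 px.

# --- exact Euclidean distance transform (squared), separable lower-envelope ---

edt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Distance (in pixels) from each pixel to the nearest background pixel
# centre; the image border counts as background (mask is padded).
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  f <- matrix(0, nr + 2, nc + 2)
  f[pad] <- (nr + nc + 4)^2 # effectively infinite; keeps arithmetic finite
  for (j in seq_len(nc + 2)) f[, j] <- edt_1d(f[, j])
  for (i in seq_len(nr + 2)) f[i, ] <- edt_1d(f[i, ])
  sqrt(f[2:(nr + 1), 2:(nc + 1), drop = FALSE])
}

# --- corner-corrected chain-code perimeter (Moore boundary tracing) ---

# 8-neighbour offsets in clockwise order starting east
.moore <- cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
                dc = c(1, 1, 0, -1, -1, -1, 0, 1))

trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # start: first foreground pixel in column-major scan, so the pixels to its
  # north and west are background
  s <- which(mask)[1]
  sr <- (s - 1) %% nr + 1; sc <- (s - 1) %/% nr + 1
  if (!any(vapply(1:8, function(k) at(sr + .moore[k, 1], sc + .moore[k, 2]),
                  NA))) {
    return(integer(0)) # isolated pixel
  }
  # Deterministic walk over states (pixel, entry direction); the chain is
  # complete when a (pixel, move) pair repeats.
  dirs <- integer(0)
  seen <- new.env(hash = TRUE, size = 256L)
  r <- sr; c <- sc
  prev <- 7L # pretend we entered moving south; backtrack points north
  max_steps <- 8L * sum(mask) + 8L
  repeat {
    moved <- FALSE
    for (step in 0:7) {
      k <- ((prev %% 8L) + step) %% 8L + 1L # clockwise from backtrack + 1
      rr <- r + .moore[k, 1]; cc <- c + .moore[k, 2]
      if (at(rr, cc)) {
        key <- sprintf("%d,%d,%d", r, c, k)
        if (!is.null(seen[[key]])) return(dirs)
        seen[[key]] <- TRUE
        dirs <- c(dirs, k)
        prev <- ((k - 1L + 4L) %% 8L) + 1L # direction pointing back
        r <- rr; c <- cc
        moved <- TRUE
        break
      }
    }
    if (!moved || length(dirs) > max_steps) return(dirs)
  }
}

# Perimeter from the chain code: corner-corrected step weights (axial 0.980,
# diagonal 1.406, -0.091 per direction change) measure the pixel-centre
# polygon; the closed outer boundary adds a half-pixel offset all around
# (+ 2*pi*0.5).
perimeter_estimate <- function(mask) {
  n_px <- sum(mask)
  if (n_px == 1L) return(4)
  dirs <- trace_boundary(mask)
  if (length(dirs) == 0) return(4)
  diag_step <- dirs %% 2 == 0 # even indices are diagonals in .moore order
  n_diag <- sum(diag_step)
  n_axial <- length(dirs) - n_diag
  n_corner <- sum(dirs != c(dirs[-1], dirs[1]))
  0.980 * n_axial + 1.406 * n_diag - 0.091 * n_corner + pi
}

# --- convex hull solidity ---

# count pixel centres inside (or on) the convex hull of foreground centres
convex_area_px <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) <= 2L) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1]) # (x = col, y = row)
  hx <- pts[h, 2]; hy <- pts[h, 1]
  if (length(h) <= 2L) return(nrow(pts))
  rr <- range(pts[, 1]); cr <- range(pts[, 2])
  cand <- expand.grid(row = rr[1]:rr[2], col = cr[1]:cr[2])
  inside <- rep(TRUE, nrow(cand))
  n <- length(hx)
  # chull returns vertices clockwise in (x, y); inside = all cross <= 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    cr_ <- ex * (cand$row - hy[i]) - ey * (cand$col - hx[i])
    inside <- inside & (cr_ <= 1e-9)
  }
  sum(inside)
}

# --- moments-based eccentricity ---

eccentricity_from_moments <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 1L) return(0)
  mu <- colMeans(pts)
  dy <- pts[, 1] - mu[1]; dx <- pts[, 2] - mu[2]
  m20 <- mean(dx^2); m02 <- mean(dy^2); m11 <- mean(dx * dy)
  tr <- m20 + m02
  det <- m20 * m02 - m11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  min(sqrt(max(1 - l2 / l1, 0)), 1 - 1e-12)
}

#' Measure shape features of one cell mask
#'
#' Computes the six features the screening analysis uses: area, perimeter,
#' form factor (4*pi*A/P^2; 1 for a perfect circle), solidity (area over
#' convex-hull area; 1 for convex shapes), eccentricity (from second central
#' moments, in `[0, 1)`), and median radius (median over member pixels of the
#' Euclidean distance to the nearest background pixel, less half a pixel).
#'
#' @param mask Logical (or 0/1) matrix marking one 8-connected cell region.
#' @param pixel_size_um Pixel size in um (default 1).
#' @return A one-row tibble with `area_um2`, `perimeter_um`, `form_factor`,
#'   `solidity`, `eccentricity`, `median_radius_um`, `n_pixels`, and a
#'   `degenerate` flag (set for single-pixel masks).
#' @export
#' @examples
#' m <- outer(1:21, 1:21, function(r, c) (r - 11)^2 + (c - 11)^2 <= 64)
#' measure_shape(m)
measure_shape <- function(mask, pixel_size_um = 1) {
  mask <- mask_as_logical(mask)
  n_px <- sum(mask)
  if (n_px == 0L) {
    abort("mask is empty: no foreground pixels.",
          class = "toposcreen_measure_error")
  }
  comp <- label_components(mask, connectivity = 8)
  if (comp$n > 1L) {
    abort(sprintf("mask has %d 8-connected components; expected one cell.",
                  comp$n), class = "toposcreen_measure_error")
  }
  px <- pixel_size_um
  if (n_px == 1L) {
    return(tibble::tibble(
      area_um2 = px^2, perimeter_um = 4 * px, form_factor = pi / 4,
      solidity = 1, eccentricity = 0, median_radius_um = 0.5 * px,
      n_pixels = 1L, degenerate = TRUE))
  }
  area <- n_px * px^2
  per <- perimeter_estimate(mask) * px
  dmap <- distance_transform(mask)
  mr <- (median(dmap[mask]) - 0.5) * px
  tibble::tibble(
    area_um2 = area,
    perimeter_um = per,
    form_factor = 4 * pi * area / per^2,
    solidity = n_px / convex_area_px(mask),
    eccentricity = eccentricity_from_moments(mask),
    median_radius_um = max(mr, 0.5 * px),
    n_pixels = n_px,
    degenerate = FALSE)
}

#' Measure per-cell intensity statistics
#'
#' Median and integrated (summed) intensity over the mask's member pixels;
#' background pixels never contribute. With an even pixel count the median is
#' the mean of the two central order statistics.
#'
#' @param mask Logical matrix (one cell) within the image bounds.
#' @param image Numeric intensity matrix of the same size as `mask`.
#' @return A one-row tibble with `median_intensity`, `integrated_intensity`,
#'   `n_pixels`.
#' @export
measure_intensity <- function(mask, image) {
  mask <- mask_as_logical(mask)
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.",
          class = "toposcreen_measure_error")
  }
  if (nrow(image) < nrow(mask) || ncol(image) < ncol(mask)) {
    abort("mask extends beyond the image bounds.",
          class = "toposcreen_measure_error")
  }
  if (!any(mask)) {
    abort("mask is empty: no foreground pixels.",
          class = "toposcreen_measure_error")
  }
  vals <- image[seq_len(nrow(mask)), seq_len(ncol(mask))][mask]
  tibble::tibble(median_intensity = median(vals),
                 integrated_intensity = sum(vals),
                 n_pixels = sum(mask))
}

#' Measure all labelled cells of an image
#'
#' @param labels Integer matrix; 0 is background, each positive label one
#'   cell (8-connected).
#' @param image Optional intensity matrix aligned with `labels`.
#' @param pixel_size_um Pixel size in um.
#' @return A tibble with one row per label: shape features and, when `image`
#'   is given, `median_intensity` and `integrated_intensity`.
#' @export
measure_cells <- function(labels, image = NULL, pixel_size_um = 1) {
  stopifnot(is.matrix(labels))
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  out <- lapply(ids, function(id) {
    m <- labels == id
    ri <- range(which(rowSums(m) > 0)); ci <- range(which(colSums(m) > 0))
    sub <- m[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
    row <- measure_shape(sub, pixel_size_um)
    if (!is.null(image)) {
      sub_img <- image[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
      row <- dplyr::bind_cols(row,
        measure_intensity(sub, sub_img)[c("median_intensity",
                                          "integrated_intensity")])
    }
    dplyr::bind_cols(tibble::tibble(label = id), row)
  })
  dplyr::bind_rows(out)
}

#' Generate a synthetic cell mask and intensity image
#'
#' Deterministic per-seed fixtures mirroring the cell-shape archetypes seen
#' on topographies: `round` (compact, low eccentricity), `spindle` (8:1
#' ellipse, eccentricity near 0.992), and `multilobed` (two lobes joined by a
#' thin bridge, solidity well below 1).
#'
#' @param archetype One of `"round"`, `"spindle"`, `"multilobed"`.
#' @param size_px Canvas side in pixels (at least 8).
#' @param seed Seed for the boundary jitter and image noise.
#' @return A list with `mask` (logical matrix), `image` (numeric matrix) and
#'   `pixel_size_um = 1`.
#' @export
generate_cell_fixture <- function(archetype = c("round", "spindle",
                                                "multilobed"),
                                  size_px = 64, seed = 1) {
  archetype <- match.arg(archetype)
  if (size_px < 8) {
    abort("`size_px` must be at least 8.", class = "toposcreen_config_error")
  }
  n <- as.integer(size_px)
  cx <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  dx <- g$col - cx; dy <- g$row - cx
  mask <- withr::with_seed(seed, {
    switch(archetype,
      round = {
        R <- 0.4 * n
        phase <- runif(1, 0, 2 * pi)
        th <- atan2(dy, dx)
        r_th <- R * (1 + 0.04 * sin(3 * th + phase))
        matrix(sqrt(dx^2 + dy^2) <= r_th, n, n)
      },
      spindle = {
        a <- 0.48 * n; b <- a / 8
        th <- runif(1, 0, pi)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
      },
      multilobed = {
        r <- 0.17 * n; off <- 0.26 * n
        lobe1 <- (dx + off)^2 + dy^2 <= r^2
        lobe2 <- (dx - off)^2 + dy^2 <= r^2
        bridge <- abs(dy) <= max(1, 0.02 * n) & abs(dx) <= off
        matrix(lobe1 | lobe2 | bridge, n, n)
      })
  })
  image <- withr::with_seed(seed + 1L, {
    base <- 10 + 90 * exp(-(dx^2 + dy^2) / (2 * (0.35 * n)^2))
    matrix(base + rnorm(n * n, 0, 2), n, n)
  })
  image[!mask] <- withr::with_seed(seed + 2L,
    rnorm(sum(!mask), 10, 2))
  list(mask = mask, image = image, pixel_size_um = 1)
}

#' Read an intensity or label image from TIFF or PNG
#'
#' @param path File path; 16-bit TIFF intensities are returned on their
#'   native integer scale.
#' @return A numeric matrix.
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort("reading TIFF requires the 'tiff' package.")
      tiff::readTIFF(path, as.is = TRUE)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        abort("reading PNG requires the 'png' package.")
      png::readPNG(path) * 255
    },
    abort(sprintf("unsupported image format `%s`.", ext),
          class = "toposcreen_schema_error"))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

mask_as_logical <- function(mask) {
  if (is.logical(mask)) {
    if (!is.matrix(mask)) abort("`mask` must be a matrix.",
                                class = "toposcreen_measure_error")
    return(mask)
  }
  if (is.matrix(mask) && is.numeric(mask)) return(mask != 0)
  abort("`mask` must be a logical or numeric matrix.",
        class = "toposcreen_measure_error")
}
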