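# Image formation for the synthetic plates.
#
# Geometry is worked in um and converted to pixels only when drawing.
# Healthy cells are drawn as parallel anti-aliased Z-line stripes with
# ~1.9 um sarcomere periodicity inside an elliptical footprint; disrupted
# cells as short dot-like puncta. All draws consume the current RNG stream,
# so a field is reproducible from its substream seed alone.

SARCOMERE_PERIOD_UM <- 1.9
ZLINE_WIDTH_UM <- 0.8

#' Sample the ground truth for one simulated cell
#'
#' Draws one mononuclear cell from a treatment condition: its healthy flag
#' (Bernoulli with the group's healthy fraction), footprint geometry, true
#' Z-line segment lengths (long parallel stripes if healthy, short puncta if
#' disrupted) and its true YAP1 nuclear/cytoplasm intensity ratio.
#'
#' @param group a [group_spec]
#' @param mode "sarcomere_60x" or "yap_4x"
#' @return list with fields healthy, lengths_um, yap_ratio, geometry
#' @export
sample_cell_truth <- function(group, mode = "sarcomere_60x") {
  if (!inherits(group, "group_spec")) stop("group must be a group_spec")
  healthy <- stats::runif(1) < group$healthy_fraction
  yap_nuclear <- stats::runif(1) < group$yap_nuclear_fraction
  if (mode == "sarcomere_60x") {
    geom <- list(a_um = stats::runif(1, 14, 17),   # semi-major axis
                 b_um = stats::runif(1, 8, 10.5),  # semi-minor axis
                 theta = stats::runif(1, 0, pi),
                 nuc_a_um = 4.5, nuc_b_um = 3.0,
                 nuc_amp = stats::runif(1, 2500, 3500),
                 cyto_amp = stats::runif(1, 220, 300),
                 stripe_amp = stats::runif(1, 2200, 2800))
    if (healthy) {
      n_seg <- sample.int(7, 1) + 8L   # 9..15 stripes
      lengths <- sample_dist(group$z_length_healthy, n_seg)
    } else {
      n_seg <- sample.int(11, 1) + 19L  # 20..30 puncta
      lengths <- sample_dist(group$z_length_disrupted, n_seg)
    }
  } else {
    geom <- list(a_um = stats::runif(1, 13, 16),
                 b_um = stats::runif(1, 10, 13),
                 theta = stats::runif(1, 0, pi),
                 nuc_a_um = 5.5, nuc_b_um = 4.5,
                 nuc_amp = stats::runif(1, 2500, 3500),
                 cyto_amp = stats::runif(1, 600, 1000))
    lengths <- numeric(0)
  }
  ratio_spec <- if (yap_nuclear) group$yap_ratio_nuclear else
    group$yap_ratio_cytosolic
  list(healthy = healthy, yap_nuclear = yap_nuclear,
       lengths_um = lengths,
       yap_ratio = sample_dist(ratio_spec, 1),
       geom = geom)
}

# Poisson-disc (dart-throwing) placement of n points with minimum spacing,
# accelerated by a bucket grid. Errors when the field cannot host n cells
# at the requested spacing.
place_cells <- function(n, shape, min_spacing_px, margin_px,
                        max_attempts_per_cell = 200) {
  if (n == 0) return(cbind(r = numeric(0), c = numeric(0)))
  lo_r <- margin_px; hi_r <- shape[1] - margin_px
  lo_c <- margin_px; hi_c <- shape[2] - margin_px
  if (hi_r <= lo_r || hi_c <= lo_c) {
    stop("field too small for requested cell geometry")
  }
  cell <- max(min_spacing_px, 1)
  nbr <- ceiling((hi_r - lo_r) / cell); nbc <- ceiling((hi_c - lo_c) / cell)
  grid <- vector("list", nbr * nbc)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- n * max_attempts_per_cell
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    p <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
    br <- min(nbr, 1L + floor((p[1] - lo_r) / cell))
    bc <- min(nbc, 1L + floor((p[2] - lo_c) / cell))
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- br + dr; cc <- bc + dc
      if (rr < 1 || rr > nbr || cc < 1 || cc > nbc) next
      for (q in grid[[(cc - 1) * nbr + rr]]) {
        if (sum((pts[q, ] - p)^2) < min_spacing_px^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- p
      idx <- (bc - 1) * nbr + br
      grid[[idx]] <- c(grid[[idx]], placed)
    }
  }
  if (placed < n) {
    stop("field too small for requested cell count at the given spacing")
  }
  colnames(pts) <- c("r", "c")
  pts
}

# --- drawing primitives (additive, anti-aliased, row/col pixel coords) ----
# Each *_patch function returns a local intensity patch (rs, cs, values);
# callers accumulate patches into the field raster in place, so drawing a
# cell never copies the whole field.

# Stripe with flat ends: intensity amp inside a length x width rectangle
# centred at (r0,c0) with axis direction (dr,dc), ~1 px linear soft edge.
# Endpoint-to-endpoint extent equals len_px at half maximum.
capsule_patch <- function(dims, r0, c0, dr, dc, len_px, width_px, amp) {
  half <- len_px / 2 + width_px / 2 + 1.5
  r_lo <- max(1, floor(r0 - half)); r_hi <- min(dims[1], ceiling(r0 + half))
  c_lo <- max(1, floor(c0 - half)); c_hi <- min(dims[2], ceiling(c0 + half))
  if (r_hi < r_lo || c_hi < c_lo) return(NULL)
  rs <- r_lo:r_hi
  cs <- c_lo:c_hi
  R <- outer(rs - r0, rep(1, length(cs)))
  C <- outer(rep(1, length(rs)), cs - c0)
  u <- R * dr + C * dc          # along-axis coordinate
  v <- -R * dc + C * dr         # across-axis coordinate
  f <- pmin(pmax(len_px / 2 + 0.5 - abs(u), 0), 1) *
    pmin(pmax(width_px / 2 + 0.5 - abs(v), 0), 1)
  list(rs = rs, cs = cs, values = amp * f)
}

# Soft-edged ellipse, axes a_px (along theta) and b_px.
ellipse_patch <- function(dims, r0, c0, a_px, b_px, theta, amp) {
  half <- max(a_px, b_px) + 2
  r_lo <- max(1, floor(r0 - half)); r_hi <- min(dims[1], ceiling(r0 + half))
  c_lo <- max(1, floor(c0 - half)); c_hi <- min(dims[2], ceiling(c0 + half))
  if (r_hi < r_lo || c_hi < c_lo) return(NULL)
  rs <- r_lo:r_hi
  cs <- c_lo:c_hi
  R <- outer(rs - r0, rep(1, length(cs)))
  C <- outer(rep(1, length(rs)), cs - c0)
  u <- R * cos(theta) + C * sin(theta)
  v <- -R * sin(theta) + C * cos(theta)
  q <- sqrt((u / a_px)^2 + (v / b_px)^2)
  f <- pmin(pmax((1 - q) * min(a_px, b_px) + 0.5, 0), 1)
  list(rs = rs, cs = cs, values = amp * f)
}

apply_patch <- function(img, p) {
  if (!is.null(p)) img[p$rs, p$cs] <- img[p$rs, p$cs] + p$values
  img
}

# single-patch convenience wrappers (used by tests and small fixtures)
draw_capsule <- function(img, r0, c0, dr, dc, len_px, width_px, amp) {
  apply_patch(img, capsule_patch(dim(img), r0, c0, dr, dc, len_px,
                                 width_px, amp))
}

draw_ellipse <- function(img, r0, c0, a_px, b_px, theta, amp) {
  apply_patch(img, ellipse_patch(dim(img), r0, c0, a_px, b_px, theta, amp))
}

# uniform point in the ellipse (footprint), rejection-free via radius sqrt
ellipse_point <- function(r0, c0, a, b, theta, shrink = 0.85) {
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- sqrt(stats::runif(1)) * shrink
  u <- rad * cos(ang) * a
  v <- rad * sin(ang) * b
  c(r0 + u * cos(theta) - v * sin(theta),
    c0 + u * sin(theta) + v * cos(theta))
}

# per-cell patch lists: $ch1 and $ch2 are lists of patches to accumulate
cell_patches_sarcomere <- function(dims, cell, centroid, px) {
  g <- cell$geom
  r0 <- centroid[1]; c0 <- centroid[2]
  p1 <- list(ellipse_patch(dims, r0, c0, g$nuc_a_um / px, g$nuc_b_um / px,
                           g$theta, g$nuc_amp))
  p2 <- list(ellipse_patch(dims, r0, c0, g$a_um / px, g$b_um / px, g$theta,
                           g$cyto_amp))
  wpx <- ZLINE_WIDTH_UM / px
  if (cell$healthy) {
    # parallel stripes perpendicular to the myofibril (major) axis,
    # regular sarcomere spacing, centred on the cell
    n <- length(cell$lengths_um)
    offsets <- (seq_len(n) - (n + 1) / 2) * SARCOMERE_PERIOD_UM / px
    adr <- cos(g$theta); adc <- sin(g$theta)        # major axis direction
    for (i in seq_len(n)) {
      p2[[length(p2) + 1L]] <- capsule_patch(
        dims, r0 + offsets[i] * adr, c0 + offsets[i] * adc, -adc, adr,
        cell$lengths_um[i] / px, wpx, g$stripe_amp)
    }
  } else {
    for (i in seq_along(cell$lengths_um)) {
      p <- ellipse_point(r0, c0, g$a_um / px, g$b_um / px, g$theta)
      phi <- stats::runif(1, 0, pi)
      p2[[length(p2) + 1L]] <- capsule_patch(
        dims, p[1], p[2], cos(phi), sin(phi), cell$lengths_um[i] / px,
        wpx, g$stripe_amp)
    }
  }
  list(ch1 = p1, ch2 = p2)
}

cell_patches_yap <- function(dims, cell, centroid, px) {
  g <- cell$geom
  r0 <- centroid[1]; c0 <- centroid[2]
  p1 <- list(ellipse_patch(dims, r0, c0, g$nuc_a_um / px, g$nuc_b_um / px,
                           g$theta, g$nuc_amp))
  # nucleus region carries ratio x cytoplasm intensity: add the difference
  p2 <- list(ellipse_patch(dims, r0, c0, g$a_um / px, g$b_um / px, g$theta,
                           g$cyto_amp),
             ellipse_patch(dims, r0, c0, g$nuc_a_um / px, g$nuc_b_um / px,
                           g$theta, (cell$yap_ratio - 1) * g$cyto_amp))
  list(ch1 = p1, ch2 = p2)
}

apply_noise <- function(img, noise) {
  d <- dim(img)
  img <- img + noise$background_level
  if (noise$photon_scale > 0) {
    img <- stats::rpois(length(img), lambda = pmax(img, 0) *
                          noise$photon_scale) / noise$photon_scale
  }
  if (noise$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise$read_noise_sd)
  }
  dim(img) <- d
  img
}

#' Render one synthetic field
#'
#' Draws the supplied cells into a two-channel 16-bit field (channel 1
#' nuclei, channel 2 alpha-actinin or YAP1 marker) and returns the image
#' together with its per-cell ground truth. Consumes the current RNG
#' stream; callers seed it per field for reproducibility.
#'
#' @param cells list of cell-truth objects from [sample_cell_truth]
#' @param centroids matrix of (row, col) pixel centroids, one row per cell
#' @param config a [sim_config]
#' @param well,field identifiers stamped into the output
#' @return list(field = field_image, truth = per-cell data.frame)
#' @export
render_field <- function(cells, centroids, config, well = "W01", field = 1L) {
  shape <- config$field_shape
  px <- config$pixel_size_um
  ch1 <- matrix(0, shape[1], shape[2])
  ch2 <- matrix(0, shape[1], shape[2])
  for (i in seq_along(cells)) {
    ps <- if (config$mode == "sarcomere_60x") {
      cell_patches_sarcomere(shape, cells[[i]], centroids[i, ], px)
    } else {
      cell_patches_yap(shape, cells[[i]], centroids[i, ], px)
    }
    # in-place accumulation: keeps the field rasters single-referenced
    for (p in ps$ch1) {
      if (!is.null(p)) ch1[p$rs, p$cs] <- ch1[p$rs, p$cs] + p$values
    }
    for (p in ps$ch2) {
      if (!is.null(p)) ch2[p$rs, p$cs] <- ch2[p$rs, p$cs] + p$values
    }
  }
  ch1 <- apply_noise(ch1, config$noise)
  ch2 <- apply_noise(ch2, config$noise)
  dim(ch1) <- dim(ch2) <- shape
  ch1 <- matrix(pmin(pmax(round(ch1), 0), 65535), shape[1], shape[2])
  ch2 <- matrix(pmin(pmax(round(ch2), 0), 65535), shape[1], shape[2])
  truth <- data.frame(
    well = rep(well, length(cells)), field = rep(field, length(cells)),
    cell_id = seq_along(cells),
    r_px = centroids[, 1], c_px = centroids[, 2],
    healthy = vapply(cells, `[[`, TRUE, "healthy"),
    yap_nuclear = vapply(cells, `[[`, TRUE, "yap_nuclear"),
    n_segments = vapply(cells, function(x) length(x$lengths_um), 1L),
    mean_true_length_um = vapply(cells, function(x) {
      if (length(x$lengths_um)) mean(x$lengths_um) else NA_real_
    }, 1),
    yap_ratio_true = vapply(cells, `[[`, 1, "yap_ratio"))
  list(field = field_image(ch1, ch2, px, well = well, field = field,
                           mode = config$mode),
       truth = truth)
}

# Sample and render one field for a group under the current RNG stream.
simulate_field <- function(config, group, well, field) {
  n <- stats::rpois(1, config$cells_per_field_mean)
  px <- config$pixel_size_um
  margin_um <- if (config$mode == "sarcomere_60x") 8 else 14
  pts <- place_cells(n, config$field_shape, config$min_spacing_um / px,
                     margin_um / px)
  cells <- lapply(seq_len(n), function(i) {
    sample_cell_truth(group, config$mode)
  })
  render_field(cells, pts, config, well = well, field = field)
}
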