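# Per-field segmentation: nuclei, cell territories, Z-line segments, and
# YAP1 nuclear/cytoplasm intensities. Standard morphology (blur, Otsu,
# watershed, seeded propagation, top-hat) is delegated to EBImage; the
# curvilinear length estimator lives in skeleton.R.

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(Inf)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[2])
  h <- tabulate(pmin(255, floor((v - rng[1]) / diff(rng) * 256)) + 1L, 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / 256 * diff(rng)
}

relabel_consecutive <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) return(matrix(0L, nrow(mask), ncol(mask)))
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- mask
  out[mask > 0] <- lut[mask[mask > 0]]
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' Segmentation parameters
#'
#' @param blur_sigma_um Gaussian pre-smoothing sigma for nuclei detection
#' @param min_nucleus_area_um2 nuclei smaller than this are discarded
#' @param watershed_tolerance intensity tolerance of the distance-transform
#'   watershed split (larger = less oversplitting)
#' @param zline_width_um nominal Z-line width driving the top-hat size
#' @param min_zline_um segments shorter than this are discarded as noise
#' @param exclude_border drop Z-line components touching the field border
#' @param bg_percentile percentile of non-territory pixels used as the
#'   background estimate subtracted from YAP intensities
#' @param nucleus_dilate_px dilation of the nucleus mask before the
#'   cytoplasm region is taken as territory minus nucleus
#' @return list of parameters
#' @export
seg_params <- function(blur_sigma_um = 1.0, min_nucleus_area_um2 = 25,
                       watershed_tolerance = 2, zline_width_um = 0.8,
                       min_zline_um = 0.5, exclude_border = TRUE,
                       bg_percentile = 0.5, nucleus_dilate_px = 1L) {
  list(blur_sigma_um = blur_sigma_um,
       min_nucleus_area_um2 = min_nucleus_area_um2,
       watershed_tolerance = watershed_tolerance,
       zline_width_um = zline_width_um, min_zline_um = min_zline_um,
       exclude_border = exclude_border, bg_percentile = bg_percentile,
       nucleus_dilate_px = as.integer(nucleus_dilate_px))
}

#' Segment nuclei from the Hoechst channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling, distance-transform
#' watershed split of touching nuclei, then a minimum-area filter. Labels
#' are consecutive 1..K. An all-flat image yields an empty mask.
#'
#' @param img nuclei-channel matrix
#' @param pixel_size_um um per pixel
#' @param params [seg_params]
#' @return integer label matrix
#' @export
segment_nuclei <- function(img, pixel_size_um, params = seg_params()) {
  stopifnot(is.matrix(img), length(img) > 0)
  sigma <- max(params$blur_sigma_um / pixel_size_um, 0.5)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img / 65535), sigma = sigma))
  thr <- otsu_threshold(sm)
  # guard against thresholding pure noise/background: require contrast
  if (diff(range(sm)) < 2e-4) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  bin <- sm > thr
  bin <- as.matrix(EBImage::fillHull(EBImage::Image(bin)))
  if (!any(bin)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(EBImage::Image(bin))
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  min_px <- params$min_nucleus_area_um2 / pixel_size_um^2
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_consecutive(lab)
}

#' Count objects in a label mask
#'
#' @param mask integer label mask with consecutive labels
#' @return object count
#' @export
count_cells <- function(mask) {
  as.integer(max(0L, max(mask)))
}

#' Partition marker foreground into one territory per nucleus
#'
#' Seeded propagation (Voronoi-like region growing on the marker image)
#' restricted to the marker-positive foreground union the nuclei. Each
#' territory carries its nucleus's label; territories are disjoint.
#'
#' @param nuclei integer nucleus label mask
#' @param marker marker-channel matrix
#' @param pixel_size_um um per pixel
#' @param params [seg_params]
#' @return integer territory label mask (same labels as `nuclei`)
#' @export
assign_territories <- function(nuclei, marker, pixel_size_um,
                               params = seg_params()) {
  stopifnot(all(dim(nuclei) == dim(marker)))
  if (max(nuclei) == 0) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  sigma <- max(params$blur_sigma_um / pixel_size_um, 0.5)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(marker / 65535),
                                 sigma = sigma))
  thr <- otsu_threshold(sm)
  fg <- sm > thr | nuclei > 0
  terr <- EBImage::propagate(EBImage::Image(marker / 65535),
                             seeds = EBImage::Image(nuclei),
                             mask = EBImage::Image(fg))
  matrix(as.integer(EBImage::imageData(terr)), nrow(nuclei), ncol(nuclei))
}

#' Detect Z-line segments and measure their lengths
#'
#' Ridge-enhances the alpha-actinin channel with a white top-hat sized to
#' the Z-line width, thresholds (Otsu over territory foreground),
#' skeletonizes each connected component and reports its longest geodesic
#' skeleton path length in um. Components shorter than `min_zline_um` are
#' discarded; components touching the border are dropped when
#' `exclude_border` is set. Each segment is assigned to the territory
#' containing its centroid.
#'
#' @param img alpha-actinin channel matrix
#' @param territories territory label mask, or NULL to treat the whole
#'   field as a single cell (label 1)
#' @param pixel_size_um um per pixel
#' @param params [seg_params]
#' @return data.frame (cell_id, length_um), one row per segment
#' @export
detect_z_lines <- function(img, territories, pixel_size_um,
                           params = seg_params()) {
  if (is.null(territories)) {
    territories <- matrix(1L, nrow(img), ncol(img))
  }
  wpx <- params$zline_width_um / pixel_size_um
  brush_d <- 2L * as.integer(ceiling(wpx)) + 1L
  th <- as.matrix(EBImage::whiteTopHat(
    EBImage::Image(img / 65535),
    EBImage::makeBrush(brush_d, shape = "disc")))
  infg <- territories > 0
  if (!any(infg)) {
    return(data.frame(cell_id = integer(0), length_um = numeric(0)))
  }
  thr <- otsu_threshold(th[infg])
  if (diff(range(th[infg])) < 2e-4) {
    return(data.frame(cell_id = integer(0), length_um = numeric(0)))
  }
  bin <- th > thr & infg
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(data.frame(cell_id = integer(0), length_um = numeric(0)))
  }
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0)
  comp <- lab[idx]
  r <- ((idx - 1) %% nr) + 1
  co <- ((idx - 1) %/% nr) + 1
  cell_ids <- integer(n_comp)
  lengths <- rep(NA_real_, n_comp)
  r_split <- split(r, comp)
  c_split <- split(co, comp)
  for (k in seq_len(n_comp)) {
    rk <- r_split[[as.character(k)]]
    ck <- c_split[[as.character(k)]]
    if (params$exclude_border &&
        (min(rk) == 1 || max(rk) == nr || min(ck) == 1 || max(ck) == nc)) {
      next
    }
    # centroid-based territory assignment (deterministic, no ties)
    cr <- round(mean(rk)); cc <- round(mean(ck))
    cr <- min(max(cr, 1), nr); cc <- min(max(cc, 1), nc)
    terr <- territories[cr, cc]
    if (terr == 0) next
    sub <- matrix(0L, max(rk) - min(rk) + 3, max(ck) - min(ck) + 3)
    sub[cbind(rk - min(rk) + 2, ck - min(ck) + 2)] <- 1L
    # thinning erodes roughly half the stripe width off each end; recover
    # the end caps from the component area via area ~ (path + w) * w
    path_px <- skeleton_path_px(thin_binary(sub)) - 1
    area_px <- length(rk)
    w_px <- (sqrt(path_px^2 + 4 * area_px) - path_px) / 2
    len_um <- (path_px + w_px) * pixel_size_um
    if (len_um < params$min_zline_um) next
    cell_ids[k] <- terr
    lengths[k] <- len_um
  }
  keep <- cell_ids > 0 & !is.na(lengths)
  data.frame(cell_id = cell_ids[keep], length_um = lengths[keep])
}

#' Measure per-cell YAP1 nuclear and cytoplasm intensities
#'
#' Nuclear mean over the cell's nucleus pixels, cytoplasm mean over the
#' territory minus the dilated nucleus; a background estimate (percentile
#' of non-territory pixels) is subtracted from both. Cells whose cytoplasm
#' region is empty are flagged unmeasurable.
#'
#' @param img YAP1 channel matrix
#' @param nuclei nucleus label mask
#' @param territories territory label mask (same labels)
#' @param params [seg_params]
#' @return data.frame (cell_id, yap_nuclear_mean, yap_cytoplasm_mean,
#'   measurable)
#' @export
measure_yap <- function(img, nuclei, territories, params = seg_params()) {
  k <- max(nuclei)
  if (k == 0) {
    return(data.frame(cell_id = integer(0), yap_nuclear_mean = numeric(0),
                      yap_cytoplasm_mean = numeric(0),
                      measurable = logical(0)))
  }
  outside <- territories == 0
  bg <- if (any(outside)) {
    stats::quantile(img[outside], params$bg_percentile, names = FALSE)
  } else 0
  nuc_bin <- nuclei > 0
  if (params$nucleus_dilate_px > 0) {
    nuc_dil <- as.matrix(EBImage::dilate(
      EBImage::Image(nuc_bin),
      EBImage::makeBrush(2L * params$nucleus_dilate_px + 1L,
                         shape = "diamond"))) > 0
  } else {
    nuc_dil <- nuc_bin
  }
  t1 <- tapply(img[nuc_bin], nuclei[nuc_bin], mean)
  nuc_mean <- rep(NA_real_, k)
  nuc_mean[as.integer(names(t1))] <- as.numeric(t1)
  cyt_bin <- territories > 0 & !nuc_dil
  cyt_mean <- rep(NA_real_, k)
  if (any(cyt_bin)) {
    t2 <- tapply(img[cyt_bin], territories[cyt_bin], mean)
    cyt_mean[as.integer(names(t2))] <- as.numeric(t2)
  }
  data.frame(cell_id = seq_len(k),
             yap_nuclear_mean = pmax(nuc_mean - bg, 0),
             yap_cytoplasm_mean = pmax(cyt_mean - bg, 0),
             measurable = !is.na(nuc_mean) & !is.na(cyt_mean))
}

#' Segment and measure one field
#'
#' Runs the full per-field chain: nuclei, territories, then Z-line lengths
#' (sarcomere mode) or YAP1 intensities (YAP mode), and assembles one
#' cell record per nucleus.
#'
#' @param fi a [field_image]
#' @param params [seg_params]
#' @return data.frame of per-cell records for the field
#' @export
segment_field <- function(fi, params = seg_params()) {
  stopifnot(inherits(fi, "field_image"))
  px <- fi$pixel_size_um
  nuc <- segment_nuclei(fi$nuclei, px, params)
  k <- count_cells(nuc)
  base <- data.frame(well = rep(fi$well, k), field = rep(fi$field, k),
                     cell_id = seq_len(k))
  if (k == 0) {
    base$mean_z_length_um <- numeric(0)
    base$n_z_lines <- integer(0)
    base$yap_nuclear_mean <- numeric(0)
    base$yap_cytoplasm_mean <- numeric(0)
    base$yap_measurable <- logical(0)
    return(base)
  }
  terr <- assign_territories(nuc, fi$marker, px, params)
  if (fi$mode == "sarcomere_60x") {
    segs <- detect_z_lines(fi$marker, terr, px, params)
    n_seg <- tabulate(segs$cell_id, nbins = k)
    sums <- rep(0, k)
    if (nrow(segs)) {
      t1 <- tapply(segs$length_um, segs$cell_id, sum)
      sums[as.integer(names(t1))] <- as.numeric(t1)
    }
    base$mean_z_length_um <- ifelse(n_seg > 0, sums / pmax(n_seg, 1),
                                    NA_real_)
    base$n_z_lines <- n_seg
    base$yap_nuclear_mean <- NA_real_
    base$yap_cytoplasm_mean <- NA_real_
    base$yap_measurable <- FALSE
  } else {
    ym <- measure_yap(fi$marker, nuc, terr, params)
    base$mean_z_length_um <- NA_real_
    base$n_z_lines <- 0L
    base$yap_nuclear_mean <- ym$yap_nuclear_mean
    base$yap_cytoplasm_mean <- ym$yap_cytoplasm_mean
    base$yap_measurable <- ym$measurable
  }
  base
}

#' Segment every field of a plate
#'
#' @param fields list of [field_image]
#' @param params [seg_params]
#' @return combined per-cell data.frame
#' @export
segment_plate <- function(fields, params = seg_params()) {
  do.call(rbind, lapply(fields, segment_field, params = params))
}
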