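# Per-cell classification and per-well indices: the well-organized-
# sarcomere call (mean Z-line length strictly above the cutoff), the
# Healthy Sarcomere Index (HSI), the YAP1 nuclear-localization index,
# relative-to-control normalization and the auxiliary cutoff search.

#' Scoring parameters
#'
#' @param z_cutoff_um mean Z-line length (um) above which a cell counts as
#'   having a well-organized sarcomere; the strict ">" rule
#' @param yap_ratio_threshold nuclear/cytoplasm intensity ratio above which
#'   a cell counts as YAP1 nuclear-localized
#' @param min_cells_per_well wells with fewer cells are flagged low-count
#' @return list of parameters
#' @export
scoring_params <- function(z_cutoff_um = 3.1, yap_ratio_threshold = 1.3,
                           min_cells_per_well = 50L) {
  if (z_cutoff_um <= 0 || yap_ratio_threshold <= 0) {
    stop("cutoffs must be positive")
  }
  list(z_cutoff_um = z_cutoff_um, yap_ratio_threshold = yap_ratio_threshold,
       min_cells_per_well = as.integer(min_cells_per_well))
}

#' Mean Z-line length of a cell
#'
#' Arithmetic mean of the cell's segment lengths; NA when no Z-line was
#' detected (such cells still count in the well denominator but are never
#' classified well-organized).
#'
#' @param lengths_um numeric vector of segment lengths
#' @return mean in um, or NA for an empty list
#' @export
mean_z_length <- function(lengths_um) {
  if (!length(lengths_um)) return(NA_real_)
  mean(lengths_um)
}

#' Well-organized-sarcomere call
#'
#' TRUE iff the mean length is defined and strictly greater than the
#' cutoff.
#'
#' @param mean_length_um per-cell mean Z-line length (um), NA allowed
#' @param params [scoring_params]
#' @return logical vector
#' @export
classify_well_organized <- function(mean_length_um,
                                    params = scoring_params()) {
  !is.na(mean_length_um) & mean_length_um > params$z_cutoff_um
}

#' YAP1 nuclear-localization call
#'
#' TRUE iff nuclear/cytoplasm mean-intensity ratio exceeds the threshold;
#' the cytoplasm mean is floored at a small positive constant.
#'
#' @param nuclear_mean,cytoplasm_mean background-subtracted mean intensities
#' @param params [scoring_params]
#' @return logical vector
#' @export
classify_yap_nuclear <- function(nuclear_mean, cytoplasm_mean,
                                 params = scoring_params()) {
  ratio <- nuclear_mean / pmax(cytoplasm_mean, 1e-6)
  !is.na(ratio) & ratio > params$yap_ratio_threshold
}

#' Per-well metrics from per-cell records
#'
#' Applies the per-cell classifications and aggregates each well: total
#' cells, number and fraction (HSI) of well-organized cells, and the YAP1
#' nuclear-localization index over measurable cells. Wells with zero cells
#' are dropped with a warning; wells below `min_cells_per_well` are flagged.
#'
#' @param cells per-cell data.frame as returned by [segment_plate]
#' @param params [scoring_params]
#' @return per-well data.frame
#' @export
compute_well_metrics <- function(cells, params = scoring_params()) {
  if (!nrow(cells)) {
    warning("no cells to score")
    return(data.frame(well = character(0), n_cells_total = integer(0),
                      n_healthy = integer(0), hsi = numeric(0),
                      n_yap_measurable = integer(0),
                      n_yap_nuclear = integer(0), yap_index = numeric(0),
                      low_count = logical(0)))
  }
  healthy <- classify_well_organized(cells$mean_z_length_um, params)
  yap_nuc <- classify_yap_nuclear(cells$yap_nuclear_mean,
                                  cells$yap_cytoplasm_mean, params) &
    cells$yap_measurable
  sp <- split(seq_len(nrow(cells)), cells$well)
  out <- do.call(rbind, lapply(names(sp), function(w) {
    i <- sp[[w]]
    n <- length(i)
    n_meas <- sum(cells$yap_measurable[i])
    data.frame(well = w, n_cells_total = n, n_healthy = sum(healthy[i]),
               hsi = sum(healthy[i]) / n,
               n_yap_measurable = n_meas,
               n_yap_nuclear = sum(yap_nuc[i]),
               yap_index = if (n_meas > 0) sum(yap_nuc[i]) / n_meas
                 else NA_real_,
               low_count = n < params$min_cells_per_well)
  }))
  rownames(out) <- NULL
  out[order(out$well), , drop = FALSE]
}

#' Per-well HSI for one well's cells
#'
#' Convenience wrapper over [compute_well_metrics] for a single well.
#'
#' @param cells per-cell records of one well
#' @param params [scoring_params]
#' @return one-row per-well data.frame
#' @export
compute_hsi <- function(cells, params = scoring_params()) {
  if (!nrow(cells)) {
    warning("well has zero cells; HSI undefined")
    return(NULL)
  }
  if (length(unique(cells$well)) != 1) stop("cells span multiple wells")
  compute_well_metrics(cells, params)
}

#' Per-well YAP1 nuclear-localization index
#'
#' @param cells per-cell records of one well (YAP mode)
#' @param params [scoring_params]
#' @return fraction of measurable cells classified nuclear-localized
#' @export
compute_yap_index <- function(cells, params = scoring_params()) {
  wm <- compute_hsi(cells, params)
  if (is.null(wm) || wm$n_yap_measurable == 0) {
    warning("well has zero measurable cells; YAP index undefined")
    return(NA_real_)
  }
  wm$yap_index
}

#' Per-group summary relative to the control group
#'
#' Joins well metrics to the plate layout, summarizes each group's metric
#' as mean +/- SD, and expresses the group mean as percent of the control
#' group mean (ratio of group means, so the control group is exactly 100).
#'
#' @param well_metrics output of [compute_well_metrics]
#' @param layout plate layout (well, group_label, dose_uM, is_control)
#' @param metric "hsi" or "yap_index"
#' @param control_label label of the control group
#' @return per-group data.frame ordered by dose (control first)
#' @export
relative_to_control <- function(well_metrics, layout, metric = "hsi",
                                control_label = "DMSO") {
  stopifnot(metric %in% names(well_metrics))
  d <- merge(well_metrics, layout, by = "well")
  d <- d[!is.na(d[[metric]]), , drop = FALSE]
  if (!any(d$group_label == control_label)) {
    stop("control group '", control_label, "' has no valid wells")
  }
  ctrl_mean <- mean(d[[metric]][d$group_label == control_label])
  if (ctrl_mean == 0) stop("control group mean is zero; ratios undefined")
  sp <- split(d, d$group_label)
  out <- do.call(rbind, lapply(sp, function(g) {
    v <- g[[metric]]
    data.frame(group_label = g$group_label[1], dose_uM = g$dose_uM[1],
               n_wells = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               percent_of_control = 100 * mean(v) / ctrl_mean)
  }))
  rownames(out) <- NULL
  out <- out[order(out$group_label != control_label, out$dose_uM), ,
             drop = FALSE]
  out
}

#' Search for the cutoff separating control from positive-control cells
#'
#' Scans a grid of candidate cutoffs and returns the one maximizing the
#' separation (Youden-style) between the two populations' well-organized
#' fractions under the strict ">" rule: J(c) = frac_control(c) -
#' frac_positive(c). Ties break toward the smaller cutoff. If the two sets
#' are identical the grid minimum is returned with a warning. This is an
#' auxiliary tool; the default pipeline uses the fixed 3.1 um cutoff.
#'
#' @param control_lengths,positive_lengths per-cell mean Z-line lengths
#'   (um) under the control and positive-control conditions
#' @param grid candidate cutoffs (um)
#' @return the selected cutoff (um)
#' @export
optimize_cutoff <- function(control_lengths, positive_lengths,
                            grid = seq(1.0, 6.0, by = 0.1)) {
  control_lengths <- control_lengths[!is.na(control_lengths)]
  positive_lengths <- positive_lengths[!is.na(positive_lengths)]
  if (!length(control_lengths) || !length(positive_lengths)) {
    stop("both cell sets must contain defined mean lengths")
  }
  j <- vapply(grid, function(cc) {
    mean(control_lengths > cc) - mean(positive_lengths > cc)
  }, 1)
  if (max(j) <= 0) {
    warning("no cutoff separates the two sets; returning grid minimum")
    return(min(grid))
  }
  grid[which.max(j)]  # which.max takes the first, i.e. smallest, maximizer
}
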