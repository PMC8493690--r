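#' Distribution specification
#'
#' A two-parameter (mean, sd) specification for a positive-valued quantity.
#' Sampling truncates at a small positive floor so lengths and intensity
#' ratios are never zero or negative.
#'
#' @param mean mean of the untruncated normal
#' @param sd standard deviation (>= 0)
#' @param floor lower truncation bound
#' @return a `dist_spec` list
#' @export
dist_spec <- function(mean, sd, floor = 0.05) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, floor > 0)
  structure(list(mean = mean, sd = sd, floor = floor), class = "dist_spec")
}

sample_dist <- function(spec, n, rng = NULL) {
  pmax(stats::rnorm(n, spec$mean, spec$sd), spec$floor)
}

#' Camera noise specification
#'
#' Shot (Poisson) plus read (Gaussian) noise on top of a constant
#' fluorescence background, in camera intensity units. `photon_scale` is the
#' number of photoelectrons per intensity unit; 0 disables shot noise.
#'
#' @param photon_scale electrons per intensity unit (>= 0; 0 = no shot noise)
#' @param read_noise_sd Gaussian read noise sd, intensity units
#' @param background_level constant background, intensity units
#' @return a `noise_spec` list
#' @export
noise_spec <- function(photon_scale = 1, read_noise_sd = 3,
                       background_level = 100) {
  if (photon_scale < 0 || read_noise_sd < 0 || background_level < 0) {
    stop("noise parameters must be non-negative")
  }
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 background_level = background_level), class = "noise_spec")
}

#' Treatment-group specification for the plate simulator
#'
#' Describes one treatment condition: the fraction of cells with intact
#' (healthy) sarcomeres, the fraction with nuclear-localized YAP1, and the
#' per-cell distributions the phenotypes are drawn from. Healthy cells carry
#' long parallel Z-line stripes; disrupted cells carry short dot-like
#' puncta, so `z_length_healthy` must have the larger mean.
#'
#' @param label group label, e.g. "DMSO" or "SUN_1uM"
#' @param dose_uM compound concentration in uM (>= 0)
#' @param healthy_fraction probability a cell is healthy
#' @param yap_nuclear_fraction probability a cell has nuclear YAP1
#' @param z_length_healthy [dist_spec] of Z-line segment length (um), healthy
#' @param z_length_disrupted [dist_spec] of punctum length (um), disrupted
#' @param yap_ratio_nuclear [dist_spec] of nuclear/cytoplasm YAP1 intensity
#'   ratio for nuclear-localized cells
#' @param yap_ratio_cytosolic [dist_spec] of that ratio for cytosolic cells
#' @param is_control logical; marks the vehicle-control group
#' @return a `group_spec` list
#' @export
group_spec <- function(label, dose_uM = 0, healthy_fraction = 1,
                       yap_nuclear_fraction = 0.8,
                       z_length_healthy = dist_spec(5.0, 0.5),
                       z_length_disrupted = dist_spec(1.0, 0.25),
                       yap_ratio_nuclear = dist_spec(2.0, 0.25),
                       yap_ratio_cytosolic = dist_spec(0.95, 0.12),
                       is_control = FALSE) {
  if (healthy_fraction < 0 || healthy_fraction > 1 ||
      yap_nuclear_fraction < 0 || yap_nuclear_fraction > 1) {
    stop("healthy_fraction and yap_nuclear_fraction must be in [0, 1]")
  }
  if (dose_uM < 0) stop("dose_uM must be >= 0")
  if (z_length_healthy$mean <= z_length_disrupted$mean) {
    stop("z_length_healthy mean must exceed z_length_disrupted mean")
  }
  structure(list(label = label, dose_uM = dose_uM,
                 healthy_fraction = healthy_fraction,
                 yap_nuclear_fraction = yap_nuclear_fraction,
                 z_length_healthy = z_length_healthy,
                 z_length_disrupted = z_length_disrupted,
                 yap_ratio_nuclear = yap_ratio_nuclear,
                 yap_ratio_cytosolic = yap_ratio_cytosolic,
                 is_control = is_control), class = "group_spec")
}

#' Synthetic plate configuration
#'
#' Defines a full synthetic plate: imaging mode, optics, plate geometry and
#' treatment groups. Mode defaults mirror the imaging design the pipeline
#' targets: 9 fields/well at 60x for sarcomere morphology (~200 cells/well)
#' and 6 fields/well at 4x for YAP1 localization (~4000 cells/well).
#'
#' @param groups list of [group_spec] objects
#' @param mode "sarcomere_60x" or "yap_4x"
#' @param rng_seed master seed; every image and truth table is a pure
#'   function of the configuration including this seed
#' @param pixel_size_um um per pixel (default 0.25 at 60x, 1.6 at 4x)
#' @param field_shape integer c(rows, cols) of each field
#' @param wells_per_group wells per treatment group
#' @param fields_per_well fields imaged per well (9 at 60x, 6 at 4x)
#' @param cells_per_field_mean Poisson mean of cells per field
#'   (~200/well at 60x, ~4000/well at 4x with mode defaults)
#' @param noise [noise_spec]
#' @param min_spacing_um minimum centroid-to-centroid spacing enforced by
#'   the Poisson-disc placement
#' @return a `sim_config` list
#' @export
sim_config <- function(groups,
                       mode = c("sarcomere_60x", "yap_4x"),
                       rng_seed = 1L,
                       pixel_size_um = NULL,
                       field_shape = NULL,
                       wells_per_group = 5L,
                       fields_per_well = NULL,
                       cells_per_field_mean = NULL,
                       noise = noise_spec(),
                       min_spacing_um = NULL) {
  mode <- match.arg(mode)
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "group_spec")))
  defaults <- switch(mode,
    sarcomere_60x = list(px = 0.25, shape = c(512L, 512L), fields = 9L,
                         cells = 22, spacing = 12),
    yap_4x        = list(px = 1.6,  shape = c(720L, 720L), fields = 6L,
                         cells = 667, spacing = 29))
  if (is.null(pixel_size_um)) pixel_size_um <- defaults$px
  if (is.null(field_shape)) field_shape <- defaults$shape
  if (is.null(fields_per_well)) fields_per_well <- defaults$fields
  if (is.null(cells_per_field_mean)) cells_per_field_mean <- defaults$cells
  if (is.null(min_spacing_um)) min_spacing_um <- defaults$spacing
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (wells_per_group < 1 || fields_per_well < 1 || cells_per_field_mean <= 0) {
    stop("all counts must be positive")
  }
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("group labels must be unique")
  structure(list(rng_seed = as.integer(rng_seed), mode = mode,
                 pixel_size_um = pixel_size_um,
                 field_shape = as.integer(field_shape),
                 wells_per_group = as.integer(wells_per_group),
                 fields_per_well = as.integer(fields_per_well),
                 cells_per_field_mean = cells_per_field_mean,
                 groups = groups, noise = noise,
                 min_spacing_um = min_spacing_um), class = "sim_config")
}

# Deterministic per-(well, field) substream seed, kept below 2^31 so it is a
# valid set.seed() argument. Computed in double precision; inputs stay well
# inside the exactly-representable integer range.
field_seed <- function(master, well_idx, field_idx) {
  s <- (as.numeric(master) %% 2147483647) * 48271 +
    well_idx * 99991 + field_idx * 101
  as.integer(s %% 2147483647)
}
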