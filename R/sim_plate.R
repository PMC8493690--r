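#' Simulate a synthetic plate in memory
#'
#' Generates every field of every well for all treatment groups of a
#' [sim_config], with per-cell and per-well ground truth. Each (well,
#' field) pair renders under its own RNG substream derived from the master
#' seed, so the plate is byte-reproducible and independent of evaluation
#' order.
#'
#' @param config a [sim_config]
#' @return list with elements `fields` (list of [field_image]), `layout`
#'   (well, group_label, dose_uM, is_control), `truth` (per-cell) and
#'   `well_truth` (per-well true healthy / YAP-nuclear fractions)
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fields <- list()
  truth <- list()
  layout <- list()
  widx <- 0L
  for (g in config$groups) {
    for (w in seq_len(config$wells_per_group)) {
      widx <- widx + 1L
      well <- sprintf("W%02d", widx)
      layout[[widx]] <- data.frame(well = well, group_label = g$label,
                                   dose_uM = g$dose_uM,
                                   is_control = as.integer(g$is_control))
      for (f in seq_len(config$fields_per_well)) {
        set.seed(field_seed(config$rng_seed, widx, f))
        out <- simulate_field(config, g, well, f)
        fields[[length(fields) + 1L]] <- out$field
        truth[[length(truth) + 1L]] <- out$truth
      }
    }
  }
  truth <- do.call(rbind, truth)
  layout <- do.call(rbind, layout)
  list(fields = fields, layout = layout, truth = truth,
       well_truth = summarize_truth(truth))
}

#' Per-well ground-truth summary
#'
#' Per-well true fractions are exact means of the per-cell flags.
#'
#' @param truth per-cell truth table from [simulate_plate]
#' @return data.frame (well, n_cells, true_healthy_fraction,
#'   true_yap_nuclear_fraction)
#' @export
summarize_truth <- function(truth) {
  sp <- split(truth, truth$well)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(well = d$well[1], n_cells = nrow(d),
               true_healthy_fraction = mean(d$healthy),
               true_yap_nuclear_fraction = mean(d$yap_nuclear))
  }))
  rownames(out) <- NULL
  out[order(out$well), , drop = FALSE]
}

#' Generate a synthetic plate on disk
#'
#' Writes one 2-page 16-bit TIFF per field (`{well}_{field}_{mode}.tif`),
#' a plate-layout CSV, a per-cell truth CSV and a per-well truth CSV.
#'
#' @param config a [sim_config]
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list of the written paths
#' @export
generate_plate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  plate <- simulate_plate(config)
  img_paths <- vapply(plate$fields, function(fi) {
    p <- file.path(out_dir, sprintf("%s_%d_%s.tif", fi$well, fi$field,
                                    fi$mode))
    write_field_tiff(fi, p)
    p
  }, "")
  layout_path <- file.path(out_dir, "layout.csv")
  truth_path <- file.path(out_dir, "truth_cells.csv")
  well_truth_path <- file.path(out_dir, "truth_wells.csv")
  utils::write.csv(plate$layout, layout_path, row.names = FALSE)
  utils::write.csv(plate$truth, truth_path, row.names = FALSE)
  utils::write.csv(plate$well_truth, well_truth_path, row.names = FALSE)
  invisible(list(images = img_paths, layout = layout_path,
                 truth = truth_path, well_truth = well_truth_path))
}

#' Load a plate written by [generate_plate]
#'
#' @param dir plate directory containing the field TIFFs and `layout.csv`
#' @param pixel_size_um pixel size of the stored fields
#' @return list(fields, layout) as in [simulate_plate]
#' @export
load_plate <- function(dir, pixel_size_um) {
  layout_path <- file.path(dir, "layout.csv")
  if (!file.exists(layout_path)) stop("no layout.csv in ", dir)
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  if (!nrow(layout)) stop("empty plate layout: ", layout_path)
  tifs <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  if (!length(tifs)) stop("no field TIFFs in ", dir)
  fields <- lapply(tifs, function(p) {
    parts <- strsplit(sub("\\.tif$", "", basename(p)), "_")[[1]]
    mode <- paste(parts[-(1:2)], collapse = "_")
    read_field_tiff(p, pixel_size_um, well = parts[1],
                    field = as.integer(parts[2]), mode = mode)
  })
  list(fields = fields, layout = layout)
}
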