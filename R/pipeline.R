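# Orchestration: simulate (or load) -> segment -> score -> trend tests,
# written as CSV tables plus a JSON run manifest under one run directory.
# The numbered scripts in analysis/ are thin drivers over these functions.

#' Run configuration
#'
#' Exactly one input source: a [sim_config] for a synthetic plate, or an
#' image directory plus layout CSV written in the simulator's format.
#'
#' @param sim a [sim_config], or NULL when reading images from disk
#' @param image_dir directory of field TIFFs + layout.csv (used when `sim`
#'   is NULL)
#' @param pixel_size_um pixel size of on-disk images
#' @param scoring [scoring_params]
#' @param segmentation [seg_params]
#' @param control_label label of the vehicle-control group
#' @param comparator_label optional second baseline (e.g. the
#'   sunitinib-alone group in a rescue design) for an increasing-direction
#'   trend test of the remaining groups against it
#' @param direction trend direction versus control
#' @param alpha_trend,alpha_two,alpha_het significance levels of the trend
#'   test, the two-group test and the heterogeneity gate
#' @param out_dir run directory
#' @param seed master seed
#' @param write_images also write the synthetic field TIFFs into the run
#'   directory
#' @return a `run_config` list
#' @export
run_config <- function(sim = NULL, image_dir = NULL, pixel_size_um = NULL,
                       scoring = scoring_params(),
                       segmentation = seg_params(),
                       control_label = "DMSO", comparator_label = NULL,
                       direction = "decreasing",
                       alpha_trend = 0.025, alpha_two = 0.05,
                       alpha_het = 0.05,
                       out_dir = tempfile("run_"), seed = 1L,
                       write_images = FALSE) {
  if (is.null(sim) == is.null(image_dir)) {
    stop("exactly one input source: 'sim' or 'image_dir'")
  }
  structure(list(sim = sim, image_dir = image_dir,
                 pixel_size_um = pixel_size_um, scoring = scoring,
                 segmentation = segmentation,
                 control_label = control_label,
                 comparator_label = comparator_label,
                 direction = direction, alpha_trend = alpha_trend,
                 alpha_two = alpha_two, alpha_het = alpha_het,
                 out_dir = out_dir, seed = as.integer(seed),
                 write_images = write_images), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Builds a [run_config] from a YAML file. Top-level keys mirror the
#' [run_config] arguments; a `sim:` block, when present, is passed to
#' [sim_config] with `groups:` entries given as [group_spec] argument
#' lists.
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    groups <- lapply(y$sim$groups, function(g) do.call(group_spec, g))
    sim_args <- y$sim[setdiff(names(y$sim), "groups")]
    y$sim <- do.call(sim_config, c(list(groups = groups), sim_args))
  }
  if (!is.null(y$scoring)) y$scoring <- do.call(scoring_params, y$scoring)
  if (!is.null(y$segmentation)) {
    y$segmentation <- do.call(seg_params, y$segmentation)
  }
  do.call(run_config, y)
}

star_label <- function(res_list, dose) {
  # significance stars by re-testing at the conventional levels
  lv <- c(0.025, 0.005, 0.0005)
  stars <- c("*", "**", "***")
  out <- ""
  for (i in seq_along(lv)) {
    tab <- res_list[[i]]$table
    if (isTRUE(tab$significant[tab$dose == dose])) out <- stars[i]
  }
  out
}

run_stats <- function(well_metrics, layout, metric, cfg) {
  d <- merge(well_metrics, layout, by = "well")
  d <- d[!is.na(d[[metric]]), , drop = FALSE]
  ctrl <- d[[metric]][d$group_label == cfg$control_label]
  dg <- d[d$group_label != cfg$control_label, , drop = FALSE]
  if (!is.null(cfg$comparator_label)) {
    dg <- dg[dg$group_label != cfg$comparator_label, , drop = FALSE]
  }
  ord <- order(dg$dose_uM)
  dg <- dg[ord, , drop = FALSE]
  doses <- split(dg[[metric]], factor(dg$group_label,
                                      levels = unique(dg$group_label)))
  if (!length(doses)) return(NULL)
  series <- dose_series(ctrl, doses, direction = cfg$direction)
  gate <- heterogeneity_gate(series, cfg$alpha_het)
  test_fun <- if (gate$test == "williams") williams_test else
    shirley_williams_test
  levels_ <- c(cfg$alpha_trend, 0.005, 0.0005)
  res_list <- lapply(levels_, function(a) test_fun(series, alpha = a))
  main <- res_list[[1]]
  tab <- main$table
  tab$stars <- vapply(tab$dose, function(dd) star_label(res_list, dd), "")
  tab$test <- gate$test
  tab$alpha <- cfg$alpha_trend
  tab$heterogeneity_p <- gate$p
  tab$metric <- metric
  tab$baseline <- cfg$control_label
  tab
}

#' Execute a full pipeline run
#'
#' Simulates (or loads) the plate, segments every field, scores the wells,
#' summarizes groups relative to control, runs the gated step-down trend
#' test (and, in a rescue design, a second increasing-direction trend test
#' of the rescue groups against the comparator group), and writes
#' `cells.csv`, `wells.csv`, `groups.csv`, `stats.csv` and `manifest.json`
#' into the run directory. Outputs are a pure function of (config, seed);
#' only the manifest carries a timestamp.
#'
#' @param cfg a [run_config]
#' @return invisibly, list of the result tables and the run directory
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$sim)) {
    plate <- simulate_plate(cfg$sim)
    if (!nrow(plate$layout)) stop("empty plate layout")
  } else {
    plate <- load_plate(cfg$image_dir, cfg$pixel_size_um)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (cfg$write_images && !is.null(cfg$sim)) {
    img_dir <- file.path(cfg$out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (fi in plate$fields) {
      write_field_tiff(fi, file.path(img_dir, sprintf(
        "%s_%d_%s.tif", fi$well, fi$field, fi$mode)))
    }
  }
  mode <- plate$fields[[1]]$mode
  metric <- if (mode == "sarcomere_60x") "hsi" else "yap_index"
  cells <- segment_plate(plate$fields, cfg$segmentation)
  wells <- compute_well_metrics(cells, cfg$scoring)
  groups <- relative_to_control(wells, plate$layout, metric,
                                cfg$control_label)
  stats_tab <- run_stats(wells, plate$layout, metric, cfg)
  if (!is.null(cfg$comparator_label)) {
    # rescue design: remaining doses vs the comparator, increasing
    cfg2 <- cfg
    cfg2$control_label <- cfg$comparator_label
    cfg2$comparator_label <- NULL
    d2 <- merge(wells, plate$layout, by = "well")
    keep <- d2$group_label != cfg$control_label
    lay2 <- plate$layout[plate$layout$group_label != cfg$control_label, ,
                         drop = FALSE]
    cfg2$direction <- "increasing"
    tab2 <- run_stats(wells[wells$well %in% lay2$well, , drop = FALSE],
                      lay2, metric, cfg2)
    stats_tab <- rbind(stats_tab, tab2)
  }
  utils::write.csv(cells, file.path(cfg$out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(wells, file.path(cfg$out_dir, "wells.csv"),
                   row.names = FALSE)
  utils::write.csv(groups, file.path(cfg$out_dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_tab, file.path(cfg$out_dir, "stats.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cfg$seed, mode = mode, metric = metric,
                   control_label = cfg$control_label,
                   comparator_label = cfg$comparator_label,
                   direction = cfg$direction,
                   alpha_trend = cfg$alpha_trend,
                   n_fields = length(plate$fields),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(dir = cfg$out_dir, cells = cells, wells = wells,
                 groups = groups, stats = stats_tab,
                 truth = plate$truth, well_truth = plate$well_truth,
                 layout = plate$layout))
}
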