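# Scenario presets mirroring the three screening experiments: a sunitinib
# dose-response, washout recovery at three timepoints, and rescue by
# co-treatment with the MST1/2 inhibitor XMU-MP-1. Severities reproduce
# each design's qualitative ordering; they are not calibrated to any
# measured plate.

#' Scenario preset definitions
#'
#' @param name "dose_response", "washout_recovery" or "rescue_cotreatment"
#' @return a `scenario_preset` list: per-timepoint group tables plus the
#'   trend-test settings the scenario uses
#' @export
scenario_preset <- function(name = c("dose_response", "washout_recovery",
                                     "rescue_cotreatment")) {
  name <- match.arg(name)
  grp <- function(label, dose, hf, ctrl = FALSE) {
    list(label = label, dose_uM = dose, healthy_fraction = hf,
         is_control = ctrl)
  }
  preset <- switch(name,
    dose_response = list(timepoints = list(
      "72h" = list(grp("DMSO", 0, 1.00, TRUE),
                   grp("SUN_0.3uM", 0.3, 0.65),
                   grp("SUN_1uM", 1, 0.15),
                   grp("SUN_3uM", 3, 0.01))),
      control = "DMSO", comparator = NULL, direction = "decreasing"),
    washout_recovery = list(timepoints = list(
      "0h" = list(grp("DMSO", 0, 1.00, TRUE),
                  grp("SUN_0.3uM", 0.3, 0.65),
                  grp("SUN_1uM", 1, 0.15),
                  grp("SUN_3uM", 3, 0.01)),
      "72h" = list(grp("DMSO", 0, 1.00, TRUE),
                   grp("SUN_0.3uM", 0.3, 0.85),
                   grp("SUN_1uM", 1, 0.70),
                   grp("SUN_3uM", 3, 0.20)),
      "144h" = list(grp("DMSO", 0, 1.00, TRUE),
                    grp("SUN_0.3uM", 0.3, 1.00),
                    grp("SUN_1uM", 1, 1.00),
                    grp("SUN_3uM", 3, 1.00))),
      control = "DMSO", comparator = NULL, direction = "decreasing"),
    rescue_cotreatment = list(timepoints = list(
      "72h" = list(grp("DMSO", 0, 1.00, TRUE),
                   grp("SUN_1uM", 0, 0.15),
                   grp("SUN+XMU_0.3uM", 0.3, 0.45),
                   grp("SUN+XMU_1uM", 1, 0.65))),
      control = "DMSO", comparator = "SUN_1uM", direction = "decreasing"))
  structure(c(list(name = name), preset), class = "scenario_preset")
}

preset_sim_config <- function(preset, timepoint, seed, wells_per_group,
                              fields_per_well, cells_per_field_mean) {
  gl <- lapply(preset$timepoints[[timepoint]], function(g) {
    group_spec(g$label, dose_uM = g$dose_uM,
               healthy_fraction = g$healthy_fraction,
               is_control = g$is_control)
  })
  sim_config(gl, mode = "sarcomere_60x", rng_seed = seed,
             wells_per_group = wells_per_group,
             fields_per_well = fields_per_well,
             cells_per_field_mean = cells_per_field_mean)
}

#' Run a scenario preset end to end
#'
#' Builds the synthetic plate(s) for the preset and runs the full pipeline
#' once per timepoint (washout plates are independent per timepoint, as
#' cells are fixed for imaging at each one).
#'
#' @param name preset name, see [scenario_preset]
#' @param seed master seed
#' @param out_dir run directory (one subdirectory per timepoint)
#' @param wells_per_group,fields_per_well,cells_per_field_mean plate size
#'   overrides (defaults: 5 wells, mode defaults otherwise)
#' @param timepoints subset of the preset's timepoints to run (default all)
#' @return invisibly, named list of per-timepoint run results
#' @export
run_scenario <- function(name, seed = 1L, out_dir = tempfile("scenario_"),
                         wells_per_group = 5L, fields_per_well = NULL,
                         cells_per_field_mean = NULL, timepoints = NULL) {
  preset <- scenario_preset(name)
  tps <- names(preset$timepoints)
  if (!is.null(timepoints)) {
    if (!all(timepoints %in% tps)) stop("unknown timepoint(s)")
    tps <- timepoints
  }
  out <- list()
  for (i in seq_along(tps)) {
    tp <- tps[i]
    sim <- preset_sim_config(preset, tp, seed = seed + (i - 1L) * 7919L,
                             wells_per_group, fields_per_well,
                             cells_per_field_mean)
    cfg <- run_config(sim = sim, control_label = preset$control,
                      comparator_label = preset$comparator,
                      direction = preset$direction,
                      out_dir = file.path(out_dir, tp), seed = sim$rng_seed)
    out[[tp]] <- run_pipeline(cfg)
  }
  invisible(out)
}
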