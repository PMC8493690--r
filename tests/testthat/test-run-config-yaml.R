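test_that("a YAML run configuration round-trips into a working run", {
  yml <- file.path(withr::local_tempdir(), "run.yaml")
  writeLines(c(
    "sim:",
    "  mode: sarcomere_60x",
    "  rng_seed: 37",
    "  wells_per_group: 2",
    "  fields_per_well: 2",
    "  cells_per_field_mean: 8",
    "  groups:",
    "    - label: DMSO",
    "      is_control: true",
    "    - label: SUN_1uM",
    "      dose_uM: 1",
    "      healthy_fraction: 0.2",
    "control_label: DMSO",
    "seed: 37"), yml)
  cfg <- read_run_config(yml)
  expect_s3_class(cfg, "run_config")
  cfg$out_dir <- withr::local_tempdir()
  out <- run_pipeline(cfg)
  expect_equal(nrow(out$groups), 2)
  expect_true(file.exists(file.path(out$dir, "stats.csv")))
})
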