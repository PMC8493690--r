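# Fixture builders shared across test files. Everything is generated in
# code; no image files ship with the package.

# single-group config, small plate, optionally noiseless
tiny_config <- function(mode = "sarcomere_60x", healthy_fraction = 0.65,
                        yap_nuclear_fraction = 0.8, wells = 1L, fields = 2L,
                        cells = NULL, seed = 42L, noiseless = FALSE,
                        groups = NULL) {
  if (is.null(groups)) {
    groups <- list(group_spec("G1", healthy_fraction = healthy_fraction,
                              yap_nuclear_fraction = yap_nuclear_fraction,
                              is_control = TRUE))
  }
  sim_config(groups, mode = mode, rng_seed = seed, wells_per_group = wells,
             fields_per_well = fields, cells_per_field_mean = cells,
             noise = if (noiseless) noise_spec(0, 0, 0) else noise_spec())
}

# field with a single rendered stripe of known length/orientation
stripe_field <- function(length_um, theta, px = 0.25, shape = 192L,
                         width_um = 0.8, amp = 2500) {
  img <- matrix(0, shape, shape)
  ctr <- (shape + 1) / 2
  img <- sarcscreen:::draw_capsule(img, ctr, ctr, cos(theta), sin(theta),
                                   length_um / px, width_um / px, amp)
  round(img)
}

# per-cell record data.frame for scoring tests
cell_records <- function(well, mean_len, nuc = NA_real_, cyt = NA_real_,
                         measurable = FALSE) {
  n <- max(length(mean_len), length(nuc), length(cyt))
  mean_len <- rep(mean_len, length.out = n)
  data.frame(well = rep(well, n), field = 1L, cell_id = seq_len(n),
             mean_z_length_um = mean_len, n_z_lines = ifelse(
               is.na(mean_len), 0L, 1L),
             yap_nuclear_mean = rep(nuc, length.out = n),
             yap_cytoplasm_mean = rep(cyt, length.out = n),
             yap_measurable = rep(measurable, length.out = n))
}
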