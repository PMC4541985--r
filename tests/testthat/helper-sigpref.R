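# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

# a small complete experiment
small_sim <- function(n_families = 6, seed = 421, ...) {
  simulate_experiment(
    study_design(n_families = n_families, replicates_per_sex = 2,
                 females_per_replicate = 3, males_per_replicate = 3),
    genetic_architecture(...),
    ptelea_params(), seed = seed
  )
}

# noiseless playback responses for one female with a Gaussian curve
noiseless_trials <- function(peak, width = 18, scale = 8,
                             grid = make_stimulus_grid(ptelea_params())) {
  data.frame(female_id = "f1",
             stimulus_hz = grid,
             response_count = scale * exp(-(grid - peak)^2 / (2 * width^2)))
}

# joint trait rows straight from simulated individuals (males: observed
# signal; females: latent peak), bypassing the spline stage
joint_rows_from_individuals <- function(ind) {
  data.frame(id = ind$id, family = ind$family, replicate = ind$replicate,
             sex = ind$sex,
             value = ifelse(ind$sex == "male", ind$signal_hz, ind$latent_hz),
             stringsAsFactors = FALSE)
}

# balanced reaction-norm design table (no response)
rn_design <- function(n_fam = 20, per_cell = 4, n_rep = 2) {
  d <- expand.grid(i = seq_len(per_cell), rep = seq_len(n_rep),
                   sex = c("male", "female"),
                   fam = sprintf("F%02d", seq_len(n_fam)),
                   stringsAsFactors = FALSE)
  data.frame(family = d$fam, sex = d$sex,
             replicate = paste(d$fam, d$sex, d$rep, sep = "|"),
             stringsAsFactors = FALSE)
}
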