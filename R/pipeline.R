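# End-to-end workflow: simulate (or load) -> preference functions ->
# preference-variation ANOVA -> animal models -> reaction-norm tests ->
# comparative span, with all tables, figures and a run manifest written to
# an output directory.

#' Read a pipeline run configuration
#'
#' Configurations are JSON with optional blocks `species`, `design`,
#' `architecture`, `chain`, plus scalars `alpha` and `seed`; absent fields
#' fall back to package defaults.
#'
#' @param path Path to a JSON configuration file.
#' @return A named list of constructed parameter objects (class
#'   `run_config`).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  build_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A named list with the same structure as the JSON file.
#' @export
build_run_config <- function(raw = list()) {
  sp <- do.call(species_params, modifyList(
    list(name = "E. binotata 'Ptelea'", mean_frequency = 338),
    as.list(raw$species %||% list())))
  des <- do.call(study_design, as.list(raw$design %||% list()))
  arch_args <- as.list(raw$architecture %||% list())
  if (!is.null(arch_args$G)) arch_args$G <- matrix(unlist(arch_args$G), 2, 2)
  arch <- do.call(genetic_architecture, arch_args)
  chain <- do.call(mcmc_config, as.list(raw$chain %||% list()))
  structure(
    list(species = sp, design = des, arch = arch, chain = chain,
         alpha = raw$alpha %||% 0.05, seed = raw$seed %||% NULL),
    class = "run_config"
  )
}

write_table <- function(df, dir, name) {
  write.csv(df, file.path(dir, name), row.names = FALSE)
}

f_test_row <- function(ft, label = ft$term) {
  data.frame(term = label, MS = ft$MS_num, F = ft$F,
             df_num = ft$df_num, df_den = ft$df_den, p = ft$p,
             denominator = ft$denominator, stringsAsFactors = FALSE)
}

#' Run the full signal-preference analysis pipeline
#'
#' Simulates an experiment under the configured design (or reads
#' `trials.csv` / `individuals.csv` from `input_dir`), then runs every
#' analysis stage and writes to `out`: the simulated tables, `peaks.csv`,
#' `table1.csv` (preference-function variation), `table2.csv` (animal-model
#' genetic estimates), `table3.csv` (reaction-norm tests), `span.csv`,
#' figures (`preference_functions.png`, `reaction_norms.png`,
#' `family_vs_species.png`), and `manifest.json`.  When the run is
#' simulated, parameter-recovery diagnostics against the generating truth
#' are appended to the manifest.
#'
#' @param config A `run_config` (see [read_run_config()]), or a path to a
#'   JSON configuration.
#' @param out Output directory.
#' @param seed Overrides `config$seed`.
#' @param input_dir Optional directory with `trials.csv` and
#'   `individuals.csv` to analyse instead of simulating.
#' @return Invisibly, a list with all fitted stage objects.
#' @export
run_pipeline <- function(config, out, seed = NULL, input_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required (config$seed or `seed`)")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  truth <- NULL
  if (is.null(input_dir)) {
    sim <- simulate_experiment(config$design, config$arch, config$species,
                               seed = seed)
    message("simulate: ", nrow(sim$individuals), " individuals, ",
            nrow(sim$trials), " trials")
    write_sim(sim, out)
    trials <- sim$trials
    individuals <- sim$individuals
    truth <- sim$truth
  } else {
    trials <- read_trials(file.path(input_dir, "trials.csv"))
    individuals <- read_individuals(file.path(input_dir, "individuals.csv"))
    set.seed(seed)
  }

  # stage: preference functions
  peaks <- peak_preferences(trials)
  message("preference functions: ", nrow(peaks), " females fitted, ",
          sum(peaks$flag == "flat"), " flat, ",
          sum(peaks$flag == "boundary"), " boundary-flagged")
  write_table(peaks, out, "peaks.csv")

  # stage: preference-function variation (Table 1 style)
  pv <- fit_preference_variation(trials, alpha = config$alpha)
  write_table(pv$tests, out, "table1.csv")
  message("preference variation: family x quadratic p = ",
          signif(pv$key_test$p, 3))

  # stage: animal models (Table 2 style)
  filt_m <- apply_inclusion_filter(individuals, "heritability", sex = "male",
                                   replicates_per_sex = config$design$replicates_per_sex)
  males <- filt_m$individuals[filt_m$individuals$sex == "male", ]
  message("heritability filter (males): ", length(filt_m$families),
          " families kept")
  am_sig <- fit_animal_model(
    data.frame(id = males$id, family = males$family,
               replicate = males$replicate, value = males$signal_hz),
    config$chain)

  filt_f <- apply_inclusion_filter(individuals, "heritability", sex = "female",
                                   replicates_per_sex = config$design$replicates_per_sex)
  pk_ok <- peaks[peaks$flag != "flat" & peaks$family %in% filt_f$families, ]
  message("heritability filter (females): ", length(filt_f$families),
          " families kept")
  am_pref <- fit_animal_model(
    data.frame(id = pk_ok$female_id, family = pk_ok$family,
               replicate = pk_ok$replicate, value = pk_ok$peak_hz),
    config$chain)

  joint <- assemble_joint_table(peaks, individuals,
                                replicates_per_sex = config$design$replicates_per_sex)
  message("correlation filter: ", length(unique(joint$family)),
          " families with both sexes")
  biv <- data.frame(id = joint$id, family = joint$family,
                    replicate = joint$replicate, value = joint$value,
                    trait = ifelse(joint$sex == "male", "signal", "preference"))
  am_biv <- fit_animal_model(biv, config$chain)

  fmt <- function(e) sprintf("%.3f (%.3f-%.3f)", e$point, e$lower, e$upper)
  table2 <- data.frame(
    quantity = c("h2_signal", "CV_A_signal", "h2_preference",
                 "CV_A_preference", "r_G"),
    estimate = c(fmt(am_sig$estimates$h2), fmt(am_sig$estimates$CV_A),
                 fmt(am_pref$estimates$h2), fmt(am_pref$estimates$CV_A),
                 fmt(am_biv$estimates$r_G)),
    point = c(am_sig$estimates$h2$point, am_sig$estimates$CV_A$point,
              am_pref$estimates$h2$point, am_pref$estimates$CV_A$point,
              am_biv$estimates$r_G$point),
    stringsAsFactors = FALSE
  )
  write_table(table2, out, "table2.csv")
  write_table(am_biv$samples, out, "posterior_bivariate.csv")

  # stage: reaction norms (Table 3 style)
  rn <- reaction_norm_tests(joint, alpha = config$alpha)
  scen <- classify_scenario(rn)
  table3 <- rbind(
    f_test_row(rn$family_sas, "family (synthetic denominator)"),
    f_test_row(rn$family_scheffe, "family (Scheffe: residual denominator)"),
    f_test_row(rn$sex_test, "sex"),
    f_test_row(rn$interaction_test, "family x sex")
  )
  write_table(table3, out, "table3.csv")
  message("reaction norm: scenario ", scen$label)

  # stage: comparative span
  lines_obj <- family_reaction_norm_lines(joint)
  bg <- species_background()
  near <- nearest_species(config$species$mean_frequency, bg)
  sp_sig <- span_fraction(lines_obj$means$signal,
                          config$species$mean_frequency,
                          near$mean_signal, trait = "signal")
  sp_pref <- span_fraction(lines_obj$means$preference,
                           config$species$mean_frequency +
                             config$arch$preference_offset,
                           near$mean_peak, trait = "peak")
  span_tab <- data.frame(
    trait = c(sp_sig$trait, sp_pref$trait),
    family_range = c(sp_sig$family_range, sp_pref$family_range),
    species_gap = c(sp_sig$species_gap, sp_pref$species_gap),
    span_fraction = c(sp_sig$span_fraction, sp_pref$span_fraction),
    nearest_species = near$species,
    stringsAsFactors = FALSE
  )
  write_table(span_tab, out, "span.csv")

  # figures
  png(file.path(out, "preference_functions.png"), 900, 600)
  op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  some <- utils::head(unique(trials$female_id), 6)
  for (fid in some) {
    pf <- fit_preference_function(trials[trials$female_id == fid, ])
    plot(pf, main = fid)
  }
  par(op); dev.off()
  png(file.path(out, "reaction_norms.png"), 600, 600)
  plot(lines_obj); dev.off()
  png(file.path(out, "family_vs_species.png"), 600, 600)
  plot_family_vs_species(lines_obj$means, bg); dev.off()

  manifest <- list(
    package = "sigpref", version = as.character(packageVersion("sigpref")),
    seed = seed, alpha = config$alpha,
    chain = unclass(config$chain),
    counts = list(individuals = nrow(individuals), trials = nrow(trials),
                  females_fitted = nrow(peaks),
                  families_heritability_males = length(filt_m$families),
                  families_heritability_females = length(filt_f$families),
                  families_correlation = length(unique(joint$family))),
    results = list(pref_variation_p = pv$key_test$p,
                   h2_signal = am_sig$estimates$h2$point,
                   h2_preference = am_pref$estimates$h2$point,
                   r_G = am_biv$estimates$r_G$point,
                   scenario = scen$label,
                   span_fraction_signal = sp_sig$span_fraction,
                   span_fraction_preference = sp_pref$span_fraction)
  )
  if (!is.null(truth)) {
    manifest$recovery <- list(
      V_A_signal = list(truth = 2 * truth$arch$G[1, 1],
                        estimate = am_sig$estimates$V_A$point),
      V_A_preference = list(truth = 2 * truth$arch$G[2, 2],
                            estimate = am_pref$estimates$V_A$point),
      r_G = list(truth = truth$r_fam,
                 estimate = am_biv$estimates$r_G$point)
    )
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(peaks = peaks, pref_variation = pv, animal_signal = am_sig,
                 animal_preference = am_pref, animal_bivariate = am_biv,
                 reaction_norm = rn, scenario = scen, lines = lines_obj,
                 span = span_tab, manifest = manifest))
}
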