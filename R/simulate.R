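# Synthetic full-sib split-family experiments with known genetic
# architecture.  Draw order is fixed and documented so that a single seed
# makes the whole experiment reproducible:
#   1. bivariate family effects (one draw per family, from G)
#   2. replicate effects (per family x sex x replicate)
#   3. individual within-family deviations (males then females, per family)
#   4. male signal measurement noise
#   5. per-female curve parameters and playback counts (per female, in
#      individual order)

# Draw n rows from N(0, Sigma) for a possibly singular 2x2 Sigma.
rmvnorm2 <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(2L * n), n, 2L)
  z %*% (t(e$vectors) * sqrt(lam))
}

#' Simulate individuals of a full-sib split-family experiment
#'
#' Draws, for each family, a bivariate family effect from the between-family
#' covariance `G` centred on the species trait means; replicate
#' (rearing-plant) effects nested within family and sex; and individual
#' within-family deviations.  Males additionally receive an observed signal
#' value: the latent value plus measurement noise averaged over
#' `signals_per_male` recorded signals.
#'
#' @param design A [study_design()].
#' @param arch A [genetic_architecture()].
#' @param species A [species_params()].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return A data frame with one row per individual: `id`, `family`,
#'   `replicate`, `sex` (`"male"`/`"female"`), `latent_hz` (true signal
#'   frequency for males, true peak preference for females), and `signal_hz`
#'   (males only, `NA` for females).
#' @export
#' @examples
#' ind <- simulate_families(study_design(n_families = 4), seed = 1)
#' table(ind$family, ind$sex)
simulate_families <- function(design = study_design(),
                              arch = genetic_architecture(),
                              species = ptelea_params(),
                              seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(arch, "genetic_architecture"),
            inherits(species, "species_params"))
  if (!is.null(seed)) set.seed(seed)
  nf <- design$n_families
  nr <- design$replicates_per_sex
  mu <- c(species$mean_frequency,
          species$mean_frequency + arch$preference_offset)

  fam_ids <- sprintf("F%02d", seq_len(nf))
  fam_eff <- rmvnorm2(nf, arch$G)

  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    # replicate effects: males (trait 1) then females (trait 2)
    rep_m <- rnorm(nr, 0, sqrt(arch$V_rep[1]))
    rep_f <- rnorm(nr, 0, sqrt(arch$V_rep[2]))

    nm <- design$males_per_replicate * nr
    nfem <- design$females_per_replicate * nr
    dev_m <- rnorm(nm, 0, sqrt(arch$V_within[1]))
    dev_f <- rnorm(nfem, 0, sqrt(arch$V_within[2]))

    rep_idx_m <- rep(seq_len(nr), each = design$males_per_replicate)
    rep_idx_f <- rep(seq_len(nr), each = design$females_per_replicate)

    latent_m <- mu[1] + fam_eff[f, 1] + rep_m[rep_idx_m] + dev_m
    latent_f <- mu[2] + fam_eff[f, 2] + rep_f[rep_idx_f] + dev_f

    meas <- rowMeans(matrix(
      rnorm(nm * arch$signals_per_male, 0, arch$signal_noise_sd),
      nm, arch$signals_per_male))
    obs_m <- latent_m + meas

    out[[f]] <- data.frame(
      id = c(sprintf("%s_M%02d", fam_ids[f], seq_len(nm)),
             sprintf("%s_F%02d", fam_ids[f], seq_len(nfem))),
      family = fam_ids[f],
      replicate = c(sprintf("%s.M.r%d", fam_ids[f], rep_idx_m),
                    sprintf("%s.F.r%d", fam_ids[f], rep_idx_f)),
      sex = rep(c("male", "female"), c(nm, nfem)),
      latent_hz = c(latent_m, latent_f),
      signal_hz = c(obs_m, rep(NA_real_, nfem)),
      stringsAsFactors = FALSE
    )
  }
  ind <- do.call(rbind, out)
  rownames(ind) <- NULL
  attr(ind, "family_effects") <- data.frame(family = fam_ids,
                                            signal = fam_eff[, 1],
                                            preference = fam_eff[, 2])
  ind
}

#' Simulate one female's playback trials
#'
#' The female's expected response to a stimulus of frequency `s` is a
#' Gaussian-shaped unimodal curve centred on her latent peak preference:
#' `R * exp(-(s - peak)^2 / (2 w^2))`, where `R` is her response level
#' (lognormal around `response_scale`) and `w` her preference width
#' (truncated normal around `width_mean`).  Counts are negative binomial
#' with dispersion `count_noise` (Poisson when 0).
#'
#' @param female One row of the individuals table (a female).
#' @param grid Stimulus grid, e.g. from [make_stimulus_grid()].
#' @param arch A [genetic_architecture()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Data frame with one row per stimulus: `female_id`, `family`,
#'   `replicate`, `stimulus_hz`, `response_count`.
#' @export
simulate_playback <- function(female, grid, arch = genetic_architecture(),
                              seed = NULL) {
  stopifnot(inherits(arch, "genetic_architecture"))
  if (!is.null(seed)) set.seed(seed)
  if (!identical(female$sex, "female")) {
    stop("`female` must be a female individual record")
  }
  resp <- arch$response_scale * exp(rnorm(1L, 0, arch$responsiveness_sd))
  w <- max(5, rnorm(1L, arch$width_mean, arch$width_sd))
  mu <- resp * exp(-(grid - female$latent_hz)^2 / (2 * w^2))
  counts <- if (arch$count_noise <= 1e-12) {
    rpois(length(grid), mu)
  } else {
    rnbinom(length(grid), mu = mu, size = 1 / arch$count_noise)
  }
  data.frame(female_id = female$id, family = female$family,
             replicate = female$replicate, stimulus_hz = grid,
             response_count = counts, stringsAsFactors = FALSE)
}

#' Simulate a complete playback experiment
#'
#' Runs [simulate_families()] and then [simulate_playback()] for every
#' female (in individual order), under a single seed.
#'
#' @inheritParams simulate_families
#' @return An object of class `sigpref_sim`: a list with `individuals`,
#'   `trials`, `grid`, and `truth` (the generating design, architecture and
#'   species parameters plus the realized family effects).
#' @export
#' @examples
#' sim <- simulate_experiment(study_design(n_families = 3), seed = 42)
#' head(sim$trials)
simulate_experiment <- function(design = study_design(),
                                arch = genetic_architecture(),
                                species = ptelea_params(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- simulate_families(design, arch, species, seed = NULL)
  grid <- make_stimulus_grid(species)
  females <- ind[ind$sex == "female", , drop = FALSE]
  trials <- vector("list", nrow(females))
  for (i in seq_len(nrow(females))) {
    trials[[i]] <- simulate_playback(females[i, ], grid, arch, seed = NULL)
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  structure(
    list(individuals = ind, trials = trials, grid = grid,
         truth = list(design = unclass(design), arch = unclass(arch),
                      species = unclass(species), seed = seed,
                      family_effects = attr(ind, "family_effects"),
                      r_fam = family_correlation(arch))),
    class = "sigpref_sim"
  )
}

#' @export
print.sigpref_sim <- function(x, ...) {
  cat("Simulated split-family experiment:",
      length(unique(x$individuals$family)), "families,",
      sum(x$individuals$sex == "male"), "males,",
      sum(x$individuals$sex == "female"), "females,",
      nrow(x$trials), "playback trials\n")
  invisible(x)
}

#' Apply the family inclusion filter
#'
#' Retains families with at least `min_per_cell` individuals in every
#' (sex, replicate) rearing cell, with all `replicates_per_sex` cells
#' present.  The heritability stage requires only the focal sex's cells;
#' the correlation stage requires both sexes.
#'
#' @param individuals Individuals table (as from [simulate_families()]).
#' @param stage `"correlation"` (both sexes must qualify) or
#'   `"heritability"` (only `sex` must qualify).
#' @param sex Focal sex for the heritability stage.
#' @param min_per_cell Minimum individuals per (sex, replicate) cell.
#' @param replicates_per_sex Number of replicate cells each qualifying sex
#'   must have.
#' @return List with `individuals` (rows of kept families) and `families`
#'   (kept family ids).
#' @export
apply_inclusion_filter <- function(individuals,
                                   stage = c("correlation", "heritability"),
                                   sex = c("male", "female"),
                                   min_per_cell = 2L,
                                   replicates_per_sex = 2L) {
  stage <- match.arg(stage)
  sex <- match.arg(sex)
  if (nrow(individuals) == 0L) {
    return(list(individuals = individuals, families = character(0)))
  }
  sexes <- if (stage == "correlation") c("male", "female") else sex

  qualifies <- function(fam_rows, s) {
    rows <- fam_rows[fam_rows$sex == s, , drop = FALSE]
    if (nrow(rows) == 0L) return(FALSE)
    cells <- table(rows$replicate)
    length(cells) == replicates_per_sex && all(cells >= min_per_cell)
  }
  fams <- unique(individuals$family)
  keep <- vapply(fams, function(f) {
    fam_rows <- individuals[individuals$family == f, , drop = FALSE]
    all(vapply(sexes, qualifies, logical(1), fam_rows = fam_rows))
  }, logical(1))
  kept <- fams[keep]
  list(individuals = individuals[individuals$family %in% kept, , drop = FALSE],
       families = kept)
}

#' Canonical signal-preference variation scenarios
#'
#' Generating architectures for the eight canonical regimes of
#' signal-preference genetic variation (labels `A`-`H`), used to exercise
#' the reaction-norm classifier:
#'
#' * `A`: strong correlation (r = 1), parallel norms, population-level
#'   correspondence; `C`: the same with a 20 Hz population-level mismatch;
#' * `B`: no genetic variation in either trait;
#' * `D`/`E`: intermediate correlation (r = 0.6) with reduced preference
#'   variance, with (`D`) and without (`E`) population-level mismatch;
#' * `F`: independent signal and preference family values (r = 0), both
#'   with full variance;
#' * `G`: genetic variation in the signal only;
#' * `H`: pure crossing (r = -1, zero family-average variance).
#'
#' The presets switch rearing-plant (replicate) variance and male
#' measurement noise off, and use equal within-family variances in the two
#' sexes (SD 5 Hz) against a between-family SD of 8 Hz, so the
#' classification reflects genetic architecture alone.
#'
#' @param panel One of `"A"` to `"H"`.
#' @return A [genetic_architecture()].
#' @export
scenario_architecture <- function(panel = c("A", "B", "C", "D", "E", "F",
                                            "G", "H")) {
  panel <- match.arg(panel)
  v <- 64
  preset <- switch(panel,
    A = list(G = matrix(v, 2, 2), offset = 0),
    B = list(G = matrix(0, 2, 2), offset = 0),
    C = list(G = matrix(v, 2, 2), offset = 20),
    D = list(G = matrix(c(v, 19.2, 19.2, 16), 2, 2), offset = 20),
    E = list(G = matrix(c(v, 19.2, 19.2, 16), 2, 2), offset = 0),
    F = list(G = diag(c(v, v)), offset = 0),
    G = list(G = diag(c(v, 0.25)), offset = 0),
    H = list(G = matrix(c(v, -v, -v, v), 2, 2), offset = 0)
  )
  genetic_architecture(G = preset$G, V_rep = c(0, 0), V_within = c(25, 25),
                       preference_offset = preset$offset, signal_noise_sd = 0)
}

#' Write / read the simulated tables
#'
#' `write_sim()` writes `trials.csv`, `individuals.csv` and `truth.json`
#' into `dir`; `read_trials()` and `read_individuals()` read them back.
#'
#' @param sim A `sigpref_sim` object.
#' @param dir Output directory (created if needed).
#' @return `write_sim()` returns the paths invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sigpref_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "individuals.csv", "truth.json"))
  write.csv(sim$trials, paths[1], row.names = FALSE)
  write.csv(sim$individuals, paths[2], row.names = FALSE)
  truth <- sim$truth
  truth$arch$G <- as.vector(truth$arch$G)  # flatten for JSON round-trip
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' @rdname write_sim
#' @param path File path.
#' @export
read_trials <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_sim
#' @export
read_individuals <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
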