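# Synthetic full-sib split-family experiment generator.

test_that("stimulus grid spans the offsets symmetrically around the mean", {
  grid <- make_stimulus_grid(ptelea_params())
  expect_length(grid, 19L)
  expect_equal(min(grid), 298)
  expect_equal(max(grid), 378)
  expect_true(338 %in% grid)
  expect_equal(grid, sort(grid))
  expect_false(anyDuplicated(grid) > 0)

  # enumerated by hand for the low-frequency species
  grid_v <- make_stimulus_grid(viburnum_params())
  expect_equal(grid_v,
               sort(c(185, 185 + c(2, 4, 6, 8, 10, 15, 20, 30, 40),
                      185 - c(2, 4, 6, 8, 10, 15, 20, 30, 40))))
  expect_length(grid_v, 2 * 9 + 1)
  expect_equal(range(grid_v), c(145, 225))

  # degenerate grid: no offsets
  sp <- species_params("deg", 185, offsets = numeric(0))
  expect_equal(make_stimulus_grid(sp), 185)

  # invalid offsets rejected before a duplicate grid can arise
  expect_error(species_params("bad", 300, offsets = c(0, 2)), "positive")
  expect_error(species_params("bad", 300, offsets = c(2, 2, 4)), "increasing")
})

test_that("zero-variance architecture collapses to the species means", {
  arch <- genetic_architecture(G = matrix(0, 2, 2), V_rep = c(0, 0),
                               V_within = c(0, 0), signal_noise_sd = 0)
  ind <- simulate_families(study_design(n_families = 3), arch,
                           ptelea_params(), seed = 1)
  expect_true(all(ind$latent_hz == 338))
  expect_true(all(ind$signal_hz[ind$sex == "male"] == 338))
  expect_true(all(is.na(ind$signal_hz[ind$sex == "female"])))
})

test_that("generator is deterministic given the seed", {
  s1 <- simulate_experiment(study_design(n_families = 4),
                            genetic_architecture(), ptelea_params(),
                            seed = 77)
  s2 <- simulate_experiment(study_design(n_families = 4),
                            genetic_architecture(), ptelea_params(),
                            seed = 77)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$trials, s2$trials)
  s3 <- simulate_experiment(study_design(n_families = 4),
                            genetic_architecture(), ptelea_params(),
                            seed = 78)
  expect_false(identical(s1$trials, s3$trials))
})

test_that("variance bookkeeping: family-mean variance matches the law of total variance", {
  # G11 = 64, V_within = 50, 200 families x 50 males
  arch <- genetic_architecture(G = diag(c(64, 64)), V_rep = c(0, 0),
                               V_within = c(50, 50), signal_noise_sd = 0)
  des <- study_design(n_families = 200, replicates_per_sex = 2,
                      males_per_replicate = 25)
  ind <- simulate_families(des, arch, ptelea_params(), seed = 5)
  m <- ind[ind$sex == "male", ]
  fam_means <- tapply(m$latent_hz, m$family, mean)
  expected <- 64 + 50 / 50
  # 3 Monte-Carlo SEs of a variance over 200 families
  se <- sqrt(2 / 199) * expected
  expect_lt(abs(var(as.numeric(fam_means)) - expected), 3 * se)

  # within-family variance recovers V_within
  wf <- mean(tapply(m$latent_hz, m$family, var))
  expect_lt(abs(wf - 50), 3 * sqrt(2 / (200 * 49)) * 50)
})

test_that("high family-level correlation survives in family means", {
  G <- matrix(c(64, 0.9 * 64, 0.9 * 64, 64), 2)
  arch <- genetic_architecture(G = G, V_rep = c(0, 0), V_within = c(25, 25),
                               signal_noise_sd = 0)
  des <- study_design(n_families = 500, females_per_replicate = 5,
                      males_per_replicate = 5)
  ind <- simulate_families(des, arch, ptelea_params(), seed = 9)
  sig <- tapply(ind$latent_hz[ind$sex == "male"],
                ind$family[ind$sex == "male"], mean)
  prf <- tapply(ind$latent_hz[ind$sex == "female"],
                ind$family[ind$sex == "female"], mean)
  # attenuation from within-family sampling noise (25/10 per mean) is mild
  expect_gt(cor(as.numeric(sig), as.numeric(prf[names(sig)])), 0.8)
})

test_that("playback responses are unimodal around the latent peak", {
  grid <- make_stimulus_grid(ptelea_params())
  fem <- data.frame(id = "x", family = "F", replicate = "r", sex = "female",
                    latent_hz = 330, signal_hz = NA_real_)
  arch <- genetic_architecture(count_noise = 0, responsiveness_sd = 0,
                               width_sd = 0)
  tr <- simulate_playback(fem, grid, arch, seed = 3)
  expect_equal(nrow(tr), 19L)
  expect_true(all(tr$response_count >= 0))
  expect_true(all(tr$response_count == round(tr$response_count)))

  # noiseless expectation: argmax of the expected curve at the grid point
  # nearest the latent peak
  mu <- arch$response_scale * exp(-(grid - 330)^2 / (2 * arch$width_mean^2))
  expect_equal(grid[which.max(mu)], grid[which.min(abs(grid - 330))])

  # null responder
  arch0 <- genetic_architecture(response_scale = 0)
  tr0 <- simulate_playback(fem, grid, arch0, seed = 4)
  expect_true(all(tr0$response_count == 0))

  expect_error(simulate_playback(transform(fem, sex = "male"), grid, arch),
               "female")
})

test_that("inclusion filter keeps exactly the families with full cells", {
  mk <- function(fam, sex, rep, k) {
    data.frame(id = paste0(fam, sex, rep, seq_len(k)), family = fam,
               replicate = paste(fam, sex, rep), sex = sex,
               stringsAsFactors = FALSE)
  }
  full <- function(fam) rbind(mk(fam, "male", "r1", 2), mk(fam, "male", "r2", 2),
                              mk(fam, "female", "r1", 2), mk(fam, "female", "r2", 2))
  # 10 families, 3 deficient in different ways
  ind <- do.call(rbind, lapply(sprintf("A%02d", 1:7), full))
  bad1 <- full("B01")[-1, ]                       # one male cell short
  bad2 <- rbind(mk("B02", "female", "r1", 1))     # single female, one cell
  bad3 <- full("B03")[1:6, ]                      # missing a female replicate
  all_ind <- rbind(ind, bad1, bad2, bad3)

  res <- apply_inclusion_filter(all_ind, stage = "correlation")
  expect_setequal(res$families, sprintf("A%02d", 1:7))

  # brute-force oracle over the same table
  keep <- vapply(unique(all_ind$family), function(f) {
    d <- all_ind[all_ind$family == f, ]
    ok <- TRUE
    for (s in c("male", "female")) {
      cells <- table(d$replicate[d$sex == s])
      ok <- ok && length(cells) == 2 && all(cells >= 2)
    }
    ok
  }, logical(1))
  expect_setequal(res$families, unique(all_ind$family)[keep])

  # heritability stage: only the focal sex's cells matter
  resm <- apply_inclusion_filter(all_ind, stage = "heritability", sex = "male")
  expect_true("B03" %in% resm$families)   # females deficient, males fine
  expect_false("B01" %in% resm$families)

  # empty input is not an error
  res0 <- apply_inclusion_filter(all_ind[0, ])
  expect_length(res0$families, 0L)

  # monotonicity: adding individuals never removes a family
  extra <- mk("B02", "male", "r1", 3)
  res2 <- apply_inclusion_filter(rbind(all_ind, extra), stage = "correlation")
  expect_true(all(res$families %in% res2$families))
})

test_that("written tables round-trip losslessly", {
  sim <- small_sim(n_families = 3, seed = 10)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  tr <- read_trials(file.path(dir, "trials.csv"))
  ind <- read_individuals(file.path(dir, "individuals.csv"))
  expect_identical(tr$female_id, sim$trials$female_id)
  expect_equal(tr$response_count, sim$trials$response_count)
  expect_equal(ind$signal_hz, sim$individuals$signal_hz)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(matrix(truth$arch$G, 2, 2), sim$truth$arch$G)
})
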