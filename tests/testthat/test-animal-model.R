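# Pseudo-pedigree, relationship matrix, posterior summaries, and the Gibbs
# animal model.

test_that("pseudo-pedigree adds two founders per family", {
  ind <- data.frame(id = sprintf("i%03d", 1:(15 * 23)),
                    family = rep(sprintf("F%02d", 1:15), each = 23))
  ped <- build_pseudo_pedigree(ind)
  expect_equal(nrow(ped), 15 * 23 + 30)
  expect_true(all(is.na(ped$sire[1:30])))
  off <- ped[-(1:30), ]
  expect_true(all(off$sire == paste0(ind$family, "_sire")))
})

test_that("relationship matrix matches path counting", {
  # two full sibs
  ped <- build_pseudo_pedigree(data.frame(id = c("x", "y"),
                                          family = c("F1", "F1")))
  A <- additive_relationship(ped)
  expect_equal(A["x", "y"], 0.5)
  expect_equal(unname(diag(A)), rep(1, nrow(A)))

  # two singleton families: unrelated
  ped2 <- build_pseudo_pedigree(data.frame(id = c("x", "y"),
                                           family = c("F1", "F2")))
  A2 <- additive_relationship(ped2)
  expect_equal(A2["x", "y"], 0)

  # constructed half sibs: shared sire only
  ped3 <- data.frame(id = c("s", "d1", "d2", "x", "y"),
                     sire = c(NA, NA, NA, "s", "s"),
                     dam = c(NA, NA, NA, "d1", "d2"))
  A3 <- additive_relationship(ped3)
  expect_equal(A3["x", "y"], 0.25)

  # founders have zero off-diagonals; matrix is PSD (Cholesky succeeds)
  sim <- small_sim(n_families = 4, seed = 60)
  A4 <- additive_relationship(build_pseudo_pedigree(sim$individuals))
  expect_equal(unname(A4["F01_sire", c("F01_dam", "F02_sire", "F02_dam")]),
               c(0, 0, 0))
  expect_silent(chol(A4 + diag(1e-10, nrow(A4))))

  # the sampler's family + Mendelian decomposition implies exactly this A
  # among offspring: Va/2 shared within families, Va/2 individual
  fam <- sim$individuals$family
  ids <- sim$individuals$id
  implied <- 0.5 * outer(fam, fam, "==") + 0.5 * diag(length(ids))
  expect_equal(unname(A4[ids, ids]), unname(implied))

  # cycles are detected
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = c(NA, NA))
  expect_error(additive_relationship(bad), "cycle")
})

test_that("cva follows its formula and inverts the printed values", {
  expect_equal(cva(0, 10), 0)
  expect_equal(cva(100, 100), 10)
  # CV_A 2.37 at mean 338 corresponds to V_A ~ 64.2
  V_A <- (2.37 * 338 / 100)^2
  expect_equal(V_A, 64.17, tolerance = 1e-3)
  expect_equal(cva(64.17, 338), 2.37, tolerance = 1e-3)
  expect_error(cva(4, 0), "positive")
  expect_error(cva(-1, 10), ">= 0")
})

test_that("posterior summaries: HPD by exhaustive scan, mode by shrunk kernel", {
  # uniform grid: any 95%-mass window works; leftmost is returned
  x <- 1:1000
  s <- summarize_posterior(x)
  expect_equal(s$lower, 1)
  expect_equal(s$upper, 950)

  # Gaussian sample: match a brute-force shortest-window scan
  set.seed(7)
  g <- rnorm(20000, 3, 2)
  s2 <- summarize_posterior(g)
  xs <- sort(g)
  m <- ceiling(0.95 * length(g))
  widths <- xs[m:length(g)] - xs[1:(length(g) - m + 1)]
  j <- which.min(widths)
  expect_equal(s2$lower, xs[j])
  expect_equal(s2$upper, xs[j + m - 1])
  # the shrunk-bandwidth mode is noisier than the mean; loose anchor only
  expect_lt(abs(s2$point - 3), 0.5)
  expect_true(s2$lower <= s2$point && s2$point <= s2$upper)

  # bimodal with taller left mode: the point estimate sits in the left mode
  set.seed(8)
  b <- c(rnorm(3000, -4, 0.4), rnorm(1500, 4, 0.4))
  s3 <- summarize_posterior(b)
  expect_lt(s3$point, 0)

  expect_error(summarize_posterior(rnorm(50)), "100")
})

test_that("univariate animal model agrees with the full-sib REML oracle", {
  # V_A ~ 2 x between-family REML component on the same data
  arch <- genetic_architecture(G = diag(c(20, 20)), V_rep = c(5, 5),
                               V_within = c(60, 60), signal_noise_sd = 0)
  des <- study_design(n_families = 60, males_per_replicate = 8)
  ind <- simulate_families(des, arch, ptelea_params(), seed = 31)
  m <- ind[ind$sex == "male", ]
  df <- data.frame(id = m$id, family = m$family, replicate = m$replicate,
                   value = m$latent_hz)
  fit <- suppressWarnings(fit_animal_model(df, mcmc_config(), seed = 32))
  expect_true(all(fit$samples$h2 >= 0 & fit$samples$h2 <= 1))

  reml <- fit_variance_components(
    data.frame(family = df$family, replicate = df$replicate, value = df$value),
    "value", c("family", "replicate"), c("family", "replicate"))
  va_reml <- 2 * unname(reml$reml["family"])
  # posterior mean within the posterior spread of the REML anchor
  expect_lt(abs(mean(fit$samples$V_A) - va_reml),
            3 * sd(fit$samples$V_A))

  # determinism under the seed
  fit2 <- suppressWarnings(fit_animal_model(df, mcmc_config(), seed = 32))
  expect_identical(fit$samples, fit2$samples)
})

test_that("replicate variance ordering is detected", {
  des <- study_design(n_families = 30, males_per_replicate = 8)
  base <- function(vrep, seed) {
    arch <- genetic_architecture(G = diag(c(15, 15)), V_rep = c(vrep, vrep),
                                 V_within = c(60, 60), signal_noise_sd = 0)
    ind <- simulate_families(des, arch, ptelea_params(), seed = seed)
    m <- ind[ind$sex == "male", ]
    fit <- suppressWarnings(fit_animal_model(
      data.frame(id = m$id, family = m$family, replicate = m$replicate,
                 value = m$latent_hz),
      mcmc_config(iterations = 20000, burn_in = 10000, thin = 10),
      seed = seed + 1))
    mean(fit$samples$V_rep)
  }
  # paired simulations: zero vs large generating replicate variance
  ord <- vapply(1:6, function(i) base(0, 100 + i) < base(40, 200 + i),
                logical(1))
  expect_gte(mean(ord), 5 / 6)
})

test_that("bivariate model: identical family structure drives r_G to the ceiling", {
  # same family values feed both traits (distinct individuals per trait):
  # the genetic correlation must come out near 1
  set.seed(41)
  nfam <- 40
  fe <- rnorm(nfam, 0, 6)
  mk <- function(trait, n_per) {
    data.frame(
      id = paste0(trait, seq_len(nfam * n_per)),
      family = rep(sprintf("F%02d", 1:nfam), each = n_per),
      replicate = rep(sprintf("F%02d.%s.r%d", rep(1:nfam, each = n_per),
                              trait, rep(1:2, length.out = n_per)), 1),
      value = 338 + rep(fe, each = n_per) + rnorm(nfam * n_per, 0, 2),
      trait = trait, stringsAsFactors = FALSE)
  }
  d <- rbind(mk("signal", 6), mk("preference", 6))
  fit <- suppressWarnings(fit_animal_model(
    d, mcmc_config(iterations = 20000, burn_in = 10000, thin = 10),
    seed = 42))
  expect_true(all(abs(fit$samples$r_G) <= 1))
  expect_gt(fit$estimates$r_G$point, 0.8)
})

test_that("the posterior is robust to the prior variance split", {
  arch <- genetic_architecture(G = diag(c(20, 20)), V_rep = c(5, 5),
                               V_within = c(60, 60), signal_noise_sd = 0)
  ind <- simulate_families(study_design(n_families = 50, males_per_replicate = 8),
                           arch, ptelea_params(), seed = 51)
  m <- ind[ind$sex == "male", ]
  df <- data.frame(id = m$id, family = m$family, replicate = m$replicate,
                   value = m$latent_hz)
  cfg1 <- mcmc_config(iterations = 20000, burn_in = 10000, thin = 10)
  cfg2 <- mcmc_config(iterations = 20000, burn_in = 10000, thin = 10,
                      prior_split = c(0.5, 0.25, 0.25))
  f1 <- suppressWarnings(fit_animal_model(df, cfg1, seed = 52))
  f2 <- suppressWarnings(fit_animal_model(df, cfg2, seed = 53))
  expect_lt(abs(mean(f1$samples$h2) - mean(f2$samples$h2)),
            2 * sd(f1$samples$h2))
})

test_that("chain configuration is validated", {
  expect_error(mcmc_config(iterations = 1000, burn_in = 2000), "smaller")
  expect_error(mcmc_config(iterations = 1000, burn_in = 500, thin = 100),
               "100 samples")
  cfg <- mcmc_config(preset = "full")
  expect_equal(cfg$iterations, 1000000L)
  expect_equal(cfg$burn_in, 500000L)
  expect_equal(cfg$thin, 500L)
  expect_error(fit_animal_model(
    data.frame(id = "a", family = "F", replicate = "r", value = 1),
    mcmc_config()), "2 families")
})
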