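# Reaction-norm dissection: joint table assembly, the four tests, the
# scenario classifier, and family lines.

test_that("joint table stacks both sexes and applies the correlation filter", {
  sim <- small_sim(n_families = 5, seed = 70)
  pk <- peak_preferences(sim$trials)
  jt <- assemble_joint_table(pk, sim$individuals)
  expect_setequal(unique(jt$sex), c("male", "female"))
  # 5 families x (6 males + 6 females), minus any flat-flagged females
  expect_equal(sum(jt$sex == "male"), sum(sim$individuals$sex == "male"))
  expect_lte(sum(jt$sex == "female"), sum(pk$flag != "flat"))

  # a family with males only is excluded (and message logged)
  ind2 <- sim$individuals
  extra <- ind2[ind2$family == "F01" & ind2$sex == "male", ]
  extra$family <- "F99"
  extra$id <- paste0("Z", seq_len(nrow(extra)))
  extra$replicate <- sub("F01", "F99", extra$replicate)
  expect_message(
    jt2 <- assemble_joint_table(pk, rbind(ind2, extra)),
    "dropped"
  )
  expect_false("F99" %in% jt2$family)

  # no qualifying family at all -> error
  lone <- ind2[ind2$family == "F01" & ind2$sex == "male", ]
  expect_error(suppressMessages(assemble_joint_table(pk[0, ], lone)), "no families")
})

test_that("reaction-norm tests have the advertised structure", {
  sim <- small_sim(n_families = 8, seed = 71)
  jt <- joint_rows_from_individuals(sim$individuals)
  rn <- reaction_norm_tests(jt)
  # Scheffe denominator is the residual; its df is the residual df
  restab <- rn$anova$table
  expect_equal(rn$family_scheffe$df_den,
               restab$df[restab$term == "residual"])
  expect_identical(rn$family_scheffe$denominator, "residual")
  # family numerator df = families - 1
  expect_equal(rn$family_sas$df_num, 7)
  # synthetic denominator df is fractional in general and positive
  expect_gt(rn$family_sas$df_den, 0)
  # fewer than 3 families rejected
  expect_error(reaction_norm_tests(jt[jt$family %in% c("F01"), ]), "3 families")
})

test_that("degenerate equal values give zero numerator mean squares", {
  d <- rn_design(n_fam = 4, per_cell = 3)
  d$value <- 338
  d$id <- seq_len(nrow(d))
  rn <- reaction_norm_tests(d)
  tab <- rn$anova$table
  expect_equal(tab$MS, rep(0, nrow(tab)))
})

test_that("SAS-model significance implies Scheffe significance when denominators order", {
  # property over random datasets
  set.seed(72)
  for (i in 1:12) {
    arch <- scenario_architecture(sample(c("A", "C", "E", "F"), 1))
    ind <- simulate_families(study_design(n_families = 10,
                                          females_per_replicate = 3,
                                          males_per_replicate = 3),
                             arch, ptelea_params())
    rn <- reaction_norm_tests(joint_rows_from_individuals(ind))
    if (!is.na(rn$family_sas$p) && rn$family_sas$MS_den >= rn$family_scheffe$MS_den &&
        rn$family_sas$p < 0.05) {
      expect_lt(rn$family_scheffe$p, 0.05)
    }
  }
})

test_that("the reusable engine path reproduces reaction_norm_tests exactly", {
  # the calibration studies drive ems_engine/ems_mean_squares directly;
  # they must agree with the one-shot fitting function
  set.seed(74)
  ind <- simulate_families(study_design(n_families = 8,
                                        females_per_replicate = 3,
                                        males_per_replicate = 3),
                           scenario_architecture("E"), ptelea_params())
  rows <- joint_rows_from_individuals(ind)
  rn <- reaction_norm_tests(rows)

  d <- data.frame(family = rows$family,
                  replicate = paste(rows$family, rows$sex, rows$replicate,
                                    sep = "|"),
                  sex = rows$sex)
  eng <- ems_engine(d, c("family", "replicate", "sex", "family:sex"),
                    c("family", "replicate", "family:sex"))
  ms <- ems_mean_squares(eng, rows$value)[, 1]
  w <- ems_synth_weights(eng, "family")
  den <- sum(w * ms[names(w)])
  expect_equal(ms[["family"]] / den, rn$family_sas$F, tolerance = 1e-10)
  expect_equal(satterthwaite_df(w, ms, eng$df), rn$family_sas$df_den,
               tolerance = 1e-10)
  expect_equal(ms[["family"]] / ms[["residual"]], rn$family_scheffe$F,
               tolerance = 1e-10)
})

test_that("the scenario decision table maps constructed patterns", {
  mk <- function(ps, vb = c(male = 50, female = 50)) {
    ft <- function(p) structure(list(term = "t", F = 1, df_num = 1,
                                     df_den = 10, p = p), class = "f_test_result")
    structure(list(family_sas = ft(ps[1]), family_scheffe = ft(ps[2]),
                   interaction_test = ft(ps[3]), sex_test = ft(ps[4]),
                   var_between = vb, alpha = 0.05),
              class = "reaction_norm_tests")
  }
  a <- 0.0125
  lo <- a / 2; hi <- 0.5
  expect_equal(classify_scenario(mk(c(lo, lo, hi, hi)))$label, "A")
  expect_equal(classify_scenario(mk(c(lo, lo, hi, lo)))$label, "C")
  expect_equal(classify_scenario(mk(c(lo, lo, lo, lo)))$label, "D")
  expect_equal(classify_scenario(mk(c(lo, lo, lo, hi)))$label, "E")
  expect_equal(classify_scenario(mk(c(hi, lo, lo, hi)))$label, "F")
  expect_equal(classify_scenario(mk(c(hi, lo, lo, hi),
                                    vb = c(male = 50, female = 1)))$label, "G")
  expect_equal(classify_scenario(mk(c(hi, hi, lo, hi)))$label, "H")
  expect_equal(classify_scenario(mk(c(hi, hi, hi, hi)))$label, "B")
  # conflicting pattern: mismatch with no variation anywhere
  expect_equal(classify_scenario(mk(c(hi, hi, hi, lo)))$label, "indeterminate")
  # rationale names the tests
  expect_match(classify_scenario(mk(c(lo, lo, hi, hi)))$rationale, "Scheffe")
})

test_that("family lines count crossings correctly", {
  rows <- function(fams, sig, prf) {
    do.call(rbind, lapply(seq_along(fams), function(i) {
      data.frame(family = fams[i], replicate = "r",
                 sex = c("male", "male", "female", "female"),
                 value = c(sig[i], sig[i], prf[i], prf[i]))
    }))
  }
  # identical pairs: no crossing
  fl <- family_reaction_norm_lines(rows(c("a", "b"), c(330, 330), c(335, 335)))
  expect_equal(fl$crossings, 0L)
  # swapped ranks between sexes: one crossing
  fl2 <- family_reaction_norm_lines(rows(c("a", "b"), c(330, 340), c(340, 330)))
  expect_equal(fl2$crossings, 1L)
  expect_equal(fl2$crossing_fraction, 1)
  # pooled means recorded
  expect_equal(unname(fl2$pooled["signal"]), 335)
})

test_that("negative family correlations cross more than positive ones", {
  set.seed(73)
  frac <- function(r, seed) {
    G <- matrix(c(36, r * 36, r * 36, 36), 2)
    arch <- genetic_architecture(G = G, V_rep = c(0, 0), V_within = c(9, 9),
                                 signal_noise_sd = 0)
    ind <- simulate_families(study_design(n_families = 12,
                                          females_per_replicate = 3,
                                          males_per_replicate = 3),
                             arch, ptelea_params(), seed = seed)
    family_reaction_norm_lines(joint_rows_from_individuals(ind))$crossing_fraction
  }
  # paired comparison over 25 seeds
  wins <- vapply(1:25, function(i) frac(-0.8, 900 + i) > frac(0.8, 900 + i),
                 logical(1))
  expect_gt(mean(wins), 0.8)
})
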