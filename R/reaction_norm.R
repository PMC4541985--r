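# Reaction-norm dissection of the signal-preference relationship.  A single
# dependent variable stacks female peak preferences and male signal
# frequencies, with a sex indicator marking which trait a row carries.  A
# family's (signal mean, preference mean) pair is then a two-point reaction
# norm across "environments" = sexes, and G x E machinery applies:
#   * family over a synthesized denominator ("SAS model") tests for a
#     signal-preference genetic correlation r > 0 beyond mismatch;
#   * family over the residual MS ("Scheffe model") asks whether some
#     families remain distinct averaged across sexes, without assuming
#     equal variances in the two sexes;
#   * family x sex tests for genotype-level signal-preference mismatch
#     (r < 1, non-parallel norms);
#   * sex (fixed) tests for population-level signal-preference mismatch.

#' Assemble the joint signal-preference trait table
#'
#' Stacks female peak preferences and male mean signal frequencies into one
#' response column with a sex indicator, keeping only families that pass
#' the correlation-stage inclusion filter (both sexes present with at least
#' `min_per_cell` individuals in every replicate cell).  Females with flat
#' (undefined-peak) preference functions are dropped; boundary-flagged
#' peaks are kept.
#'
#' @param peaks Peak table from [peak_preferences()] (`female_id`, `family`,
#'   `replicate`, `peak_hz`, `flag`).
#' @param individuals Individuals table with male `signal_hz` values.
#' @param min_per_cell,replicates_per_sex Passed to
#'   [apply_inclusion_filter()].
#' @return Data frame with columns `id`, `family`, `replicate`, `sex`,
#'   `value` (Hz), one row per individual.
#' @export
assemble_joint_table <- function(peaks, individuals, min_per_cell = 2L,
                                 replicates_per_sex = 2L) {
  males <- individuals[individuals$sex == "male" & !is.na(individuals$signal_hz), ]
  fem <- peaks[peaks$flag != "flat" & !is.na(peaks$peak_hz), ]
  rows <- rbind(
    data.frame(id = males$id, family = males$family,
               replicate = males$replicate,
               sex = rep("male", nrow(males)),
               value = males$signal_hz, stringsAsFactors = FALSE),
    data.frame(id = fem$female_id, family = fem$family,
               replicate = fem$replicate,
               sex = rep("female", nrow(fem)),
               value = fem$peak_hz, stringsAsFactors = FALSE)
  )
  filt <- apply_inclusion_filter(rows, stage = "correlation",
                                 min_per_cell = min_per_cell,
                                 replicates_per_sex = replicates_per_sex)
  dropped <- setdiff(unique(rows$family), filt$families)
  if (length(dropped)) {
    message("assemble_joint_table: dropped ", length(dropped),
            " family(ies) failing the correlation-stage filter: ",
            paste(dropped, collapse = ", "))
  }
  if (length(filt$families) == 0L) {
    stop("no families with both sexes pass the inclusion filter")
  }
  out <- filt$individuals
  rownames(out) <- NULL
  out
}

# method-of-moments between-family variance for one sex (one-way ANOVA,
# unbalanced-safe n0), floored at zero
between_family_variance <- function(value, family) {
  f <- droplevels(factor(family))
  k <- nlevels(f)
  if (k < 2L) return(NA_real_)
  n_i <- tabulate(f)
  n <- sum(n_i)
  means <- tapply(value, f, mean)
  ss_b <- sum(n_i * (means - mean(value))^2)
  ss_w <- sum((value - means[f])^2)
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (n - k)
  n0 <- (n - sum(n_i^2) / n) / (k - 1)
  max(0, (ms_b - ms_w) / n0)
}

#' Reaction-norm tests of the signal-preference relationship
#'
#' Fits the joint mixed model (family, replicate and family x sex random,
#' sex fixed) and computes the four tests described above.  Replicate is
#' nested within family and sex by default (adults are re-housed by sex
#' onto separate plants); set `nesting = "family"` to share replicate
#' labels across sexes.
#'
#' @param rows Joint table from [assemble_joint_table()].
#' @param alpha Significance level used when reporting/classifying.
#' @param nesting `"family_sex"` (default) or `"family"`.
#' @return Object of class `reaction_norm_tests`: the ANOVA (`anova`), the
#'   four `f_test_result`s (`family_sas`, `family_scheffe`, `sex_test`,
#'   `interaction_test`), per-sex between-family variances
#'   (`var_between`), a Levene-style descriptive check of variance
#'   equality across sexes (`levene_p`, reported, never gating), and
#'   `alpha`.
#' @export
reaction_norm_tests <- function(rows, alpha = 0.05,
                                nesting = c("family_sex", "family")) {
  nesting <- match.arg(nesting)
  stopifnot(all(c("family", "replicate", "sex", "value") %in% names(rows)))
  if (length(unique(rows$family)) < 3L) {
    stop("need at least 3 families for the reaction-norm tests")
  }
  d <- data.frame(
    family = as.character(rows$family),
    sex = as.character(rows$sex),
    value = as.numeric(rows$value),
    stringsAsFactors = FALSE
  )
  d$replicate <- if (nesting == "family_sex") {
    paste(rows$family, rows$sex, rows$replicate, sep = "|")
  } else {
    paste(rows$family, rows$replicate, sep = "|")
  }

  anova <- mixed_anova(d, "value",
                       terms = c("family", "replicate", "sex", "family:sex"),
                       random = c("family", "replicate", "family:sex"))
  family_sas <- f_test(anova, "family", denominator = "synthetic")
  family_scheffe <- f_test(anova, "family", denominator = "residual")
  sex_test <- f_test(anova, "sex", denominator = "synthetic")
  interaction_test <- f_test(anova, "family:sex", denominator = "synthetic")

  # consistency: whenever the synthesized denominator is at least the
  # residual MS, SAS-model significance must imply Scheffe significance
  if (!is.na(family_sas$p) && !is.na(family_scheffe$p) &&
      family_sas$MS_den >= family_scheffe$MS_den &&
      family_sas$p < alpha && family_scheffe$p >= alpha) {
    warning("SAS-model family test significant but Scheffe test not, ",
            "despite synthetic denominator >= residual MS")
  }

  vb <- c(
    male = between_family_variance(d$value[d$sex == "male"],
                                   d$family[d$sex == "male"]),
    female = between_family_variance(d$value[d$sex == "female"],
                                     d$family[d$sex == "female"])
  )
  # Levene-style (Brown-Forsythe) descriptive check of equal variances
  lev_df <- data.frame(
    ad = abs(d$value - tapply(d$value, d$sex, median)[d$sex]),
    sex = d$sex)
  lev <- stats::anova(stats::lm(ad ~ sex, data = lev_df))
  levene_p <- lev[["Pr(>F)"]][1]

  structure(
    list(anova = anova, family_sas = family_sas,
         family_scheffe = family_scheffe, sex_test = sex_test,
         interaction_test = interaction_test,
         var_between = vb, levene_p = levene_p,
         alpha = alpha, n_families = length(unique(d$family)),
         nesting = nesting),
    class = "reaction_norm_tests"
  )
}

#' @export
print.reaction_norm_tests <- function(x, ...) {
  cat("Reaction-norm dissection of the signal-preference relationship\n")
  cat("  families:", x$n_families, " (replicate nesting:", x$nesting, ")\n\n")
  print(x$anova)
  cat("\n")
  print(x$family_sas)
  print(x$family_scheffe)
  print(x$sex_test)
  print(x$interaction_test)
  cat(sprintf("\nBetween-family variance: signal %.2f, preference %.2f Hz^2\n",
              x$var_between["male"], x$var_between["female"]))
  cat(sprintf("Levene-style equal-variance check across sexes: p = %.3g (descriptive)\n",
              x$levene_p))
  invisible(x)
}

#' Classify the signal-preference variation pattern
#'
#' Maps the significance pattern of the four reaction-norm tests, plus the
#' relative per-sex between-family variances, onto the canonical taxonomy
#' of signal-preference variation regimes (labels `A`-`H`):
#'
#' * `A`/`C`: strong genetic correlation (family significant over the
#'   synthesized denominator, no interaction), with population-level
#'   correspondence (`A`) or mismatch (`C`);
#' * `D`/`E`: 0 < r < 1 (family and interaction both significant), with
#'   mismatch (`D`) or correspondence (`E`);
#' * `F`/`G`: r << 1 (interaction without family), yet some families remain
#'   distinct (Scheffe significant); `G` when the preference shows little
#'   between-family variance relative to the signal, otherwise `F`;
#' * `H`: pure crossing (interaction only, Scheffe not significant);
#' * `B`: no significant genetic variation at all;
#' * `"indeterminate"` when the pattern is internally inconsistent.
#'
#' Because the decision consults four tests jointly, significance is called
#' at a Bonferroni-corrected level `alpha / 4` by default.
#'
#' @param tests A [reaction_norm_tests()] object.
#' @param alpha Per-test level for the classification; defaults to
#'   `tests$alpha / 4`.
#' @param low_variance_ratio Below this ratio of preference to signal
#'   between-family variance the `F`-vs-`G` branch is called `G`.
#' @return Object of class `scenario_label` with `label` and `rationale`.
#' @export
classify_scenario <- function(tests, alpha = NULL, low_variance_ratio = 0.2) {
  stopifnot(inherits(tests, "reaction_norm_tests"))
  if (is.null(alpha)) alpha <- tests$alpha / 4
  sig <- function(ft) !is.na(ft$p) && ft$p < alpha
  S <- sig(tests$family_sas)       # r > 0 beyond mismatch
  I <- sig(tests$interaction_test) # genotype-level mismatch (r < 1)
  C <- sig(tests$family_scheffe)   # some families distinct across sexes
  X <- sig(tests$sex_test)         # population-level mismatch

  vb <- tests$var_between
  ratio <- if (is.finite(vb["male"]) && vb["male"] > 0) {
    vb["female"] / vb["male"]
  } else {
    NA_real_
  }

  label <- if (S && !I) {
    if (!X) "A" else "C"
  } else if (S && I) {
    if (X) "D" else "E"
  } else if (!S && I) {
    if (C) {
      if (X) "indeterminate"
      else if (!is.na(ratio) && ratio < low_variance_ratio) "G"
      else "F"
    } else {
      if (!X) "H" else "indeterminate"
    }
  } else {  # neither family-over-synthetic nor interaction
    if (!C && !X) "B" else "indeterminate"
  }

  pattern <- sprintf(
    "family(SAS) %s, family(Scheffe) %s, family x sex %s, sex %s at alpha = %.4g; preference/signal between-family variance ratio = %.3g",
    ifelse(S, "significant", "ns"), ifelse(C, "significant", "ns"),
    ifelse(I, "significant", "ns"), ifelse(X, "significant", "ns"),
    alpha, ratio)
  structure(list(label = label, rationale = pattern, alpha = alpha),
            class = "scenario_label")
}

#' @export
print.scenario_label <- function(x, ...) {
  cat("Signal-preference variation scenario: ", x$label, "\n  ", x$rationale,
      "\n", sep = "")
  invisible(x)
}

#' Family reaction-norm lines (signal mean vs preference mean)
#'
#' Computes each family's (mean signal, mean peak preference) pair and the
#' number of pairwise crossings: two families cross when their rank order
#' differs between the sexes, the visual signature of signal-preference
#' mismatch.
#'
#' @param rows Joint table from [assemble_joint_table()].
#' @return Object of class `family_lines`: data frame `means` (`family`,
#'   `signal`, `preference`), `crossings` (count), `crossing_fraction`
#'   (of family pairs), and the pooled sex means.
#' @export
family_reaction_norm_lines <- function(rows) {
  m <- rows[rows$sex == "male", ]
  f <- rows[rows$sex == "female", ]
  fams <- sort(intersect(unique(m$family), unique(f$family)))
  means <- data.frame(
    family = fams,
    signal = as.numeric(tapply(m$value, factor(m$family, fams), mean)[fams]),
    preference = as.numeric(tapply(f$value, factor(f$family, fams), mean)[fams]),
    stringsAsFactors = FALSE
  )
  nfam <- nrow(means)
  crossings <- 0L
  if (nfam >= 2L) {
    for (i in seq_len(nfam - 1L)) {
      ds <- means$signal[i] - means$signal[(i + 1L):nfam]
      dp <- means$preference[i] - means$preference[(i + 1L):nfam]
      crossings <- crossings + sum(ds * dp < 0)
    }
  }
  n_pairs <- nfam * (nfam - 1L) / 2L
  structure(
    list(means = means, crossings = crossings,
         crossing_fraction = if (n_pairs > 0) crossings / n_pairs else NA_real_,
         pooled = c(signal = mean(m$value), preference = mean(f$value))),
    class = "family_lines"
  )
}

#' @export
print.family_lines <- function(x, ...) {
  cat("Family reaction-norm lines:", nrow(x$means), "families,",
      x$crossings, "pairwise crossings",
      sprintf("(fraction %.2f)\n", x$crossing_fraction))
  invisible(x)
}

#' @export
plot.family_lines <- function(x, ...) {
  rng <- range(c(x$means$signal, x$means$preference))
  plot(NA, xlim = c(0.8, 2.2), ylim = rng, xaxt = "n",
       xlab = "", ylab = "Frequency (Hz)", ...)
  axis(1, at = c(1, 2), labels = c("Male signal", "Female peak preference"))
  segments(1, x$means$signal, 2, x$means$preference, col = "grey30")
  arrows(0.9, x$pooled["signal"], 0.98, x$pooled["signal"], length = 0.08)
  arrows(2.1, x$pooled["preference"], 2.02, x$pooled["preference"],
         length = 0.08)
  invisible(x)
}
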