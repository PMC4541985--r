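# Test for genetic variation in overall preference-function shape.  The
# response is the raw number of female duetting responses per playback
# stimulus, modelled (on the Gaussian scale) with family, rearing-plant
# replicate nested within family, individual female nested within
# replicate, linear and quadratic stimulus-frequency regressors, and the
# family x linear and family x quadratic interactions.  Female preferences
# are curvilinear with intermediate peaks, so genetic variation in the
# preference function is indicated by the family x quadratic interaction.

#' Test for genetic variation in female preference functions
#'
#' Fits the overall preference-function mixed model to the playback trials
#' and reports the ANOVA with a synthesized-denominator F test per term.
#' Stimulus frequency is mean-centred before squaring, so all F statistics
#' are invariant to shifting every stimulus by a constant.  The key test is
#' the family x quadratic-stimulus interaction.
#'
#' @param trials Trials table with columns `female_id`, `family`,
#'   `replicate`, `stimulus_hz`, `response_count`.
#' @param alpha Significance level at which genetic variation in function
#'   shape is declared.
#' @return Object of class `preference_variation`: `anova`, `tests` (data
#'   frame of term, MS, F, df_num, df_den, p), `key_test` (the family x
#'   quadratic `f_test_result`), `significant`, `alpha`.
#' @export
fit_preference_variation <- function(trials, alpha = 0.05) {
  need <- c("female_id", "family", "replicate", "stimulus_hz",
            "response_count")
  stopifnot(all(need %in% names(trials)))
  if (length(unique(trials$family)) < 2L) {
    stop("the family x stimulus tests are undefined with a single family")
  }
  d <- data.frame(
    family = as.character(trials$family),
    replicate = as.character(trials$replicate),
    individual = as.character(trials$female_id),
    stim = trials$stimulus_hz - mean(trials$stimulus_hz),
    y = as.numeric(trials$response_count),
    stringsAsFactors = FALSE
  )
  d$stim2 <- d$stim^2
  terms <- c("family", "replicate", "individual", "stim", "stim2",
             "family:stim", "family:stim2")
  random <- c("family", "replicate", "individual", "family:stim",
              "family:stim2")
  anova <- mixed_anova(d, "y", terms = terms, random = random)
  fts <- lapply(terms, function(t) f_test(anova, t, denominator = "synthetic"))
  names(fts) <- terms
  tests <- do.call(rbind, lapply(fts, function(ft) {
    data.frame(term = ft$term, MS = ft$MS_num, F = ft$F, df_num = ft$df_num,
               df_den = ft$df_den, p = ft$p, denominator = ft$denominator,
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  key <- fts[["family:stim2"]]
  structure(
    list(anova = anova, tests = tests, key_test = key,
         significant = !is.na(key$p) && key$p < alpha, alpha = alpha,
         n_families = length(unique(d$family))),
    class = "preference_variation"
  )
}

#' @export
print.preference_variation <- function(x, ...) {
  cat("Genetic variation in overall preference functions (",
      x$n_families, " families)\n", sep = "")
  tab <- x$tests
  tab$MS <- signif(tab$MS, 4)
  tab$F <- round(tab$F, 2)
  tab$df_num <- round(tab$df_num, 1)
  tab$df_den <- round(tab$df_den, 1)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "MS", "F", "df_num", "df_den", "p")],
        row.names = FALSE)
  cat("\nKey family x quadratic-stimulus test: p =", signif(x$key_test$p, 3),
      if (x$significant) "=> genetic variation in preference-function shape\n"
      else "=> no significant variation at alpha =", x$alpha, "\n")
  invisible(x)
}
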