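#' Genetic architecture of the simulated population
#'
#' Describes the generating (co)variance structure for the two sex-limited
#' traits: male signal dominant frequency (trait 1) and female peak
#' preference (trait 2).  Under the full-sib coding used throughout, `G` is
#' the *between-family* covariance matrix; the additive genetic variance
#' reported by the animal model corresponds to `2 * diag(G)`, and the
#' family-level (genetic) correlation is `G[1,2] / sqrt(G[1,1] * G[2,2])`.
#'
#' Defaults reproduce a *Ptelea*-like world: signal V_A = 64.2 Hz^2
#' (h^2 = 0.5, CV_A = 2.37 at a 338 Hz mean), preference V_A = 80.8 Hz^2
#' (h^2 = 0.20, CV_A = 2.66), and a weak negative family-level correlation
#' of -0.14.
#'
#' @param G 2x2 symmetric positive semidefinite between-family covariance
#'   matrix (Hz^2), rows/cols = (signal, preference).
#' @param V_rep Length-2 replicate (rearing-plant) variance per trait (Hz^2).
#' @param V_within Length-2 within-family variance per trait (Hz^2).  For a
#'   coherent full-sib world `V_within[t] >= G[t,t]` (the within-family
#'   segregation variance equals half the additive variance).
#' @param response_scale Mean peak response level (duet counts) of females.
#' @param responsiveness_sd Per-female multiplicative spread of the response
#'   level (standard deviation on the log scale).
#' @param width_mean,width_sd Mean and per-female spread of the preference
#'   width (Gaussian curve SD, Hz).
#' @param count_noise Overdispersion of response counts: negative binomial
#'   with `size = 1/count_noise`; `0` gives Poisson counts.
#' @param preference_offset Population-level offset (Hz) of the mean female
#'   peak preference from the species-mean signal frequency; nonzero values
#'   create population-level signal-preference mismatch.
#' @param signal_noise_sd Per-recorded-signal measurement noise SD (Hz) for
#'   male signals.
#' @param signals_per_male Number of recorded signals averaged per male.
#'
#' @return An object of class `genetic_architecture`.
#' @export
#' @examples
#' arch <- genetic_architecture()
#' family_correlation(arch)
genetic_architecture <- function(G = matrix(c(32.1, -5.04, -5.04, 40.4), 2, 2),
                                 V_rep = c(signal = 10, preference = 10),
                                 V_within = c(signal = 86.2, preference = 353.7),
                                 response_scale = 8,
                                 responsiveness_sd = 0.3,
                                 width_mean = 18,
                                 width_sd = 4,
                                 count_noise = 0.05,
                                 preference_offset = 0,
                                 signal_noise_sd = 3,
                                 signals_per_male = 3L) {
  G <- as.matrix(G)
  if (!all(dim(G) == c(2L, 2L)) || max(abs(G - t(G))) > 1e-8) {
    stop("`G` must be a symmetric 2x2 matrix")
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("`G` must be positive semidefinite")
  }
  V_rep <- rep_len(as.numeric(V_rep), 2L)
  V_within <- rep_len(as.numeric(V_within), 2L)
  if (any(c(V_rep, V_within) < 0)) stop("variances must be >= 0")
  stopifnot(response_scale >= 0, responsiveness_sd >= 0, width_mean > 0,
            width_sd >= 0, count_noise >= 0, signal_noise_sd >= 0,
            signals_per_male >= 1)
  structure(
    list(G = G, V_rep = V_rep, V_within = V_within,
         response_scale = response_scale,
         responsiveness_sd = responsiveness_sd,
         width_mean = width_mean, width_sd = width_sd,
         count_noise = count_noise,
         preference_offset = preference_offset,
         signal_noise_sd = signal_noise_sd,
         signals_per_male = as.integer(signals_per_male)),
    class = "genetic_architecture"
  )
}

#' Family-level (genetic) correlation implied by an architecture
#'
#' @param arch A [genetic_architecture()] object.
#' @return `G[1,2]/sqrt(G[1,1]*G[2,2])`, or `NA` when either diagonal is 0.
#' @export
family_correlation <- function(arch) {
  stopifnot(inherits(arch, "genetic_architecture"))
  G <- arch$G
  if (G[1, 1] <= 0 || G[2, 2] <= 0) return(NA_real_)
  G[1, 2] / sqrt(G[1, 1] * G[2, 2])
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("Genetic architecture (traits: signal, preference)\n")
  cat("  between-family covariance G:\n")
  print(round(x$G, 3))
  cat("  implied V_A (2*diag(G)):", paste(round(2 * diag(x$G), 2), collapse = ", "), "\n")
  cat("  family-level correlation:", round(family_correlation(x), 3), "\n")
  cat("  V_rep:", paste(round(x$V_rep, 2), collapse = ", "),
      " V_within:", paste(round(x$V_within, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Study design for a full-sib split-family experiment
#'
#' @param n_families Number of full-sib families.
#' @param replicates_per_sex Rearing-plant replicates per sex per family
#'   (the experiments modelled here used 2).
#' @param females_per_replicate,males_per_replicate Individuals per
#'   replicate cell.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_families = 25L, replicates_per_sex = 2L,
                         females_per_replicate = 5L,
                         males_per_replicate = 7L) {
  counts <- c(n_families, replicates_per_sex, females_per_replicate,
              males_per_replicate)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be integers >= 1")
  }
  structure(
    list(n_families = as.integer(n_families),
         replicates_per_sex = as.integer(replicates_per_sex),
         females_per_replicate = as.integer(females_per_replicate),
         males_per_replicate = as.integer(males_per_replicate)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Full-sib split-family design:", x$n_families, "families,",
      x$replicates_per_sex, "replicates/sex,",
      x$females_per_replicate, "females and",
      x$males_per_replicate, "males per replicate\n")
  invisible(x)
}
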