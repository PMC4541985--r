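# Bayesian animal model over the full-sib pseudo-pedigree: each family's
# offspring are coded as the progeny of one invented, unrelated sire-dam
# pair, so full-sib structure (A = 0.5 between sibs, 0 between families)
# enters the model.  Because the design is full-sib, the "additive"
# component mixes additive and nonadditive variance; it is a family-genetic
# component and is labelled V_A by convention.

#' Build the full-sib pseudo-pedigree
#'
#' Adds one founder sire and one founder dam per family (unknown parents,
#' unrelated across families) and links every individual to its family's
#' founder pair.
#'
#' @param individuals Individuals table with `id` and `family` columns.
#' @return Data frame of class `pedigree` with columns `id`, `sire`, `dam`
#'   (`NA` for founders), founders first.
#' @export
#' @examples
#' ind <- simulate_families(study_design(n_families = 2), seed = 1)
#' ped <- build_pseudo_pedigree(ind)
#' nrow(ped) == nrow(ind) + 4
build_pseudo_pedigree <- function(individuals) {
  stopifnot(all(c("id", "family") %in% names(individuals)))
  fams <- unique(individuals$family)
  founders <- data.frame(
    id = c(paste0(fams, "_sire"), paste0(fams, "_dam")),
    sire = NA_character_, dam = NA_character_,
    stringsAsFactors = FALSE
  )
  offspring <- data.frame(
    id = individuals$id,
    sire = paste0(individuals$family, "_sire"),
    dam = paste0(individuals$family, "_dam"),
    stringsAsFactors = FALSE
  )
  ped <- rbind(founders, offspring)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Additive relationship matrix from a pedigree
#'
#' Recursive tabular method: parents are processed before offspring,
#' `A[i,i] = 1 + 0.5 A[sire, dam]` and `A[i,j] = 0.5 (A[j, sire] +
#' A[j, dam])`.  Unknown parents contribute 0.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`.
#' @return Symmetric additive relationship matrix with ids as dimnames.
#' @export
additive_relationship <- function(pedigree) {
  ids <- pedigree$id
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  n <- length(ids)
  sire <- match(pedigree$sire, ids)
  dam <- match(pedigree$dam, ids)
  if (any(!is.na(pedigree$sire) & is.na(sire)) ||
      any(!is.na(pedigree$dam) & is.na(dam))) {
    stop("pedigree refers to parents that are not listed as individuals")
  }
  # topological order: repeatedly admit individuals whose parents are done
  done <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !done &
      vapply(seq_len(n), function(i) {
        (is.na(sire[i]) || done[sire[i]]) && (is.na(dam[i]) || done[dam[i]])
      }, logical(1))
    if (!any(ready)) {
      if (all(done)) break
      stop("pedigree contains a cycle")
    }
    ord <- c(ord, which(ready))
    done[ready] <- TRUE
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    s <- sire[i]; d <- dam[i]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * a_sd
    prev <- ord[seq_len(match(i, ord) - 1L)]
    if (length(prev)) {
      val <- 0.5 * ((if (!is.na(s)) A[prev, s] else 0) +
                      (if (!is.na(d)) A[prev, d] else 0))
      A[i, prev] <- val
      A[prev, i] <- val
    }
  }
  A
}

#' MCMC settings for the animal model
#'
#' The `"full"` preset uses chains of 1,000,000 iterations with a burn-in
#' of 500,000 and sampling every 500; the `"desk"` preset (default) is a
#' 20x shorter chain with the same retained-sample count scale, suitable
#' for simulation studies.
#'
#' @param iterations,burn_in,thin Chain settings; `(iterations - burn_in) /
#'   thin` must be at least 100.
#' @param prior_nu Degree-of-belief parameter of the variance priors (just
#'   above the minimum proper value; low belief).
#' @param prior_split Fractions of the phenotypic variance assigned to the
#'   additive, replicate and residual components in the prior scale
#'   (default: divided equally).
#' @param preset `"desk"` or `"full"`; explicitly supplied `iterations`,
#'   `burn_in`, `thin` override the preset.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = NULL, burn_in = NULL, thin = NULL,
                        prior_nu = 1.002, prior_split = c(1, 1, 1) / 3,
                        preset = c("desk", "full")) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(iterations = 1000000L, burn_in = 500000L, thin = 500L)
  } else {
    list(iterations = 50000L, burn_in = 25000L, thin = 25L)
  }
  iterations <- as.integer(iterations %||% def$iterations)
  burn_in <- as.integer(burn_in %||% def$burn_in)
  thin <- as.integer(thin %||% def$thin)
  if (burn_in >= iterations) stop("`burn_in` must be smaller than `iterations`")
  if ((iterations - burn_in) / thin < 100) {
    stop("chain must retain at least 100 samples: (iterations - burn_in)/thin >= 100")
  }
  prior_split <- prior_split / sum(prior_split)
  if (length(prior_split) != 3L || any(prior_split <= 0)) {
    stop("`prior_split` must be 3 positive fractions")
  }
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 prior_nu = prior_nu, prior_split = prior_split,
                 preset = preset),
            class = "mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of additive variance
#'
#' `CV_A = 100 * sqrt(V_A) / mean`, a mean-standardized measure of
#' evolvability.
#'
#' @param V_A Additive genetic variance (same squared units as the trait).
#' @param trait_mean Trait mean; must be positive.
#' @return The coefficient (in percent of the mean).
#' @export
#' @examples
#' cva(100, 100)  # 10
cva <- function(V_A, trait_mean) {
  if (any(trait_mean <= 0)) stop("`trait_mean` must be positive")
  if (any(V_A < 0)) stop("`V_A` must be >= 0")
  100 * sqrt(V_A) / trait_mean
}

#' Summarize a posterior sample
#'
#' Point estimate = mode of a kernel density whose bandwidth is
#' `bandwidth_factor` times the display bandwidth (the convention of the
#' animal-model software family this package follows); interval = highest
#' posterior density (shortest) interval of the stated mass, leftmost on
#' ties; the lag-1 autocorrelation of the retained samples is reported and
#' flagged when above 0.1.
#'
#' @param samples Numeric vector of at least 100 retained samples.
#' @param mass Interval mass (default 0.95).
#' @param bandwidth_factor Bandwidth shrinkage for the point-estimate
#'   density (default 0.1).
#' @return Object of class `posterior_summary`: `point`, `lower`, `upper`,
#'   `mass`, `lag1_autocorrelation`, `flagged`, `n`.
#' @export
summarize_posterior <- function(samples, mass = 0.95, bandwidth_factor = 0.1) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 100L) stop("need at least 100 posterior samples")
  xs <- sort(samples)
  m <- ceiling(mass * n)
  widths <- xs[m:n] - xs[1:(n - m + 1L)]
  j <- which.min(widths)  # leftmost shortest window
  if (var(samples) == 0) {
    point <- samples[1]
  } else {
    d <- density(samples, adjust = bandwidth_factor)
    point <- d$x[which.max(d$y)]
  }
  lag1 <- if (var(samples) == 0) 0 else
    as.numeric(acf(samples, lag.max = 1L, plot = FALSE)$acf[2L])
  structure(list(point = point, lower = xs[j], upper = xs[j + m - 1L],
                 mass = mass, lag1_autocorrelation = lag1,
                 flagged = is.finite(lag1) && abs(lag1) > 0.1, n = n),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%.4g (%.0f%% HPD %.4g to %.4g; lag-1 ac %.3f%s)\n",
              x$point, 100 * x$mass, x$lower, x$upper,
              x$lag1_autocorrelation,
              if (x$flagged) ", FLAGGED" else ""))
  invisible(x)
}

prepare_trait <- function(df, what) {
  if (length(unique(df$family)) < 2L) {
    stop("animal model needs at least 2 families (", what, ")")
  }
  if (var(df$value) <= 0) stop("trait variance must be positive (", what, ")")
  df
}

#' Fit the animal model by Gibbs sampling
#'
#' Univariate (one trait) or bivariate (signal and preference) Gaussian
#' animal model over the full-sib pseudo-pedigree, with additive
#' (A-structured), replicate and residual components.  In the bivariate
#' model the genetic covariance is free while the residual covariance is
#' fixed at exactly zero, because any individual carries either a signal or
#' a preference value, never both; each replicate group likewise belongs to
#' one sex.  Priors split the observed phenotypic variance of each trait
#' equally among the additive, replicate and residual components, with a
#' low degree of belief.
#'
#' @param data Data frame with columns `id`, `family`, `replicate`,
#'   `value`, and (for the bivariate model) `trait` with values `"signal"`
#'   and `"preference"`.
#' @param config An [mcmc_config()].
#' @param seed Optional seed for the chain.
#' @return Object of class `animal_model` with elements `samples` (data
#'   frame of retained draws: per-trait `V_A`, `V_rep`, `V_res`, `h2`,
#'   `CV_A`, plus `r_G`/`cov_A` for the bivariate model), `estimates`
#'   (list of [summarize_posterior()] results), `traits`, `means`,
#'   `n_families`, `config`.
#' @export
fit_animal_model <- function(data, config = mcmc_config(), seed = NULL) {
  stopifnot(inherits(config, "mcmc_config"))
  if (!is.null(seed)) set.seed(seed)
  need <- c("id", "family", "replicate", "value")
  stopifnot(all(need %in% names(data)))
  bivariate <- "trait" %in% names(data) &&
    length(unique(data$trait)) == 2L

  if (!bivariate) {
    data <- prepare_trait(data, "univariate")
    fam <- factor(data$family)
    rep_f <- factor(data$replicate)
    Vp <- var(data$value)
    V0 <- Vp * config$prior_split
    res <- .gibbs_univariate(
      data$value - mean(data$value),
      as.integer(fam) - 1L, as.integer(rep_f) - 1L,
      nlevels(fam), nlevels(rep_f),
      V0[1], V0[2], V0[3], config$prior_nu,
      config$iterations, config$burn_in, config$thin
    )
    samples <- data.frame(V_A = res$V_A, V_rep = res$V_rep,
                          V_res = res$V_res, h2 = res$h2)
    samples$CV_A <- cva(samples$V_A, mean(data$value))
    traits <- "trait"
    means <- c(trait = mean(data$value))
    n_fam <- nlevels(fam)
  } else {
    data$trait <- as.character(data$trait)
    lev <- c("signal", "preference")
    if (!all(data$trait %in% lev)) {
      stop("`trait` must be 'signal' or 'preference'")
    }
    for (t in lev) prepare_trait(data[data$trait == t, ], t)
    one_sex <- names(which(table(unique(data[c("family", "trait")])$family) < 2L))
    if (length(one_sex)) {
      message("fit_animal_model: ", length(one_sex), " family(ies) carry ",
              "only one trait and inform variances but not the genetic ",
              "covariance: ", paste(one_sex, collapse = ", "))
    }
    fam <- factor(data$family)
    rep_f <- factor(paste(data$trait, data$replicate, sep = "|"))
    tr <- as.integer(factor(data$trait, levels = lev)) - 1L
    rep_trait <- tapply(tr, rep_f, `[`, 1L)[levels(rep_f)]
    Vp <- tapply(data$value, data$trait, var)[lev]
    mns <- tapply(data$value, data$trait, mean)[lev]
    yc <- data$value - mns[data$trait]
    split <- config$prior_split
    res <- .gibbs_bivariate(
      as.numeric(yc), tr, as.integer(fam) - 1L, as.integer(rep_f) - 1L,
      as.integer(rep_trait), nlevels(fam), nlevels(rep_f),
      as.numeric(Vp * split[1]), as.numeric(Vp * split[2]),
      as.numeric(Vp * split[3]),
      config$prior_nu + 1, config$prior_nu,
      config$iterations, config$burn_in, config$thin
    )
    s <- as.data.frame(res$samples)
    samples <- data.frame(
      V_A_signal = s$V_A_1, V_A_preference = s$V_A_2,
      cov_A = s$cov_A, r_G = s$r_G,
      V_rep_signal = s$V_rep_1, V_rep_preference = s$V_rep_2,
      V_res_signal = s$V_res_1, V_res_preference = s$V_res_2,
      h2_signal = s$h2_1, h2_preference = s$h2_2
    )
    samples$CV_A_signal <- cva(samples$V_A_signal, mns["signal"])
    samples$CV_A_preference <- cva(samples$V_A_preference, mns["preference"])
    traits <- lev
    means <- setNames(as.numeric(mns), lev)
    n_fam <- nlevels(fam)
  }

  estimates <- lapply(samples, summarize_posterior)
  flagged <- vapply(estimates, `[[`, logical(1), "flagged")
  if (any(flagged)) {
    warning("high lag-1 autocorrelation (> 0.1) in: ",
            paste(names(estimates)[flagged], collapse = ", "),
            "; consider a longer chain")
  }
  structure(
    list(samples = samples, estimates = estimates, traits = traits,
         means = means, n_families = n_fam, config = config,
         bivariate = bivariate),
    class = "animal_model"
  )
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Animal model (full-sib pseudo-pedigree), ", x$n_families,
      " families, ", nrow(x$samples), " retained samples\n", sep = "")
  keys <- if (x$bivariate) {
    c("h2_signal", "CV_A_signal", "h2_preference", "CV_A_preference", "r_G")
  } else {
    c("V_A", "h2", "CV_A")
  }
  for (k in keys) {
    cat(sprintf("  %-16s ", k))
    print(x$estimates[[k]])
  }
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$estimates), function(k) {
    e <- object$estimates[[k]]
    data.frame(quantity = k, point = e$point, lower = e$lower,
               upper = e$upper, lag1 = e$lag1_autocorrelation,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' @export
coef.animal_model <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "point")
}

#' @export
plot.animal_model <- function(x, which = if (x$bivariate) "r_G" else "h2", ...) {
  s <- x$samples[[which]]
  plot(density(s), main = paste("Posterior of", which), xlab = which, ...)
  e <- x$estimates[[which]]
  abline(v = c(e$lower, e$point, e$upper), lty = c(3, 1, 3))
  invisible(x)
}
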