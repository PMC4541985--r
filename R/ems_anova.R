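# Mixed-model ANOVA machinery: containment-aware partial (Type-III style)
# mean squares via orthogonal projections, expected-mean-square (EMS)
# coefficients computed by synthesis on the realized (possibly unbalanced)
# design, synthesized denominators with Satterthwaite fractional degrees of
# freedom, and F tests.
#
# Terms are strings naming columns of the data, joined by ":".  Character /
# factor columns enter as factors (interactions collapse to a single
# factor); numeric columns enter multiplicatively as covariates.  Each term
# T gets an *effect space* V_T: the column space of its indicator matrix
# Z_T swept of the intercept and of the effect spaces of every term it
# contains (containment detected numerically: S is contained in T when
# col(Z_S) is a subspace of col(Z_T), which covers nesting coded through
# unique labels).  The partial SS of T is y'(P_full - P_{-T})y, the
# increment of V_T after all other effect spaces; on balanced designs this
# reproduces the classical (Type III) ANOVA exactly.  For a random term U,
# the EMS coefficient of sigma^2_U in MS_T is tr(Q_T Z_U Z_U') / df_T
# (Hartley's method of synthesis), which reduces to the textbook
# coefficients on balanced designs.

orth_basis <- function(M, tol = 1e-9) {
  if (is.null(M) || ncol(M) == 0L) {
    return(matrix(numeric(0), nrow = if (is.null(M)) 0L else nrow(M), ncol = 0L))
  }
  s <- svd(M, nv = 0)
  r <- sum(s$d > tol * max(s$d[1], 1))
  s$u[, seq_len(r), drop = FALSE]
}

# indicator (design) matrix of a term: cell indicators times the covariate
# product; a pure-covariate term is the covariate column itself
build_term_Z <- function(data, term) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("term '", term, "': column(s) not in data: ",
         paste(missing, collapse = ", "))
  }
  is_fac <- vapply(vars, function(v) !is.numeric(data[[v]]), logical(1))
  cov <- rep(1, nrow(data))
  for (v in vars[!is_fac]) cov <- cov * data[[v]]
  if (any(is_fac)) {
    f <- droplevels(interaction(data[vars[is_fac]], drop = TRUE, sep = ":"))
    Z <- matrix(0, nrow(data), nlevels(f))
    Z[cbind(seq_len(nrow(data)), as.integer(f))] <- cov
    Z
  } else {
    matrix(cov, ncol = 1L)
  }
}

#' Precompute the projection structure of a mixed-model ANOVA
#'
#' Builds, for a fixed design, everything that does not depend on the
#' response: each term's effect-space basis and quadratic form, degrees of
#' freedom, and the EMS coefficient matrix.  Reuse the engine with
#' [ems_mean_squares()] to analyse many simulated responses on the same
#' design cheaply.
#'
#' @param data Data frame holding the design columns.
#' @param terms Character vector of model terms (column names joined by
#'   `":"`), e.g. `c("family", "replicate", "sex", "family:sex")`.
#' @param random Character vector naming which of `terms` are random.
#' @return An object of class `ems_engine`.
#' @export
ems_engine <- function(data, terms, random) {
  stopifnot(all(random %in% terms))
  n <- nrow(data)
  Z_list <- lapply(terms, build_term_Z, data = data)
  names(Z_list) <- terms
  O_list <- lapply(Z_list, orth_basis)

  # containment: s contained in t  <=>  col(Z_s) subset of col(Z_t)
  k <- length(terms)
  contains <- matrix(FALSE, k, k, dimnames = list(terms, terms))
  for (t in seq_len(k)) {
    for (s in seq_len(k)) {
      if (s == t || ncol(Z_list[[s]]) > ncol(Z_list[[t]])) next
      R <- Z_list[[s]] - O_list[[t]] %*% crossprod(O_list[[t]], Z_list[[s]])
      contains[t, s] <- max(abs(R)) < 1e-8 * max(1, max(abs(Z_list[[s]])))
    }
  }

  # effect spaces, built in containment order
  ord <- order(rowSums(contains))
  V_list <- vector("list", k)
  names(V_list) <- terms
  ones <- matrix(1 / sqrt(n), n, 1L)
  for (t in ord) {
    sweep_basis <- cbind(ones, do.call(cbind, c(
      list(matrix(numeric(0), n, 0L)),
      V_list[terms[contains[t, ]]]
    )))
    Q1 <- orth_basis(sweep_basis)
    Zp <- Z_list[[t]] - Q1 %*% crossprod(Q1, Z_list[[t]])
    V_list[[t]] <- orth_basis(Zp)
    if (ncol(V_list[[t]]) == 0L) {
      stop("term '", terms[t], "' is confounded with the terms it contains ",
           "(zero degrees of freedom)")
    }
  }

  X_full <- cbind(ones, do.call(cbind, V_list))
  Q_full <- orth_basis(X_full)
  df_res <- n - ncol(Q_full)
  if (df_res <= 0) stop("no residual degrees of freedom")

  bases <- vector("list", k)
  df <- numeric(k)
  for (i in seq_len(k)) {
    X_minus <- cbind(ones, do.call(cbind, V_list[-i]))
    Q1 <- orth_basis(X_minus)
    Xp <- V_list[[i]] - Q1 %*% crossprod(Q1, V_list[[i]])
    B <- orth_basis(Xp)
    if (ncol(B) == 0L) {
      stop("term '", terms[i], "' is confounded with the other model terms ",
           "(zero partial degrees of freedom)")
    }
    bases[[i]] <- B
    df[i] <- ncol(B)
  }
  names(bases) <- names(df) <- terms
  mats <- lapply(Z_list, function(Z) list(Z = Z))

  comp <- c(random, "residual")
  C <- matrix(0, length(terms) + 1L, length(comp),
              dimnames = list(c(terms, "residual"), comp))
  for (u in random) {
    Z <- mats[[u]]$Z
    for (t in terms) {
      C[t, u] <- sum(crossprod(bases[[t]], Z)^2) / df[t]
    }
    C["residual", u] <- (sum(Z^2) - sum(crossprod(Q_full, Z)^2)) / df_res
  }
  C[, "residual"] <- 1
  C[abs(C) < 1e-9] <- 0

  structure(
    list(terms = terms, random = random, bases = bases, Q_full = Q_full,
         df = c(df, residual = df_res), ems = C, n = n),
    class = "ems_engine"
  )
}

#' Mean squares for one or many responses on a precomputed design
#'
#' @param engine An [ems_engine()].
#' @param y Numeric response vector, or a matrix with one column per
#'   simulated response.
#' @return A matrix of mean squares (rows = terms plus `"residual"`,
#'   columns = responses).
#' @export
ems_mean_squares <- function(engine, y) {
  Y <- as.matrix(y)
  stopifnot(nrow(Y) == engine$n)
  ss <- vapply(engine$terms, function(t) {
    colSums(crossprod(engine$bases[[t]], Y)^2)
  }, numeric(ncol(Y)))
  ss <- matrix(ss, ncol(Y), length(engine$terms),
               dimnames = list(NULL, engine$terms))
  ss_res <- colSums(Y^2) - colSums(crossprod(engine$Q_full, Y)^2)
  ms <- t(cbind(ss, residual = ss_res)) / engine$df
  ms
}

#' Type-III mixed-model ANOVA with EMS coefficients
#'
#' Fits the ANOVA decomposition for `response` on the given terms and
#' returns mean squares, degrees of freedom and the EMS coefficient matrix.
#' Use [synthesize_denominator()] / [f_test()] on the result.
#'
#' @inheritParams ems_engine
#' @param response Name of the numeric response column.
#' @return An object of class `ems_anova`: list with `table` (term, df, SS,
#'   MS), `ems` (coefficient matrix), and the `engine`.
#' @export
#' @examples
#' d <- expand.grid(g = factor(1:6), i = 1:4)
#' d$y <- rnorm(nrow(d)) + rnorm(6)[d$g]
#' a <- mixed_anova(d, "y", terms = "g", random = "g")
#' a$table
mixed_anova <- function(data, response, terms, random) {
  stopifnot(response %in% names(data), is.numeric(data[[response]]))
  engine <- ems_engine(data, terms, random)
  ms <- ems_mean_squares(engine, data[[response]])[, 1]
  tab <- data.frame(term = names(engine$df),
                    df = as.numeric(engine$df),
                    MS = as.numeric(ms),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, ems = engine$ems, engine = engine,
                 response = response),
            class = "ems_anova")
}

#' @export
print.ems_anova <- function(x, ...) {
  cat("Mixed-model ANOVA (Type III mean squares)\n")
  tab <- x$table
  tab$MS <- signif(tab$MS, 5)
  tab$df <- round(tab$df, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Weights w over candidate rows such that sum_i w_i EMS_i equals the target
# EMS vector.  Independent of the observed mean squares.  Candidates are
# random-term and residual mean squares only: a fixed term's MS carries a
# noncentrality and cannot appear in a denominator.
synth_weights <- function(ems, term, random, from = NULL) {
  target <- ems[term, ]
  if (term %in% colnames(ems)) target[term] <- 0  # drop own component
  cand <- setdiff(intersect(rownames(ems), c(random, "residual")), term)
  if (!is.null(from)) cand <- intersect(cand, from)
  E <- ems[cand, , drop = FALSE]
  if (is.null(from)) {
    # drop candidates containing components absent from the target
    usable <- apply(E, 1L, function(r) all(r[target == 0] == 0))
    cand <- cand[usable]
  }
  E <- ems[cand, , drop = FALSE]
  w <- tryCatch(qr.solve(t(E), target, tol = 1e-10), error = function(e) NULL)
  if (is.null(w) || max(abs(drop(t(E) %*% w) - target)) > 1e-6 * max(1, abs(target))) {
    stop("no linear combination of mean squares matches the expected ",
         "denominator for term '", term, "'; EMS table:\n",
         paste(utils::capture.output(print(round(ems, 4))), collapse = "\n"))
  }
  w <- setNames(as.numeric(w), cand)
  w[abs(w) < 1e-10] <- 0
  w[w != 0]
}

#' Synthesized-denominator weights for a precomputed design
#'
#' Returns the (response-independent) weights of the mean-square
#' combination whose expectation matches `term`'s EMS minus its own
#' component, for reuse across many simulated responses on the same
#' [ems_engine()].
#'
#' @param engine An [ems_engine()].
#' @param term Numerator term.
#' @param from Optional restriction of the candidate mean squares.
#' @return Named numeric weights over mean squares.
#' @export
ems_synth_weights <- function(engine, term, from = NULL) {
  stopifnot(inherits(engine, "ems_engine"))
  synth_weights(engine$ems, term, engine$random, from = from)
}

#' Satterthwaite degrees of freedom of a mean-square combination
#'
#' `df = (sum_i c_i MS_i)^2 / sum_i (c_i MS_i)^2 / df_i`.
#'
#' @param w Named weights over mean squares.
#' @param ms Mean squares (same names).
#' @param df Degrees of freedom (same names).
#' @return Fractional degrees of freedom.
#' @export
satterthwaite_df <- function(w, ms, df) {
  cm <- w * ms[names(w)]
  sum(cm)^2 / sum(cm^2 / df[names(w)])
}

#' Synthesize the error term for an F test
#'
#' Finds the linear combination of observed mean squares whose expectation
#' equals the expected mean square of `term` minus the contribution of the
#' term's own variance component, and computes its Satterthwaite
#' (fractional) degrees of freedom.  On balanced designs where a single
#' mean square already has the required expectation, the combination
#' reduces to that mean square exactly.
#'
#' @param anova An [mixed_anova()] result.
#' @param term Numerator term.
#' @param from Optional restriction of the candidate mean squares.
#' @return List with `term`, `MS`, `df`, and the `coefficients` of the
#'   combination.  A non-positive synthesized MS is floored at a small
#'   positive value with a warning.
#' @export
synthesize_denominator <- function(anova, term, from = NULL) {
  stopifnot(inherits(anova, "ems_anova"), term %in% anova$table$term)
  w <- synth_weights(anova$ems, term, anova$engine$random, from = from)
  ms <- setNames(anova$table$MS, anova$table$term)
  df <- setNames(anova$table$df, anova$table$term)
  ms_syn <- sum(w * ms[names(w)])
  if (ms_syn <= 0) {
    warning("synthesized denominator for '", term,
            "' is non-positive; floored")
    ms_syn <- 1e-12
  }
  list(term = paste0("synthetic(", paste(names(w)[w != 0], collapse = " + "), ")"),
       MS = ms_syn, df = satterthwaite_df(w, ms, df), coefficients = w)
}

#' F test of a model term
#'
#' `F = MS_num / MS_den`, with the p-value from the upper tail of the F
#' distribution at (possibly fractional) degrees of freedom.
#'
#' @param anova An [mixed_anova()] result.
#' @param term Numerator term.
#' @param denominator `"synthetic"` (EMS-matched combination, the default),
#'   `"residual"`, the name of another term, or a list with `MS` and `df`.
#' @param from Passed to [synthesize_denominator()] when synthesizing.
#' @return An object of class `f_test_result`: `term`, `F`, `df_num`,
#'   `df_den`, `p`, `MS_num`, `MS_den`, `denominator`.
#' @export
f_test <- function(anova, term, denominator = "synthetic", from = NULL) {
  stopifnot(inherits(anova, "ems_anova"), term %in% anova$table$term)
  row <- anova$table[anova$table$term == term, ]
  den <- if (is.list(denominator)) {
    denominator
  } else if (identical(denominator, "synthetic")) {
    synthesize_denominator(anova, term, from = from)
  } else {
    dr <- anova$table[anova$table$term == denominator, ]
    if (nrow(dr) == 0L) stop("unknown denominator term '", denominator, "'")
    list(term = denominator, MS = dr$MS, df = dr$df)
  }
  if (!is.finite(den$MS) || den$MS <= 0) {
    res <- list(term = term, F = NA_real_, df_num = row$df, df_den = den$df,
                p = NA_real_, MS_num = row$MS, MS_den = den$MS,
                denominator = den$term, flag = "zero-denominator")
    class(res) <- "f_test_result"
    return(res)
  }
  Fval <- row$MS / den$MS
  res <- list(term = term, F = Fval, df_num = row$df, df_den = den$df,
              p = pf(Fval, row$df, den$df, lower.tail = FALSE),
              MS_num = row$MS, MS_den = den$MS, denominator = den$term,
              flag = "ok")
  class(res) <- "f_test_result"
  res
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("F test of '%s': F = %.3f (df %s, %s), p = %.4g  [den: %s]\n",
              x$term, x$F, format(round(x$df_num, 2)),
              format(round(x$df_den, 2)), x$p, x$denominator))
  invisible(x)
}

#' Variance components by REML and by method of moments
#'
#' REML estimates (via `lme4`, bounded at zero) for each random term's
#' variance component, together with the Type-III ANOVA table, EMS
#' coefficients, and method-of-moments component estimates obtained by
#' solving the EMS equations for the observed mean squares (negative
#' solutions floored at zero).
#'
#' @inheritParams mixed_anova
#' @return List with `reml` (named variance components, including
#'   `residual`), `mom` (method-of-moments components), and `anova` (the
#'   [mixed_anova()] object).
#' @export
fit_variance_components <- function(data, response, terms, random) {
  anova <- mixed_anova(data, response, terms, random)

  # method of moments: solve EMS system on random + residual rows
  rows <- c(random, "residual")
  E <- anova$ems[rows, , drop = FALSE]
  ms <- setNames(anova$table$MS, anova$table$term)[rows]
  mom <- pmax(qr.solve(E, ms, tol = 1e-10), 0)
  names(mom) <- colnames(E)

  reml <- rep(0, length(random) + 1L)
  names(reml) <- c(random, "residual")
  if (var(data[[response]]) == 0) {
    return(list(reml = reml, mom = mom * 0, anova = anova))
  }

  ranef_part <- vapply(random, function(term) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    is_fac <- vapply(vars, function(v) !is.numeric(data[[v]]), logical(1))
    fac <- paste(vars[is_fac], collapse = ":")
    covs <- vars[!is_fac]
    if (!any(is_fac)) stop("random term '", term, "' has no factor")
    if (length(covs)) {
      sprintf("(0 + %s | %s)", paste(covs, collapse = ":"), fac)
    } else {
      sprintf("(1 | %s)", fac)
    }
  }, character(1))
  fixed <- setdiff(terms, random)
  rhs <- paste(c(if (length(fixed)) fixed else "1", ranef_part),
               collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  for (i in seq_along(random)) {
    vars <- strsplit(random[i], ":", fixed = TRUE)[[1]]
    is_fac <- vapply(vars, function(v) !is.numeric(data[[v]]), logical(1))
    grp <- paste(vars[is_fac], collapse = ":")
    hit <- which(vc$grp %in% c(grp, make.names(grp)) |
                   gsub("\\.\\d+$", "", vc$grp) == grp)
    if (length(hit)) reml[random[i]] <- sum(vc$vcov[hit])
  }
  reml["residual"] <- vc$vcov[vc$grp == "Residual"]
  list(reml = reml, mom = mom, anova = anova)
}
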