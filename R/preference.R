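# Individual mate-preference functions: cubic smoothing-spline fits of
# response counts on stimulus frequency, with the peak preference extracted
# from a dense evaluation grid.

default_lambda_grid <- function() 10^seq(-8, 2, length.out = 41)

#' Optimize the spline smoothing parameter by GCV
#'
#' Evaluates the generalized cross-validation score of a cubic smoothing
#' spline at each value of a log-spaced grid of smoothing parameters and
#' returns the minimizer.  Ties (within 1e-10 relative) are broken toward
#' the heaviest smoothing, so degenerate data yield the maximal smoothing of
#' the search grid.
#'
#' @param trials Data frame with columns `stimulus_hz` and `response_count`
#'   for a single female.
#' @param lambda_grid Search grid of smoothing parameters (lambda on the
#'   internal unit-interval scale of [stats::smooth.spline()]).
#' @return The selected smoothing parameter (a single lambda value).
#' @export
optimize_smoothing <- function(trials, lambda_grid = default_lambda_grid()) {
  x <- trials$stimulus_hz
  y <- trials$response_count
  if (length(unique(x)) < 5L) {
    stop("need at least 5 distinct stimulus frequencies")
  }
  if (var(y) == 0) return(max(lambda_grid))
  crit <- vapply(lambda_grid, function(l) {
    fit <- try(smooth.spline(x, y, lambda = l, cv = FALSE,
                             keep.data = FALSE), silent = TRUE)
    if (inherits(fit, "try-error")) Inf else fit$cv.crit
  }, numeric(1))
  best <- min(crit)
  # heaviest smoothing among (near-)ties
  max(lambda_grid[crit <= best * (1 + 1e-10)])
}

#' Fit a female's mate-preference function
#'
#' Fits a natural cubic smoothing spline of response count on stimulus
#' frequency (knots at the distinct stimulus values) and extracts the peak
#' preference: the stimulus frequency, within the tested range, at which the
#' fitted curve is maximal (see [extract_peak()]).
#'
#' @param trials Data frame with columns `stimulus_hz` and `response_count`
#'   (one female; columns `female_id`, `family`, `replicate` are carried
#'   through when present).
#' @param smoothing `"auto"` (GCV via [optimize_smoothing()]) or a numeric
#'   smoothing parameter.
#' @param resolution Dense evaluation grid step (Hz) for peak extraction.
#' @return An object of class `preference_function` with elements `x`, `y`,
#'   `spline`, `smoothing`, `grid`, `fitted`, `peak_preference`,
#'   `peak_response`, and `flag` (`"ok"`, `"flat"`, or `"boundary"`).
#' @export
#' @examples
#' grid <- make_stimulus_grid(ptelea_params())
#' y <- round(8 * exp(-(grid - 330)^2 / (2 * 25^2)))
#' pf <- fit_preference_function(data.frame(stimulus_hz = grid,
#'                                          response_count = y))
#' pf$peak_preference
fit_preference_function <- function(trials, smoothing = "auto",
                                    resolution = 0.1) {
  x <- trials$stimulus_hz
  y <- trials$response_count
  if (length(unique(x)) < 5L) {
    stop("need at least 5 distinct stimulus frequencies")
  }
  id <- if ("female_id" %in% names(trials)) trials$female_id[1] else NA_character_

  if (var(y) == 0) {
    # constant responses: the spline is the constant itself for any
    # smoothing; the peak is undefined
    grid <- seq(min(x), max(x), by = resolution)
    obj <- list(female_id = id, x = x, y = y, spline = NULL,
                smoothing = max(default_lambda_grid()),
                grid = grid, fitted = rep(y[1], length(grid)),
                peak_preference = NA_real_, peak_response = y[1],
                flag = "flat")
    class(obj) <- "preference_function"
    return(obj)
  }

  lambda <- if (identical(smoothing, "auto")) {
    optimize_smoothing(trials)
  } else {
    as.numeric(smoothing)
  }
  fit <- smooth.spline(x, y, lambda = lambda, cv = FALSE)
  obj <- list(female_id = id, x = x, y = y, spline = fit,
              smoothing = lambda, grid = NULL, fitted = NULL,
              peak_preference = NA_real_, peak_response = NA_real_,
              flag = "ok")
  class(obj) <- "preference_function"
  pk <- extract_peak(obj, resolution = resolution)
  obj$grid <- pk$grid
  obj$fitted <- pk$fitted
  obj$peak_preference <- pk$peak_preference
  obj$peak_response <- pk$peak_response
  obj$flag <- pk$flag
  obj
}

#' Extract the peak preference from a fitted preference function
#'
#' Evaluates the fitted curve on a dense grid of the stated resolution
#' spanning the tested stimulus range and returns its argmax.  Exact ties
#' are broken toward the lowest frequency.  A curve whose range of fitted
#' values is below `flat_tol` is flagged `"flat"` with an undefined peak;
#' a peak at either end of the range is flagged `"boundary"` (kept, not
#' dropped).
#'
#' @param pf A `preference_function` object.
#' @param resolution Grid step in Hz (default 0.1).
#' @param flat_tol Flatness tolerance in response units.
#' @return List with `peak_preference`, `peak_response`, `grid`, `fitted`,
#'   `flag`.
#' @export
extract_peak <- function(pf, resolution = 0.1, flat_tol = 1e-6) {
  stopifnot(inherits(pf, "preference_function"))
  lo <- min(pf$x); hi <- max(pf$x)
  grid <- seq(lo, hi, by = resolution)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  fitted <- if (is.null(pf$spline)) {
    rep(pf$y[1], length(grid))
  } else {
    predict(pf$spline, grid)$y
  }
  if (diff(range(fitted)) < flat_tol) {
    return(list(peak_preference = NA_real_,
                peak_response = max(fitted),
                grid = grid, fitted = fitted, flag = "flat"))
  }
  i <- which.max(fitted)  # first max = lowest frequency on ties
  flag <- if (i == 1L || i == length(grid)) "boundary" else "ok"
  list(peak_preference = grid[i], peak_response = fitted[i],
       grid = grid, fitted = fitted, flag = flag)
}

#' @export
print.preference_function <- function(x, ...) {
  cat("Preference function", if (!is.na(x$female_id)) paste0("(", x$female_id, ")"),
      "\n  smoothing:", signif(x$smoothing, 3),
      "\n  peak preference:", round(x$peak_preference, 2), "Hz",
      "(flag:", paste0(x$flag, ")"), "\n")
  invisible(x)
}

#' @export
predict.preference_function <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(object$spline)) return(rep(object$y[1], length(newdata)))
  predict(object$spline, as.numeric(newdata))$y
}

#' @export
plot.preference_function <- function(x, ...) {
  plot(x$x, x$y, xlab = "Stimulus frequency (Hz)",
       ylab = "Response count", pch = 16, ...)
  lines(x$grid, x$fitted, lwd = 2)
  if (!is.na(x$peak_preference)) {
    arrows(x$peak_preference, x$peak_response + 0.12 * diff(range(x$y, 0)),
           x$peak_preference, x$peak_response, length = 0.08)
  }
  invisible(x)
}

#' Estimate peak preferences for every female in a trials table
#'
#' Fits a preference function per female and collects the peaks; females
#' with flat (undefined-peak) functions are flagged so downstream stages can
#' exclude them.
#'
#' @param trials Trials table (`female_id`, `family`, `replicate`,
#'   `stimulus_hz`, `response_count`).
#' @inheritParams fit_preference_function
#' @return Data frame: `female_id`, `family`, `replicate`, `peak_hz`,
#'   `peak_response`, `smoothing`, `flag`.
#' @export
peak_preferences <- function(trials, smoothing = "auto", resolution = 0.1) {
  stopifnot(all(c("female_id", "stimulus_hz", "response_count") %in%
                  names(trials)))
  split_idx <- split(seq_len(nrow(trials)), trials$female_id)
  rows <- lapply(split_idx, function(ix) {
    tr <- trials[ix, , drop = FALSE]
    pf <- fit_preference_function(tr, smoothing = smoothing,
                                  resolution = resolution)
    data.frame(
      female_id = tr$female_id[1],
      family = if ("family" %in% names(tr)) tr$family[1] else NA_character_,
      replicate = if ("replicate" %in% names(tr)) tr$replicate[1] else NA_character_,
      peak_hz = pf$peak_preference,
      peak_response = pf$peak_response,
      smoothing = pf$smoothing,
      flag = pf$flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$female_id), , drop = FALSE]
}
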