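#' Calibration regression of observed on predicted outcome
#'
#' Simple least-squares regression of the observed outcome on a model's
#' predictions. Because R-squared is invariant to affine rescaling of the
#' explanatory variable, this puts predictors with different output scales
#' on one common footing; its residuals feed the residual-variance
#' comparison of [paired_bootstrap_f()].
#'
#' @param observed Numeric vector of true outcome values.
#' @param predicted Numeric vector of predictions, same length, `n >= 4`,
#'   non-constant.
#' @return An object of class `slim_calibration`: list with `slope`,
#'   `intercept`, `r2`, `adjusted_r2` (at k = 1), `residuals`, `n`.
#' @export
calibration_fit <- function(observed, predicted) {
  observed <- as.double(observed); predicted <- as.double(predicted)
  if (length(observed) != length(predicted)) stop("length mismatch")
  n <- length(observed)
  if (n < 4L) stop("need at least 4 paired values")
  if (var(predicted) == 0) {
    stop("predicted values are constant: calibration slope undefined")
  }
  fit <- fit_ols(matrix(predicted, ncol = 1L,
                        dimnames = list(NULL, "predicted")), observed)
  structure(list(slope = unname(fit$slopes[1L]),
                 intercept = fit$intercept,
                 r2 = fit$r2,
                 adjusted_r2 = fit$adjusted_r2,
                 residuals = fit$residuals,
                 n = n),
            class = "slim_calibration")
}

#' Central F-distribution band
#'
#' Lower and upper quantiles of the central F distribution,
#' `qf(alpha, dof1, dof2)` and `qf(1 - alpha, dof1, dof2)`, used to band
#' the bootstrap residual-variance ratios.
#'
#' @param alpha Lower tail probability in `(0, 0.5)`; default 0.05.
#' @param dof1,dof2 Positive integer degrees of freedom.
#' @return Named numeric vector `c(f_lower, f_upper)`.
#' @export
f_bounds <- function(alpha = 0.05, dof1, dof2) {
  if (!is.numeric(dof1) || !is.numeric(dof2) || dof1 < 1 || dof2 < 1) {
    stop("degrees of freedom must be >= 1")
  }
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  c(f_lower = qf(alpha, dof1, dof2), f_upper = qf(1 - alpha, dof1, dof2))
}

#' Paired bootstrap F-test of two predictors' residual variances
#'
#' Compares the predictive accuracy of two sets of predictions for the
#' same observed outcome. Plain F-tests on calibration residuals are
#' unreliable here because the two prediction vectors are typically
#' strongly correlated, so the two calibration regressions are
#' bootstrapped SIMULTANEOUSLY: each replicate draws one set of case
#' indices with replacement, applies it to both (observed, predicted)
#' pairs, refits both calibration regressions, and records the residual
#' variance ratio `F_b = var(resid_a) / var(resid_b)`. The p-value counts
#' how rarely `F_b` leaves the central-F band:
#' `p = 1 - (#(F < f_lower) + #(F > f_upper)) / B`, with both margins at
#' `n - 2` degrees of freedom (the calibration regressions have a single
#' explanatory variable). Small p means the two residual variances differ
#' beyond resampling noise.
#'
#' @param observed Observed outcome vector.
#' @param predicted_a,predicted_b Prediction vectors of the two models,
#'   same length as `observed`.
#' @param B Number of bootstrap replicates; default 1000.
#' @param alpha Tail probability for the F band; default 0.05.
#' @param seed Optional integer seed for the resampling.
#' @return An object of class `slim_comparison`: list with `f_stats`
#'   (length `B`), `mean_f`, `p_value`, `f_lower`, `f_upper`, `dof`
#'   (integer pair, both `n - 2`), `B`, `alpha`, `n`, `n_redrawn`.
#' @export
paired_bootstrap_f <- function(observed, predicted_a, predicted_b,
                               B = 1000L, alpha = 0.05, seed = NULL) {
  observed <- as.double(observed)
  predicted_a <- as.double(predicted_a)
  predicted_b <- as.double(predicted_b)
  n <- length(observed)
  if (length(predicted_a) != n || length(predicted_b) != n) {
    stop("all three vectors must have the same length")
  }
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dof <- n - 2L
  band <- f_bounds(alpha, dof, dof)

  f_stats <- numeric(B)
  redrawn <- 0L
  draws_cap <- 10L * B
  draws <- 0L
  b <- 1L
  while (b <= B) {
    if (draws >= draws_cap) {
      stop("exceeded ", draws_cap, " bootstrap draws while redrawing ",
           "degenerate replicates")
    }
    idx <- sample.int(n, n, replace = TRUE)
    draws <- draws + 1L
    if (var(predicted_a[idx]) == 0 || var(predicted_b[idx]) == 0) {
      redrawn <- redrawn + 1L
      next
    }
    ra <- calibration_fit(observed[idx], predicted_a[idx])$residuals
    rb <- calibration_fit(observed[idx], predicted_b[idx])$residuals
    f_stats[b] <- var(ra) / var(rb)
    b <- b + 1L
  }
  if (redrawn > 0L) {
    message(redrawn, " degenerate bootstrap replicate(s) redrawn")
  }
  outside <- sum(f_stats < band["f_lower"]) + sum(f_stats > band["f_upper"])
  structure(list(f_stats = f_stats,
                 mean_f = mean(f_stats),
                 p_value = 1 - outside / B,
                 f_lower = unname(band["f_lower"]),
                 f_upper = unname(band["f_upper"]),
                 dof = c(dof, dof),
                 B = as.integer(B),
                 alpha = alpha,
                 n = n,
                 n_redrawn = redrawn),
            class = "slim_comparison")
}

#' @export
print.slim_comparison <- function(x, ...) {
  cat("Paired bootstrap F-test (B =", x$B, ", dof =", x$dof[1L], ")\n")
  cat("  mean F:", format(x$mean_f, digits = 4),
      " band: [", format(x$f_lower, digits = 4), ",",
      format(x$f_upper, digits = 4), "]\n")
  cat("  p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Write a comparison result as a one-row CSV report
#'
#' @param x A `slim_comparison`.
#' @param path Output CSV path.
#' @param f_dump Optional path; when given, the per-replicate F statistics
#'   are also written (one column, `B` rows) for audit.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(x, path, f_dump = NULL) {
  stopifnot(inherits(x, "slim_comparison"))
  df <- data.frame(mean_f = x$mean_f, p_value = x$p_value,
                   f_lower = x$f_lower, f_upper = x$f_upper,
                   B = x$B, dof1 = x$dof[1L], dof2 = x$dof[2L],
                   n = x$n, n_redrawn = x$n_redrawn)
  data.table::fwrite(df, path)
  if (!is.null(f_dump)) {
    data.table::fwrite(data.frame(f = x$f_stats), f_dump)
  }
  invisible(path)
}

#' Greedily reduce a fitted model against test data
#'
#' Walks the model's terms in their original acceptance order, refitting
#' on the test data, and keeps a term only when adding it raises the test
#' R-squared by at least `epsilon` over the model built from the terms
#' kept so far. Exposes the redundancy of a selected model: terms that
#' carried signal on the training data but add nothing out of sample are
#' dropped. The returned model is refit on the test data with only the
#' kept terms.
#'
#' @param model A [slim_model()].
#' @param test_m Test predictor matrix containing every model term.
#' @param test_y Test outcome vector.
#' @param epsilon Minimum R-squared gain to keep a term; default 0.01.
#' @return A [slim_model()] on the kept terms, fitted to the test data,
#'   with attribute `"dropped"` listing removed term names.
#' @export
reduce_model <- function(model, test_m, test_y, epsilon = 0.01) {
  stopifnot(inherits(model, "slim_model"))
  terms <- names(model$coefficients)
  missing <- setdiff(terms, colnames(test_m))
  if (length(missing)) {
    stop("model term(s) absent from test data: ", paste(missing, collapse = ", "))
  }
  kept <- character(0)
  r2 <- 0
  fit <- NULL
  for (t in terms) {
    cand_fit <- fit_ols(test_m[, c(kept, t), drop = FALSE], test_y)
    if (cand_fit$rank_deficient) next
    if (cand_fit$r2 - r2 >= epsilon) {
      kept <- c(kept, t)
      r2 <- cand_fit$r2
      fit <- cand_fit
    }
  }
  out <- if (length(kept)) {
    slim_model(intercept = fit$intercept,
               coefficients = setNames(unname(fit$slopes), kept),
               adjusted_r2 = fit$adjusted_r2,
               config = model$config)
  } else {
    slim_model(intercept = mean(test_y), adjusted_r2 = 0,
               config = model$config)
  }
  attr(out, "dropped") <- setdiff(terms, kept)
  out
}
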