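#' Selection configuration
#'
#' The three gates of the forward-selection algorithm, with the default
#' values used throughout: a predictor enters the candidate queue when its
#' absolute marginal correlation with the outcome exceeds
#' `corr_threshold`; a popped candidate is refit only when its absolute
#' correlation with the current residuals exceeds `resid_corr_threshold`
#' (the cheap shortcut that avoids a QR decomposition per candidate); and
#' it is accepted only when the model's adjusted R-squared improves by at
#' least `delta_r2`.
#'
#' @param corr_threshold Marginal-correlation screen, in `[0, 1)`; default 0.1.
#' @param resid_corr_threshold Residual-correlation gate, in `[0, 1)`;
#'   default 0.1.
#' @param delta_r2 Minimum adjusted-R-squared gain per accepted term, in
#'   `(0, 1)`; default 0.01 (each accepted predictor must explain at least
#'   1% more variance, after the degrees-of-freedom penalty).
#' @param strict_gt If `TRUE` the gain gate uses a strict `>` instead of
#'   the default `>=` comparison.
#' @return An object of class `slim_config`.
#' @export
selection_config <- function(corr_threshold = 0.1, resid_corr_threshold = 0.1,
                             delta_r2 = 0.01, strict_gt = FALSE) {
  for (v in c(corr_threshold, resid_corr_threshold)) {
    if (!is.numeric(v) || v < 0 || v >= 1) stop("thresholds must lie in [0, 1)")
  }
  if (!is.numeric(delta_r2) || delta_r2 <= 0 || delta_r2 >= 1) {
    stop("delta_r2 must lie in (0, 1)")
  }
  structure(list(corr_threshold = corr_threshold,
                 resid_corr_threshold = resid_corr_threshold,
                 delta_r2 = delta_r2,
                 strict_gt = isTRUE(strict_gt)),
            class = "slim_config")
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)`: the coefficient of
#' determination penalized for the `k` non-intercept terms in the model.
#' Equals `r2` when `k = 0`.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param k Number of non-intercept terms.
#' @return The adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n - k - 1 < 1) {
    stop("adjusted R-squared undefined: need n - k - 1 >= 1 (n = ", n,
         ", k = ", k, ")")
  }
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Least-squares fit with intercept by QR decomposition
#'
#' Fits `y ~ 1 + columns` by Householder QR. Rank deficiency at relative
#' tolerance `tol` is flagged rather than raised, since near-duplicate
#' columns are expected in highly correlated designs (forward selection
#' treats a deficient refit as a rejection).
#'
#' @param columns Numeric matrix of selected predictors (`n` rows; may
#'   have zero columns for an intercept-only fit).
#' @param y Numeric outcome of length `n`.
#' @param tol Relative rank tolerance of the QR factorization; default 1e-10.
#' @return An object of class `slim_ols`: list with `intercept`, `slopes`
#'   (named if `columns` has names), `fitted`, `residuals`, `r2`,
#'   `adjusted_r2`, `rank_deficient`, `n`, `k`.
#' @export
fit_ols <- function(columns, y, tol = 1e-10) {
  if (is.null(dim(columns))) columns <- as.matrix(columns)
  n <- length(y)
  k <- ncol(columns)
  if (nrow(columns) != n) stop("length mismatch between columns and outcome")
  if (n <= k + 1L) {
    stop("more terms than supportable by n: need n > k + 1 (n = ", n,
         ", k = ", k, ")")
  }
  X <- cbind(`(Intercept)` = 1, columns)
  qx <- qr(X, tol = tol)
  deficient <- qx$rank < ncol(X)
  coefs <- qr.coef(qx, y)
  coefs[is.na(coefs)] <- 0        # dropped directions contribute nothing
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  ssy <- sum((y - mean(y))^2)
  r2 <- if (ssy > 0) 1 - sum(resid^2) / ssy else 0
  r2 <- min(max(r2, 0), 1)
  structure(list(intercept = unname(coefs[1L]),
                 slopes = coefs[-1L],
                 fitted = fitted,
                 residuals = resid,
                 r2 = r2,
                 adjusted_r2 = adjusted_r2(r2, n, k),
                 rank_deficient = deficient,
                 n = n, k = k),
            class = "slim_ols")
}

#' Greedy forward selection with residual-correlation and adjusted-R2 gates
#'
#' The core algorithm. Predictors are screened by marginal Pearson
#' correlation (`|r| >` `corr_threshold`) into a queue sorted by
#' descending `|r|`. Starting from the intercept-only model (baseline
#' adjusted R-squared 0, residuals `y - mean(y)`), candidates are popped
#' one by one:
#' \enumerate{
#'   \item If the candidate's absolute correlation with the current
#'     residuals is `<=` `resid_corr_threshold`, it is rejected without a
#'     refit (the shortcut that saves a QR decomposition per weak
#'     candidate).
#'   \item Otherwise the current terms plus the candidate are refit by QR;
#'     a rank-deficient design rejects the candidate.
#'   \item The candidate is accepted only if the adjusted R-squared gain
#'     is at least `delta_r2`; acceptance updates the model, its
#'     residuals and the baseline adjusted R-squared.
#' }
#' Rejected candidates never re-enter. Selection halts early (with a
#' warning) if accepting another term would exhaust the residual degrees
#' of freedom. The reported coefficients come from the final joint refit,
#' so they equal an ordinary least-squares fit on exactly the accepted
#' columns.
#'
#' @param m Numeric predictor matrix with column names.
#' @param y Numeric outcome vector.
#' @param config A [selection_config()].
#' @param workers Workers for the screening pass; never changes the result.
#' @param verbose If `TRUE`, log one line per examined candidate.
#' @return An object of class `slim_trace`: list with `steps` (one row per
#'   popped candidate: `index`, `name`, `abs_corr`, `resid_corr`,
#'   `adj_r2_before`, `adj_r2_after`, `decision`), `final_model` (a
#'   [slim_model()]), `queue_size`, `n`, and `config`. Decisions are one
#'   of `accepted`, `rejected_resid_corr`, `rejected_rank`,
#'   `rejected_delta_r2`.
#' @export
run_selection <- function(m, y, config = selection_config(), workers = 1L,
                          verbose = FALSE) {
  stopifnot(inherits(config, "slim_config"))
  stop_on_invalid(m, y)
  y <- as.double(y)
  n <- length(y)

  queue <- screen_candidates(m, y, threshold = config$corr_threshold,
                             workers = workers)
  if (nrow(queue) == 0L) {
    message("no predictor passed the correlation screen; returning intercept-only model")
  }

  accepted <- integer(0)
  residuals <- y - mean(y)
  adj <- 0
  final_fit <- NULL
  steps <- vector("list", nrow(queue))
  gain_ok <- if (config$strict_gt) {
    function(g) g > config$delta_r2
  } else {
    function(g) g >= config$delta_r2
  }

  for (i in seq_len(nrow(queue))) {
    j <- queue$index[i]
    if (n - (length(accepted) + 1L) - 1L < 1L) {
      warning("selection halted early: accepting another term would exhaust ",
              "residual degrees of freedom (n = ", n, ")")
      steps <- steps[seq_len(i - 1L)]
      break
    }
    rc <- abs(pearson_cor(m[, j], residuals))
    rec <- list(index = j, name = queue$name[i], abs_corr = queue$abs_corr[i],
                resid_corr = rc, adj_r2_before = adj,
                adj_r2_after = NA_real_, decision = NA_character_)
    if (rc <= config$resid_corr_threshold) {
      rec$decision <- "rejected_resid_corr"
    } else {
      fit <- fit_ols(m[, c(accepted, j), drop = FALSE], y)
      if (fit$rank_deficient) {
        rec$decision <- "rejected_rank"
      } else {
        rec$adj_r2_after <- fit$adjusted_r2
        if (gain_ok(fit$adjusted_r2 - adj)) {
          rec$decision <- "accepted"
          accepted <- c(accepted, j)
          residuals <- fit$residuals
          adj <- fit$adjusted_r2
          final_fit <- fit
        } else {
          rec$decision <- "rejected_delta_r2"
        }
      }
    }
    if (verbose) {
      message(sprintf("[%d/%d] col %d (%s): |r|=%.4f |r_resid|=%.4f -> %s",
                      i, nrow(queue), j, rec$name, rec$abs_corr, rc,
                      rec$decision))
    }
    steps[[i]] <- rec
  }

  steps_df <- if (length(steps)) {
    do.call(rbind, lapply(steps, function(s) as.data.frame(s, stringsAsFactors = FALSE)))
  } else {
    data.frame(index = integer(0), name = character(0), abs_corr = numeric(0),
               resid_corr = numeric(0), adj_r2_before = numeric(0),
               adj_r2_after = numeric(0), decision = character(0),
               stringsAsFactors = FALSE)
  }

  model <- if (length(accepted)) {
    slim_model(intercept = final_fit$intercept,
               coefficients = setNames(unname(final_fit$slopes),
                                       colnames(m)[accepted]),
               adjusted_r2 = final_fit$adjusted_r2,
               config = config)
  } else {
    slim_model(intercept = mean(y), adjusted_r2 = 0, config = config)
  }

  structure(list(steps = steps_df,
                 final_model = model,
                 queue_size = nrow(queue),
                 n = n,
                 config = config),
            class = "slim_trace")
}

#' @export
print.slim_trace <- function(x, ...) {
  acc <- sum(x$steps$decision == "accepted")
  cat("Forward selection:", x$queue_size, "candidate(s) screened,",
      acc, "accepted\n")
  if (acc) {
    cat("  final adjusted R-squared:",
        format(x$final_model$adjusted_r2, digits = 4), "\n")
  }
  if (nrow(x$steps)) {
    cat("  decisions:\n")
    print(table(x$steps$decision))
  }
  invisible(x)
}
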