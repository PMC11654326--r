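#' Describe a planted signal for synthetic data
#'
#' Ground truth for parameter-recovery experiments: which columns carry
#' signal, their slopes, the residual noise level, and (optionally) groups
#' of columns made mutually correlated to mimic the redundancy of
#' methylome data, where many CpG columns move together.
#'
#' @param support Integer vector of distinct 1-based column indices
#'   carrying signal.
#' @param effects Numeric vector of slopes, one per support column.
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   the outcome; `>= 0`.
#' @param blocks Optional list of integer vectors, each a group of columns
#'   to equicorrelate.
#' @param rho Within-block correlation in `[0, 1)`; scalar or one value
#'   per block.
#' @return An object of class `slim_truth`.
#' @export
synthetic_truth <- function(support, effects, noise_sd, blocks = NULL,
                            rho = 0) {
  support <- as.integer(support)
  if (anyDuplicated(support) || any(support < 1L)) {
    stop("support indices must be distinct positive integers")
  }
  if (length(effects) != length(support)) {
    stop("one effect per support column required")
  }
  if (any(!is.finite(effects))) stop("effects must be finite")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(blocks)) {
    stopifnot(is.list(blocks))
    rho <- rep_len(rho, length(blocks))
    if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  }
  structure(list(support = support, effects = as.double(effects),
                 noise_sd = noise_sd, blocks = blocks, rho = rho),
            class = "slim_truth")
}

# Fill an n x p matrix with iid N(0,1) draws column-block by column-block.
# Column-major sequential fill means the values are identical to a single
# rnorm(n * p) call, whatever the block size, while peak memory stays at
# one matrix (a single 4 GB vector for the 500,000-column design would
# otherwise be duplicated by matrix()).
gaussian_matrix <- function(n, p, block_size = 25000L) {
  m <- matrix(NA_real_, n, p)
  big <- (as.double(n) * block_size * 8) > 1e8
  for (s in seq(1L, p, by = block_size)) {
    e <- min(p, s + block_size - 1L)
    m[, s:e] <- rnorm(n * (e - s + 1L))
    if (big) gc(verbose = FALSE)   # drop the spent draw buffer promptly
  }
  colnames(m) <- paste0("V", seq_len(p))
  m
}

#' Generate a pure-noise dataset
#'
#' Every predictor entry and the outcome are iid standard Gaussian, so any
#' variable a selection procedure picks is a false positive. At
#' `n = 1000, p = 500000` this is the canonical null design for measuring
#' the false-positive behaviour of screening-plus-greedy selection at
#' scale; the small preset `n = 200, p = 5000` is convenient for quick
#' checks.
#'
#' @param n Number of rows (samples), `>= 3`.
#' @param p Number of predictor columns, `>= 1`.
#' @param seed Optional integer seed; identical arguments and seed give an
#'   identical dataset.
#' @return List with `x` (n x p matrix, columns `V1..Vp`) and `y`
#'   (length-n outcome, label `"y"`).
#' @export
generate_null <- function(n, p, seed = NULL) {
  stopifnot(n >= 3, p >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- gaussian_matrix(n, p)
  y <- structure(rnorm(n), label = "y")
  list(x = x, y = y)
}

#' Generate data with planted sparse linear signal
#'
#' Columns are iid N(0,1); columns listed in a block of `truth$blocks` are
#' replaced by `sqrt(rho) * z_block + sqrt(1 - rho) * noise` with one
#' shared latent factor `z_block` per block, which equicorrelates the
#' block at `rho` while keeping every column marginally N(0,1). The
#' outcome is `y = x[, support] %*% effects + N(0, noise_sd^2)`.
#'
#' @param n Number of rows.
#' @param p Number of columns; must exceed `length(truth$support) + 1`.
#' @param truth A [synthetic_truth()] with support indices `<= p`.
#' @param seed Optional integer seed.
#' @return List with `x`, `y`, and `truth` (echoed back).
#' @export
generate_planted <- function(n, p, truth, seed = NULL) {
  stopifnot(inherits(truth, "slim_truth"), n >= 3, p >= 1)
  if (length(truth$support) >= n - 1L) {
    stop("need |support| < n - 1 for an estimable planted model")
  }
  if (any(truth$support > p)) stop("support index exceeds p")
  if (!is.null(seed)) set.seed(seed)
  x <- gaussian_matrix(n, p)
  if (!is.null(truth$blocks)) {
    for (b in seq_along(truth$blocks)) {
      cols <- as.integer(truth$blocks[[b]])
      if (any(cols > p)) stop("block index exceeds p")
      rho <- truth$rho[b]
      z <- rnorm(n)
      x[, cols] <- sqrt(rho) * z + sqrt(1 - rho) * x[, cols]
    }
  }
  signal <- drop(x[, truth$support, drop = FALSE] %*% truth$effects)
  y <- structure(signal + rnorm(n, sd = truth$noise_sd), label = "y")
  list(x = x, y = y, truth = truth)
}

#' Write the ground truth of a planted dataset as CSV
#'
#' One row per support column (`column`, `name`, `effect`) plus the noise
#' standard deviation in an attribute row; the sidecar lets a simulation
#' written to disk be scored later.
#'
#' @param truth A [synthetic_truth()].
#' @param path Output CSV path.
#' @param column_names Optional column-name vector to label support indices.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path, column_names = NULL) {
  stopifnot(inherits(truth, "slim_truth"))
  nm <- if (is.null(column_names)) paste0("V", truth$support)
        else column_names[truth$support]
  df <- data.frame(column = truth$support, name = nm,
                   effect = truth$effects, noise_sd = truth$noise_sd)
  data.table::fwrite(df, path)
  invisible(path)
}
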