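#' Pearson product-moment correlation with degenerate-input handling
#'
#' Standard Pearson correlation of two equal-length vectors. When either
#' vector has zero variance the correlation is undefined; this returns 0
#' with attribute `"degenerate" = TRUE` so screening can treat constant
#' columns (or an exhausted residual) as uninformative rather than
#' erroring.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Correlation in `[-1, 1]`; attribute `"degenerate"` is `TRUE`
#'   when either input is constant.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 3L) stop("need at least 3 observations")
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(structure(0, degenerate = TRUE))
  structure(cor(x, y), degenerate = FALSE)
}

# Column-wise correlations with y, computed block-by-block so a 4 GB
# matrix is never copied whole. Per-column serial accumulation (colSums /
# crossprod over fixed blocks) keeps the result identical across worker
# counts.
column_correlations <- function(m, y, workers = 1L, block_size = 20000L) {
  n <- nrow(m)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  p <- ncol(m)
  starts <- seq(1L, p, by = block_size)
  big <- (as.double(n) * block_size * 8) > 1e8
  one_block <- function(s) {
    e <- min(p, s + block_size - 1L)
    blk <- m[, s:e, drop = FALSE]
    num <- as.vector(crossprod(blk, yc))          # sum(yc) = 0, so x centering cancels
    ssx <- colSums(blk^2) - n * colMeans(blk)^2
    r <- numeric(length(ssx))
    ok <- ssx > 0 & ssy > 0
    r[ok] <- num[ok] / sqrt(ssx[ok] * ssy)
    rm(blk)
    # a matrix much larger than the GC trigger lets block temporaries pile
    # up for gigabytes before collection; reclaim them eagerly
    if (big) gc(verbose = FALSE)
    list(r = r, degenerate = ssx == 0)
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(starts, one_block, mc.cores = workers)
  } else {
    lapply(starts, one_block)
  }
  list(r = unlist(lapply(res, `[[`, "r"), use.names = FALSE),
       degenerate = unlist(lapply(res, `[[`, "degenerate"), use.names = FALSE))
}

#' Screen predictors by marginal correlation into a candidate queue
#'
#' Correlates every column of `m` with the outcome and retains the columns
#' whose absolute Pearson correlation strictly exceeds `threshold`
#' (default 0.1). Candidates are ordered by descending absolute
#' correlation — the priority queue that forward selection pops from —
#' with ties broken by ascending column index. Zero-variance columns get
#' r = 0, are never enqueued, and are counted in a single warning.
#'
#' @param m Numeric predictor matrix with column names.
#' @param y Numeric outcome vector, `length(y) == nrow(m)`.
#' @param threshold Screening threshold in `[0, 1)`; default 0.1.
#' @param workers Number of parallel workers for the correlation pass;
#'   affects wall time only, never the result.
#' @return An object of class `slim_queue`: data frame with columns
#'   `index` (1-based column index), `name`, `abs_corr`, `corr` (signed),
#'   plus attribute `"threshold"`.
#' @export
screen_candidates <- function(m, y, threshold = 0.1, workers = 1L) {
  stop_on_invalid(m, y)
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)")
  }
  cc <- column_correlations(m, y, workers = workers)
  ndeg <- sum(cc$degenerate)
  if (ndeg > 0L) {
    warning(ndeg, " zero-variance column(s) assigned r = 0 and excluded")
  }
  keep <- which(abs(cc$r) > threshold)
  keep <- keep[order(-abs(cc$r[keep]), keep)]
  q <- data.frame(index = keep,
                  name = colnames(m)[keep],
                  abs_corr = abs(cc$r[keep]),
                  corr = cc$r[keep],
                  stringsAsFactors = FALSE)
  structure(q, threshold = threshold, class = c("slim_queue", "data.frame"))
}

#' @export
print.slim_queue <- function(x, ...) {
  cat("Candidate queue:", nrow(x), "predictor(s) with |r| >",
      attr(x, "threshold"), "\n")
  if (nrow(x)) print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  invisible(x)
}
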