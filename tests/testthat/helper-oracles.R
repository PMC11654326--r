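# Independent oracles: deliberately naive recomputations used to check the
# package's optimized paths.

# one cor() call per column, plain set comprehension + sort
brute_screen <- function(m, y, threshold = 0.1) {
  r <- apply(m, 2L, function(col) {
    if (var(col) == 0 || var(y) == 0) 0 else cor(col, y)
  })
  keep <- unname(which(abs(r) > threshold))
  keep[order(-abs(r[keep]), keep)]
}

# normal-equations least squares (numerically inferior, algebraically exact)
normal_eq_coef <- function(columns, y) {
  X <- cbind(1, columns)
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# closed-form simple regression of y on x
simple_reg <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# textbook sum-of-products Pearson correlation
textbook_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

random_named_matrix <- function(n, p) {
  m <- matrix(rnorm(n * p), n, p)
  colnames(m) <- paste0("V", seq_len(p))
  m
}
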