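test_that("adjusted R-squared follows the penalized formula", {
  expect_equal(adjusted_r2(1, 50, 7), 1)
  expect_equal(adjusted_r2(0.42, 30, 0), 0.42)          # k = 0 is the identity
  expect_equal(adjusted_r2(0.5, 10, 2), 1 - 0.5 * 9 / 7)
  expect_error(adjusted_r2(0.5, 5, 4), "n - k - 1")
})

test_that("fit_ols recovers exact and degenerate fits", {
  x <- matrix(seq(-3, 3, length.out = 30), ncol = 1, dimnames = list(NULL, "x"))
  f <- fit_ols(x, 2 * x[, 1] + 1)
  expect_equal(unname(f$slopes), 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-12)

  xs <- matrix(rep(1:4, 8), ncol = 1, dimnames = list(NULL, "x"))
  y_orth <- rep(c(1, -1, -1, 1), 8) + 5   # orthogonal to the centered column
  f2 <- fit_ols(xs, y_orth)
  expect_equal(unname(f2$slopes), 0, tolerance = 1e-12)
  expect_equal(f2$r2, 0, tolerance = 1e-12)

  expect_error(fit_ols(random_named_matrix(4, 3), rnorm(4)), "supportable by n")
})

test_that("QR solution equals the normal equations on random designs", {
  set.seed(202)
  for (i in 1:10) {
    X <- random_named_matrix(50, 3)
    y <- rnorm(50)
    f <- fit_ols(X, y)
    expect_equal(c(f$intercept, unname(f$slopes)), normal_eq_coef(X, y),
                 tolerance = 1e-8)
    expect_false(f$rank_deficient)
  }
  dup <- cbind(a = rnorm(30))
  dup <- cbind(dup, b = dup[, "a"])
  expect_true(fit_ols(dup, rnorm(30))$rank_deficient)
})

test_that("outcome equal to one column yields that single exact term", {
  set.seed(33)
  m <- random_named_matrix(200, 20)
  tr <- run_selection(m, m[, 7])
  expect_identical(names(tr$final_model$coefficients), "V7")
  expect_equal(unname(tr$final_model$coefficients), 1, tolerance = 1e-10)
  expect_equal(tr$final_model$intercept, 0, tolerance = 1e-10)
  first <- tr$steps[1, ]
  expect_equal(first$decision, "accepted")
  # all later candidates face (numerically) zero residuals: none can be accepted
  later <- tr$steps[-1, ]
  expect_true(all(later$decision != "accepted"))
})

test_that("planted signals are recovered with coefficients equal to an OLS refit", {
  set.seed(404)
  truth <- synthetic_truth(c(1, 2), c(1.5, -1.0), noise_sd = 0.5)
  d <- generate_planted(500, 2000, truth, seed = 404)
  tr <- run_selection(d$x, d$y)
  sel <- sort(tr$steps$index[tr$steps$decision == "accepted"])
  expect_identical(sel, c(1L, 2L))
  refit <- normal_eq_coef(d$x[, names(tr$final_model$coefficients), drop = FALSE],
                          as.double(d$y))
  expect_equal(c(tr$final_model$intercept, unname(tr$final_model$coefficients)),
               refit, tolerance = 1e-10)
})

test_that("accepted adjusted-R2 trajectory is increasing by at least delta_r2", {
  set.seed(505)
  truth <- synthetic_truth(1:5, c(1, -0.8, 0.6, 0.5, -0.4), noise_sd = 1)
  d <- generate_planted(300, 400, truth, seed = 505)
  tr <- run_selection(d$x, d$y)
  acc <- tr$steps[tr$steps$decision == "accepted", ]
  expect_gte(nrow(acc), 2)
  gains <- acc$adj_r2_after - acc$adj_r2_before
  expect_true(all(gains >= tr$config$delta_r2))
  expect_true(all(diff(acc$adj_r2_after) > 0))
  # every popped candidate received a decision, in queue order, no repeats
  q <- screen_candidates(d$x, d$y)
  expect_identical(tr$steps$index, q$index)
  expect_false(anyDuplicated(tr$steps$index) > 0)
  expect_true(all(tr$steps$decision %in%
    c("accepted", "rejected_resid_corr", "rejected_rank", "rejected_delta_r2")))
})

test_that("residual gate only skips work: gate 0 and 0.1 agree on strong signals", {
  set.seed(606)
  truth <- synthetic_truth(c(3, 9), c(2, -1.5), noise_sd = 0.5)
  d <- generate_planted(400, 300, truth, seed = 606)
  tr_gated <- run_selection(d$x, d$y, selection_config(resid_corr_threshold = 0.1))
  tr_open  <- run_selection(d$x, d$y, selection_config(resid_corr_threshold = 0))
  sel_g <- tr_gated$steps$index[tr_gated$steps$decision == "accepted"]
  sel_o <- tr_open$steps$index[tr_open$steps$decision == "accepted"]
  expect_identical(sel_g, sel_o)
  # the gate must have saved refits for this to be a shortcut, not a no-op
  expect_gt(sum(tr_gated$steps$decision == "rejected_resid_corr"),
            sum(tr_open$steps$decision == "rejected_resid_corr"))
})

test_that("degenerate inputs resolve to the intercept-only model", {
  set.seed(707)
  m <- random_named_matrix(50, 10)
  expect_message(tr <- run_selection(m, rep(3.5, 50)), "intercept-only")
  expect_length(tr$final_model$coefficients, 0)
  expect_equal(tr$final_model$intercept, 3.5)
  expect_equal(predict(tr$final_model, m), rep(3.5, 50))
})

test_that("an exact duplicate of an accepted column never enters the model", {
  set.seed(808)
  m <- random_named_matrix(100, 5)
  m[, 2] <- m[, 1]                       # perfect twin
  y <- 2 * m[, 1] + rnorm(100, sd = 0.1)
  tr <- run_selection(m, y)
  dec <- tr$steps$decision[match(c(1L, 2L), tr$steps$index)]
  expect_equal(sum(dec == "accepted"), 1)        # exactly one of the twins
  expect_match(dec[dec != "accepted"], "^rejected")
  expect_length(tr$final_model$coefficients, 1)
})

test_that("selection halts before exhausting residual degrees of freedom", {
  # orthogonal-to-intercept design: three exact signal columns are accepted
  # in turn (n = 5 supports at most 3 terms), then a fourth, weakly
  # correlated candidate forces the degrees-of-freedom guard
  cm <- stats::contr.helmert(5)
  y <- rowSums(cm[, 1:3])
  m <- cbind(cm[, 1:3], cm[, 4] + 1.5 * cm[, 1])
  colnames(m) <- paste0("H", 1:4)
  expect_warning(tr <- run_selection(m, y), "halted early")
  expect_identical(names(tr$final_model$coefficients), c("H3", "H2", "H1"))
  expect_false(4L %in% tr$steps$index)     # never examined, queue abandoned
})

test_that("same inputs give identical traces across worker counts", {
  set.seed(111)
  truth <- synthetic_truth(c(2, 4), c(1, -1), noise_sd = 0.8)
  d <- generate_planted(200, 1000, truth, seed = 111)
  t1 <- run_selection(d$x, d$y, workers = 1)
  t2 <- run_selection(d$x, d$y, workers = 2)
  t8 <- run_selection(d$x, d$y, workers = 8)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$steps, t8$steps)
  expect_identical(t1$final_model$coefficients, t8$final_model$coefficients)
})

test_that("strict-gt configuration tightens the gain gate", {
  cfg <- selection_config(strict_gt = TRUE)
  expect_true(cfg$strict_gt)
  expect_error(selection_config(delta_r2 = 0), "delta_r2")
  expect_error(selection_config(corr_threshold = 1), "0, 1")
})
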