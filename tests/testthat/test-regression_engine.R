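test_that("fit_ols recovers exact linear systems and flags rank issues", {
  x <- matrix(seq_len(8), 8, 1, dimnames = list(NULL, "x"))
  fit <- fit_ols(x, 1 + 2 * x[, 1], validate = FALSE)
  expect_equal(fit$model$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(fit$model$coefficients), 2, tolerance = 1e-10)
  expect_equal(fit$report$r2, 1, tolerance = 1e-12)

  Xdup <- cbind(a = rnorm(10), b = 0)
  Xdup[, "b"] <- Xdup[, "a"]
  expect_error(fit_ols(Xdup, rnorm(10)), "collinear.*b")
})

test_that("fit_ols equals independent normal-equation solution (n=6)", {
  set.seed(21)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(6)
  Xi <- cbind(1, X)
  beta_oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)  # brute-force normal eqs
  fit <- fit_ols(X, y, validate = FALSE)
  expect_equal(unname(c(fit$model$intercept, fit$model$coefficients)),
               unname(drop(beta_oracle)), tolerance = 1e-10)
})

test_that("forward stepwise finds a dominant predictor and stops", {
  set.seed(31)
  X <- cbind(x1 = rnorm(60), x2 = rnorm(60))
  y <- 3 * X[, "x1"] + rnorm(60, 0, 0.1)
  res <- forward_stepwise(X, y)
  expect_equal(res$entry_order[1], "x1")
  expect_false("x2" %in% res$entry_order)
  expect_false(res$empty)
})

test_that("stepwise returns an empty model when nothing qualifies", {
  set.seed(32)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(200)
  expect_warning(res <- forward_stepwise(X, y, p_enter = 1e-6),
                 "intercept-only")
  expect_true(res$empty)
  expect_equal(res$entry_order, character())
})

test_that("stepwise ties break to the lower column index", {
  set.seed(33)
  x <- rnorm(30)
  X <- cbind(x1 = x, x2 = x)  # exactly collinear candidates
  y <- x + rnorm(30, 0, 0.01)
  res <- forward_stepwise(X, y)
  expect_equal(res$entry_order[1], "x1")
})

test_that("PLS with all components reduces to OLS", {
  set.seed(41)
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "x"))
  y <- 0.3 + 1.7 * x[, 1] + rnorm(20, 0, 0.2)
  pls1 <- pls_fit(x, y, 1)
  ols <- fit_ols(x, y, validate = FALSE)
  expect_equal(predict(pls1, x), unname(predict_log_fm(ols$model, x)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # orthonormal columns, LVs = columns -> full OLS equivalence
  Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  colnames(Q) <- c("a", "b", "c")
  y2 <- drop(Q %*% c(1, -2, 0.5)) + rnorm(30, 0, 0.1)
  pls_full <- pls_fit(Q, y2, 3)
  ols_full <- fit_ols(Q, y2, validate = FALSE)
  expect_equal(predict(pls_full, Q),
               unname(predict_log_fm(ols_full$model, Q)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PLS is deterministic and rejects bad inputs", {
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  f1 <- pls_fit(X, y, 2)
  f2 <- pls_fit(X, y, 2)
  expect_identical(f1$regression_vector, f2$regression_vector)

  Xc <- cbind(X, const = 1)
  expect_error(pls_fit(Xc, y, 2), "zero-variance.*const")
  expect_error(pls_fit(X, y, 5), "rank")
})

test_that("VIP scores satisfy the normalization identity", {
  for (seed in 1:4) {
    set.seed(seed)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(40 * p), 40, p,
                dimnames = list(NULL, paste0("d", seq_len(p))))
    y <- rnorm(40)
    vip <- vip_scores(pls_fit(X, y, 2))
    expect_equal(mean(vip^2), 1, tolerance = 1e-8)
  }
})

test_that("vip_reduce keeps the informative descriptor, drops noise", {
  set.seed(55)
  n <- 200
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c("signal", paste0("noise", 1:20))))
  y <- 2 * X[, "signal"] + rnorm(n, 0, 0.1)
  res <- vip_reduce(X, y, n_latent = 2)
  expect_true("signal" %in% res$retained)
  expect_lt(length(res$retained), 21L)
  # retained sets shrink weakly monotonically
  sizes <- vapply(res$trace, function(it) length(it$retained), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("single-descriptor vip_reduce stops immediately with VIP 1", {
  set.seed(56)
  X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x"))
  y <- X[, 1] + rnorm(30, 0, 0.2)
  res <- vip_reduce(X, y, n_latent = 1)
  expect_equal(res$retained, "x")
  expect_equal(unname(res$trace[[1]]$vip), 1, tolerance = 1e-8)
  expect_equal(res$stopping_reason, "all_vip_ge_1")
})

test_that("best_subset finds an exact generating subset", {
  set.seed(61)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- 2 * X[, "x1"] - X[, "x2"]
  res <- best_subset(X, y, max_size = 2)
  expect_equal(sort(res[[1]]$descriptors), c("x1", "x2"))
  expect_equal(res[[1]]$q2_loo, 1, tolerance = 1e-10)
})

test_that("best_subset enumerates the expected combination count", {
  set.seed(62)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rnorm(20)
  res <- best_subset(X, y, max_size = 2)
  expect_length(res, 4L + 6L)

  res1 <- best_subset(X[, 1, drop = FALSE], y, max_size = 3)
  expect_length(res1, 1L)

  expect_error(best_subset(X, y, max_size = 4, guard_limit = 3),
               "guard limit")
})

test_that("best_subset q2 ranking matches explicit LOO refits", {
  set.seed(63)
  X <- matrix(rnorm(18 * 5), 18, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(18, 0, 0.3)
  res <- best_subset(X, y, max_size = 2)
  # oracle: recompute q2_loo by explicit per-row refits for every subset
  for (cand in res[1:5]) {
    oracle <- q2_loo(X[, cand$descriptors, drop = FALSE], y,
                     ols_fitter())$q2_loo
    expect_equal(cand$q2_loo, oracle, tolerance = 1e-8)
  }
  q2s <- vapply(res, function(cc) cc$q2_loo, 0)
  expect_true(all(diff(q2s) <= 1e-12))
})

test_that("prefilter drops constant and near-collinear columns", {
  set.seed(71)
  a <- rnorm(50)
  X <- cbind(a = a, b = a + rnorm(50, 0, 1e-4), c = rnorm(50),
             const = rep(2, 50))
  keep <- prefilter_descriptors(X)
  expect_equal(keep, c("a", "c"))
})
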