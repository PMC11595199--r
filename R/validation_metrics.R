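#' Training-set fit statistics
#'
#' Computes the determination coefficient R^2 = 1 - RSS/TSS, its adjusted
#' form and the overall F statistic for a fitted regression with
#' `n_params` descriptors (or PLS latent variables — PLS models count
#' latent variables, not original descriptors, as parameters).
#'
#' @param y observed responses.
#' @param y_hat fitted values, same length.
#' @param n_params number of model parameters excluding the intercept.
#' @return list with `r2`, `r2_adj`, `f_value`. A perfect fit reports
#'   `f_value = Inf`.
#' @export
training_stats <- function(y, y_hat, n_params) {
  stopifnot(length(y) == length(y_hat), n_params >= 1)
  n <- length(y)
  if (n < n_params + 2L) {
    stop("need at least n_params + 2 observations", call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero response variance", call. = FALSE)
  r2 <- 1 - sum((y - y_hat)^2) / tss
  list(r2 = r2,
       r2_adj = r2_adj_from_r2(r2, n, n_params),
       f_value = f_from_r2(r2, n, n_params))
}

#' Adjusted R-squared from printed summary quantities
#'
#' `r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1)`. Exposed separately so
#' that published statistic blocks (R^2, n, descriptor or latent-variable
#' count p) can be checked analytically without refitting.
#'
#' @param r2 determination coefficient.
#' @param n number of training observations.
#' @param n_params number of descriptors or latent variables.
#' @export
r2_adj_from_r2 <- function(r2, n, n_params) {
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Overall F statistic from printed summary quantities
#'
#' `F = [r2 / (1 - r2)] * [(n - p - 1) / p]`; `Inf` when r2 = 1.
#'
#' @inheritParams r2_adj_from_r2
#' @export
f_from_r2 <- function(r2, n, n_params) {
  if (r2 >= 1) return(Inf)
  (r2 / (1 - r2)) * ((n - n_params - 1) / n_params)
}

#' Leave-one-out cross-validation Q^2
#'
#' For each training row, the model is refitted on the remaining rows and
#' the held-out row predicted; `q2_loo = 1 - PRESS/TSS` with TSS taken
#' about the full training mean.
#'
#' @param X descriptor matrix (training rows).
#' @param y responses.
#' @param fit_fun a fitting procedure: `function(X, y)` returning a
#'   prediction function `function(X_new) -> numeric`. See [ols_fitter()]
#'   and [pls_fitter()].
#' @return list with `q2_loo` and `press`.
#' @export
q2_loo <- function(X, y, fit_fun = ols_fitter()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows for LOO", call. = FALSE)
  press <- 0
  for (i in seq_len(n)) {
    pred_fun <- tryCatch(fit_fun(X[-i, , drop = FALSE], y[-i]),
                         error = function(e) {
                           stop("LOO refit failed on fold ", i, ": ",
                                conditionMessage(e), call. = FALSE)
                         })
    press <- press + (y[i] - pred_fun(X[i, , drop = FALSE]))^2
  }
  tss <- sum((y - mean(y))^2)
  list(q2_loo = 1 - press / tss, press = as.numeric(press))
}

#' Leave-many-out (k-fold) cross-validated RMSE
#'
#' Rows are shuffled with the given seed, split into `k_folds` near-equal
#' folds, and the root mean squared held-out error is pooled over folds.
#' The default 8 folds matches the published LMO protocol; fold
#' construction (a seeded uniform shuffle) is this package's choice, so
#' the seed is part of the contract.
#'
#' @inheritParams q2_loo
#' @param k_folds number of folds (>= 2), default 8.
#' @param seed RNG seed for the shuffle, default 1.
#' @return `rmsecv`, a single number in response units.
#' @export
rmsecv_lmo <- function(X, y, fit_fun = ols_fitter(), k_folds = 8L,
                       seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_folds < 2L) stop("k_folds must be >= 2", call. = FALSE)
  if (n < k_folds) stop("need at least k_folds rows", call. = FALSE)
  perm <- withr_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k_folds), length.out = n)
  sse <- 0
  for (k in seq_len(k_folds)) {
    hold <- which(fold_of == k)
    pred_fun <- fit_fun(X[-hold, , drop = FALSE], y[-hold])
    sse <- sse + sum((y[hold] - pred_fun(X[hold, , drop = FALSE]))^2)
  }
  sqrt(sse / n)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' External (test-set) validation statistics
#'
#' `q2_f1` scales the prediction error by deviations about the *training*
#' mean, `q2_f2` about the *test* mean; `rmsep` is the root mean squared
#' external prediction error and `r2_ext` the squared Pearson correlation
#' between observed and predicted test responses.
#'
#' @param y_test observed test responses (length >= 2).
#' @param y_hat_test predicted test responses.
#' @param y_train_mean mean response of the training set.
#' @return list with `q2_f1`, `q2_f2`, `rmsep`, `r2_ext`.
#' @export
external_stats <- function(y_test, y_hat_test, y_train_mean) {
  stopifnot(length(y_test) == length(y_hat_test), length(y_test) >= 2L)
  sse <- sum((y_test - y_hat_test)^2)
  ss_test <- sum((y_test - mean(y_test))^2)
  if (ss_test <= 0) {
    stop("zero test-set response variance: q2_f2 undefined", call. = FALSE)
  }
  list(q2_f1 = 1 - sse / sum((y_test - y_train_mean)^2),
       q2_f2 = 1 - sse / ss_test,
       rmsep = sqrt(sse / length(y_test)),
       r2_ext = suppressWarnings(stats::cor(y_test, y_hat_test))^2)
}

#' Full validation report for a fitted model
#'
#' Convenience wrapper assembling every statistic the package reports:
#' training R^2/adjusted R^2/F, leave-one-out Q^2, 8-fold RMSECV and the
#' external test statistics.
#'
#' @param X_train,y_train training descriptor matrix and responses.
#' @param X_test,y_test optional external test set.
#' @param fit_fun fitting procedure as in [q2_loo()].
#' @param n_params parameter count for R^2_adj / F (latent variables for
#'   PLS fits).
#' @param k_folds,seed passed to [rmsecv_lmo()].
#' @return list of class `validation_report`.
#' @export
validation_report <- function(X_train, y_train, X_test = NULL,
                              y_test = NULL, fit_fun = ols_fitter(),
                              n_params = ncol(as.matrix(X_train)),
                              k_folds = 8L, seed = 1L) {
  X_train <- as.matrix(X_train)
  pred_fun <- fit_fun(X_train, y_train)
  ts <- training_stats(y_train, pred_fun(X_train), n_params)
  loo <- q2_loo(X_train, y_train, fit_fun)
  out <- list(r2 = ts$r2, r2_adj = ts$r2_adj, f_value = ts$f_value,
              q2_loo = loo$q2_loo, press = loo$press,
              rmsecv = rmsecv_lmo(X_train, y_train, fit_fun, k_folds, seed),
              n_train = nrow(X_train), n_params = n_params)
  if (!is.null(X_test) && !is.null(y_test)) {
    ex <- external_stats(y_test, pred_fun(as.matrix(X_test)),
                         mean(y_train))
    out <- c(out, ex, list(n_test = length(y_test)))
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) formatC(v, digits = 3, format = "f")
  cat("validation_report\n")
  cat(sprintf("  training (n=%d, p=%d): R2=%s R2_adj=%s F=%s\n",
              x$n_train, x$n_params, fmt(x$r2), fmt(x$r2_adj),
              fmt(x$f_value)))
  cat(sprintf("  internal: Q2_LOO=%s RMSECV=%s\n", fmt(x$q2_loo),
              fmt(x$rmsecv)))
  if (!is.null(x$q2_f1)) {
    cat(sprintf("  external (n=%d): Q2_F1=%s Q2_F2=%s RMSEP=%s R2_ext=%s\n",
                x$n_test, fmt(x$q2_f1), fmt(x$q2_f2), fmt(x$rmsep),
                fmt(x$r2_ext)))
  }
  invisible(x)
}
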