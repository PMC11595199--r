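#' Pre-filter descriptor columns
#'
#' Drops zero-variance columns (variance below `zero_var_tol`) and, among
#' near-collinear pairs (`|Pearson r| > cor_limit`), keeps only the
#' first-listed member. Mirrors the automatic discarding of constant and
#' strongly co-linear variables done before PLS/MLR model building.
#'
#' @param X descriptor matrix.
#' @param cor_limit pairwise absolute correlation limit, default 0.99.
#' @param zero_var_tol variance tolerance, default 1e-12.
#' @return character vector of retained column names.
#' @export
prefilter_descriptors <- function(X, cor_limit = 0.99,
                                  zero_var_tol = 1e-12) {
  X <- as.matrix(X)
  vars <- apply(X, 2L, stats::var)
  keep <- colnames(X)[vars > zero_var_tol]
  if (length(keep) > 1L) {
    cc <- abs(suppressWarnings(stats::cor(X[, keep, drop = FALSE])))
    drop <- logical(length(keep))
    for (j in seq_along(keep)[-1L]) {
      if (any(cc[j, seq_len(j - 1L)][!drop[seq_len(j - 1L)]] > cor_limit,
              na.rm = TRUE)) {
        drop[j] <- TRUE
      }
    }
    keep <- keep[!drop]
  }
  keep
}

#' Ordinary least squares fit
#'
#' Fits `y ~ X` with an intercept and returns the coefficients as a
#' `linear_model` plus a [validation_report()]. Rank-deficient input is an
#' error naming the collinear columns.
#'
#' @param X descriptor matrix, more rows than columns + 1.
#' @param y responses.
#' @param validate compute the full validation report (LOO + 8-fold CV)?
#'   Set `FALSE` for speed inside search loops.
#' @param model_id id stored on the returned model.
#' @return list with `model` (a `linear_model`) and `report`
#'   (`validation_report` or training stats only).
#' @export
fit_ols <- function(X, y, validate = TRUE, model_id = "ols") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) <= ncol(X) + 1L) {
    stop("need more rows than descriptors + 1", call. = FALSE)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(Xi))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  model <- linear_model(model_id, unname(beta[1L]), beta[-1L], "MLR")
  report <- if (validate) {
    validation_report(X, y, fit_fun = ols_fitter())
  } else {
    c(training_stats(y, predict_log_fm(model, X), ncol(X)),
      list(n_train = nrow(X), n_params = ncol(X)))
  }
  list(model = model, report = report)
}

#' OLS fitting procedure for cross-validation
#'
#' Returns a `function(X, y)` that fits OLS and yields a prediction
#' closure, the contract used by [q2_loo()], [rmsecv_lmo()] and
#' [best_subset()].
#' @export
ols_fitter <- function() {
  function(X, y) {
    X <- as.matrix(X)
    Xi <- cbind(1, X)
    beta <- qr.coef(qr(Xi), y)
    beta[is.na(beta)] <- 0
    function(X_new) {
      drop(cbind(1, as.matrix(X_new)) %*% beta)
    }
  }
}

#' PLS fitting procedure for cross-validation
#'
#' @param n_latent number of latent variables for each refit.
#' @export
pls_fitter <- function(n_latent = 2L) {
  function(X, y) {
    fit <- pls_fit(X, y, n_latent)
    function(X_new) predict(fit, X_new)
  }
}

#' Forward stepwise descriptor selection
#'
#' Greedy forward selection: at each step the candidate descriptor with
#' the smallest partial-F p-value is added if that p-value is below
#' `p_enter`; the search stops when no candidate qualifies or `max_terms`
#' is reached. Ties (identical p-values) resolve to the lowest column
#' index. If nothing qualifies at step one, an intercept-only model is
#' returned with `empty = TRUE` (a warning, not an error).
#'
#' @param X candidate descriptor matrix.
#' @param y responses.
#' @param p_enter entry significance threshold, default 0.05.
#' @param max_terms maximum number of descriptors to admit.
#' @return list with `model`, `entry_order` (character), `empty` flag and
#'   `report` (NULL when empty).
#' @export
forward_stepwise <- function(X, y, p_enter = 0.05,
                             max_terms = ncol(as.matrix(X))) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  selected <- integer()
  rss_cur <- sum((y - mean(y))^2)
  repeat {
    if (length(selected) >= max_terms) break
    candidates <- setdiff(seq_len(ncol(X)), selected)
    if (!length(candidates)) break
    p_new <- length(selected) + 1L
    df_resid <- n - p_new - 1L
    if (df_resid < 1L) break
    best_p <- Inf
    best_j <- NA_integer_
    best_rss <- NA_real_
    for (j in candidates) {
      Xi <- cbind(1, X[, c(selected, j), drop = FALSE])
      qr_x <- qr(Xi)
      if (qr_x$rank < ncol(Xi)) next  # exactly collinear with current set
      res <- qr.resid(qr_x, y)
      rss_j <- sum(res^2)
      f <- (rss_cur - rss_j) / (rss_j / df_resid)
      p_val <- stats::pf(f, 1, df_resid, lower.tail = FALSE)
      if (p_val < best_p - 1e-15) {
        best_p <- p_val
        best_j <- j
        best_rss <- rss_j
      }
    }
    if (!is.finite(best_p) || is.na(best_j) || best_p >= p_enter) break
    selected <- c(selected, best_j)
    rss_cur <- best_rss
  }
  if (!length(selected)) {
    warning("no descriptor met p_enter; returning intercept-only model")
    model <- linear_model("stepwise", mean(y),
                          stats::setNames(0, colnames(X)[1L]), "MLR")
    return(list(model = model, entry_order = character(), empty = TRUE,
                report = NULL))
  }
  fit <- fit_ols(X[, selected, drop = FALSE], y, model_id = "stepwise")
  list(model = fit$model, entry_order = colnames(X)[selected],
       empty = FALSE, report = fit$report)
}

#' NIPALS partial least squares regression (PLS1)
#'
#' Fits a PLS regression with the NIPALS algorithm after auto-scaling
#' (columns centred and scaled to unit variance; the response centred).
#' The fit is deterministic for fixed input. The equivalent regression
#' vector on the original descriptor scale is stored so predictions are a
#' plain affine map.
#'
#' @param X descriptor matrix; zero-variance columns are an error (remove
#'   them with [prefilter_descriptors()]).
#' @param y responses.
#' @param n_latent number of latent variables, `1 <= n_latent <=`
#'   rank of the scaled matrix.
#' @return object of class `pls_model` with elements `n_latent`,
#'   `x_weights`, `x_loadings`, `y_loadings`, `scores`, `scaling`
#'   (`mean`, `sd`, `y_mean`), `regression_vector`, `intercept`.
#' @export
pls_fit <- function(X, y, n_latent = 2L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 1e-12)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds <= 1e-12], collapse = ", "), call. = FALSE)
  }
  Xs <- scale(X, center = mu, scale = sds)
  rank_x <- qr(Xs)$rank
  if (n_latent < 1L || n_latent > rank_x) {
    stop("n_latent must be between 1 and rank(X) = ", rank_x,
         call. = FALSE)
  }
  y_mean <- mean(y)
  f <- y - y_mean
  E <- Xs
  W <- P <- matrix(0, p, n_latent,
                   dimnames = list(colnames(X),
                                   paste0("LV", seq_len(n_latent))))
  Tm <- matrix(0, nrow(X), n_latent)
  q <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
  }
  # regression vector on the auto-scaled scale, then back-transformed
  b_scaled <- W %*% solve(crossprod(P, W), q)
  beta <- drop(b_scaled) / sds
  intercept <- y_mean - sum(beta * mu)
  structure(list(n_latent = n_latent, x_weights = W, x_loadings = P,
                 y_loadings = q, scores = Tm,
                 scaling = list(mean = mu, sd = sds, y_mean = y_mean),
                 regression_vector = stats::setNames(beta, colnames(X)),
                 intercept = intercept),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  m <- as_descriptor_matrix(newdata)
  missing <- setdiff(names(object$regression_vector), colnames(m))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop(m[, names(object$regression_vector), drop = FALSE] %*%
         object$regression_vector) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d LV over %d descriptors\n", x$n_latent,
              length(x$regression_vector)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP scores from a fitted [pls_fit()] model:
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` where
#' `SSY_a = q_a^2 * t_a't_a` is the response variance explained by latent
#' variable `a`. The scores satisfy `mean(VIP^2) = 1`.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  w2 <- model$x_weights^2  # columns already unit norm
  p <- nrow(w2)
  sqrt(p * drop(w2 %*% ssy) / sum(ssy))
}

#' Iterative VIP-based variable reduction
#'
#' Repeatedly fits a PLS model, computes VIP scores and drops every
#' descriptor with VIP below `vip_floor`, until no descriptor is dropped
#' (all VIP >= floor), `max_iter` is reached, or only one descriptor
#' remains. This is the published reduction loop ("VIP < 1 rejected,
#' procedure repeated").
#'
#' @param X descriptor matrix, already pre-filtered (no zero-variance or
#'   near-collinear columns).
#' @param y responses.
#' @param n_latent latent variables per iteration (capped at the current
#'   descriptor count).
#' @param vip_floor rejection threshold, default 1.0.
#' @param max_iter iteration cap, default 50.
#' @return list with `retained` (character), `trace` (list of per-iteration
#'   `list(retained, vip)`), `stopping_reason` in
#'   `{"all_vip_ge_1","max_iter","floor_reached"}`.
#' @export
vip_reduce <- function(X, y, n_latent = 2L, vip_floor = 1.0,
                       max_iter = 50L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  retained <- colnames(X)
  trace <- list()
  reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    lv <- min(n_latent, length(retained))
    fit <- pls_fit(X[, retained, drop = FALSE], y, lv)
    vip <- vip_scores(fit)
    trace[[it]] <- list(retained = retained, vip = vip)
    drop_names <- names(vip)[vip < vip_floor]
    if (!length(drop_names)) {
      reason <- "all_vip_ge_1"
      break
    }
    if (length(drop_names) == length(retained)) {
      stop("all descriptors dropped at iteration ", it,
           "; consider a lower vip_floor", call. = FALSE)
    }
    retained <- setdiff(retained, drop_names)
    if (length(retained) == 1L) {
      # a single descriptor always has VIP = 1: record and stop
      fit1 <- pls_fit(X[, retained, drop = FALSE], y, 1L)
      trace[[it + 1L]] <- list(retained = retained,
                               vip = vip_scores(fit1))
      reason <- "floor_reached"
      break
    }
  }
  list(retained = retained, trace = trace, stopping_reason = reason)
}

# PRESS for an OLS fit via the hat-matrix shortcut: residual_i/(1-h_ii).
# Fast path used by best_subset; the test suite checks it against
# explicit leave-one-out refits.
press_ols <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) return(NA_real_)
  res <- qr.resid(qr_x, y)
  h <- rowSums(qr.Q(qr_x)^2)
  if (any(h > 1 - 1e-10)) return(NA_real_)
  sum((res / (1 - h))^2)
}

#' Exhaustive best-subset search ranked by cross-validated Q^2
#'
#' Enumerates every descriptor combination of size 1..`max_size`, fits
#' OLS, and ranks candidates by leave-one-out `q2_loo` (descending), with
#' a lexicographic tie-break on the joined descriptor names. Subsets whose
#' design is rank-deficient or that leave no residual degrees of freedom
#' are skipped.
#'
#' @param X_pool candidate descriptor matrix.
#' @param y responses.
#' @param max_size largest subset size.
#' @param criterion ranking criterion; only `"q2_loo"` is implemented.
#' @param guard_limit maximum number of combinations to enumerate.
#' @return list of candidates, each `list(descriptors, q2_loo, model)`,
#'   best first.
#' @export
best_subset <- function(X_pool, y, max_size, criterion = "q2_loo",
                        guard_limit = 100000L) {
  criterion <- match.arg(criterion, "q2_loo")
  X_pool <- as.matrix(X_pool)
  if (is.null(colnames(X_pool))) {
    colnames(X_pool) <- paste0("x", seq_len(ncol(X_pool)))
  }
  p <- ncol(X_pool)
  max_size <- min(max_size, p, nrow(X_pool) - 2L)
  n_comb <- sum(choose(p, seq_len(max_size)))
  if (n_comb > guard_limit) {
    stop(sprintf(
      "%d combinations exceed guard limit %d; reduce the pool first",
      n_comb, guard_limit), call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  cands <- list()
  for (k in seq_len(max_size)) {
    combs <- utils::combn(p, k)
    for (ci in seq_len(ncol(combs))) {
      idx <- combs[, ci]
      press <- press_ols(X_pool[, idx, drop = FALSE], y)
      if (is.na(press)) next
      cands[[length(cands) + 1L]] <- list(
        descriptors = colnames(X_pool)[idx],
        q2_loo = 1 - press / tss)
    }
  }
  if (!length(cands)) stop("no admissible subset found", call. = FALSE)
  key <- vapply(cands, function(cc) paste(cc$descriptors, collapse = "|"),
                "")
  q2 <- vapply(cands, function(cc) cc$q2_loo, 0)
  ord <- order(-q2, key, method = "radix")
  cands <- cands[ord]
  # attach fitted coefficients for the leading candidates only; the full
  # ranking keeps descriptors + q2_loo for every admissible subset
  for (i in seq_len(min(10L, length(cands)))) {
    fit <- fit_ols(X_pool[, cands[[i]]$descriptors, drop = FALSE], y,
                   validate = FALSE, model_id = "best_subset")
    cands[[i]]$model <- fit$model
  }
  cands
}
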