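#' Similarity configuration for Read-Across
#'
#' Bundles the Read-Across hyperparameters: the similarity kernel, its
#' width and the number of close source compounds used per prediction.
#' Distances are Euclidean on auto-scaled descriptors (training mean/sd);
#' the kernels map distance `d` to similarity in (0, 1]:
#' `euclidean: 1/(1+d)`, `gaussian: exp(-d^2/(2*sigma^2))`,
#' `laplacian: exp(-d/gamma)`.
#'
#' @param kernel `"euclidean"`, `"gaussian"` or `"laplacian"`.
#' @param sigma Gaussian width (> 0), used when `kernel = "gaussian"`.
#' @param gamma Laplacian width (> 0), used when `kernel = "laplacian"`.
#' @param n_close number of close source compounds (>= 1).
#' @return list of class `ra_config`.
#' @export
ra_config <- function(kernel = c("gaussian", "laplacian", "euclidean"),
                      sigma = 1, gamma = 1, n_close = 5L) {
  kernel <- match.arg(kernel)
  if (kernel == "gaussian" && (!is.finite(sigma) || sigma <= 0)) {
    stop("sigma must be > 0 for the gaussian kernel", call. = FALSE)
  }
  if (kernel == "laplacian" && (!is.finite(gamma) || gamma <= 0)) {
    stop("gamma must be > 0 for the laplacian kernel", call. = FALSE)
  }
  if (n_close < 1L) stop("n_close must be >= 1", call. = FALSE)
  structure(list(kernel = kernel, sigma = sigma, gamma = gamma,
                 n_close = as.integer(n_close)),
            class = "ra_config")
}

#' @export
print.ra_config <- function(x, ...) {
  width <- switch(x$kernel, gaussian = sprintf("sigma=%g", x$sigma),
                  laplacian = sprintf("gamma=%g", x$gamma), "")
  cat(sprintf("ra_config: %s kernel %s n_close=%d\n", x$kernel, width,
              x$n_close))
  invisible(x)
}

#' Kernel similarity between two descriptor vectors
#'
#' Both vectors are assumed already auto-scaled with the training
#' mean/sd. Identical vectors have similarity 1 under every kernel.
#'
#' @param a,b numeric vectors of equal length.
#' @param config an [ra_config()].
#' @return similarity in (0, 1].
#' @export
similarity <- function(a, b, config) {
  if (length(a) != length(b)) {
    stop("vectors have different lengths", call. = FALSE)
  }
  kernel_similarity(sqrt(sum((a - b)^2)), config)
}

kernel_similarity <- function(d, config) {
  switch(config$kernel,
         euclidean = 1 / (1 + d),
         gaussian = exp(-d^2 / (2 * config$sigma^2)),
         laplacian = exp(-d / config$gamma))
}

# Auto-scaling parameters from a source (training) matrix.
autoscale_params <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[sds <= 1e-12] <- 1  # constant columns contribute zero distance
  list(mean = mu, sd = sds)
}

apply_autoscale <- function(X, params) {
  scale(X, center = params$mean, scale = params$sd)
}

# Log-similarities of one scaled query row to all scaled source rows.
# Working on the log scale keeps the similarity weighting well defined
# for very tight kernels, where the raw similarities underflow to zero
# but their ratios (and hence the Read-Across weights) do not.
log_similarities_to_sources <- function(q_scaled, src_scaled, config) {
  d <- sqrt(rowSums(sweep(src_scaled, 2L, q_scaled)^2))
  switch(config$kernel,
         euclidean = -log1p(d),
         gaussian = -d^2 / (2 * config$sigma^2),
         laplacian = -d / config$gamma)
}

# Select the n_close most similar sources; ties broken by lexicographic
# compound id. Returns indices into the source rows.
select_close <- function(sims, ids, n_close) {
  ord <- order(-sims, ids, method = "radix")
  ord[seq_len(n_close)]
}

#' Read-Across prediction
#'
#' Predicts the response of each query compound as the similarity-weighted
#' mean of its `n_close` most similar source (training) compounds:
#' `y_hat = sum(s_i * y_i) / sum(s_i)`. Ties in similarity resolve to the
#' lexicographically lower source id. A query whose similarities to all
#' sources are numerically zero is an applicability error.
#'
#' @param query descriptor matrix of query compounds (raw scale; columns
#'   must match `sources_x`).
#' @param sources_x raw descriptor matrix of source compounds; the
#'   auto-scaling used for distances is fitted on these rows.
#' @param sources_y responses of the source compounds.
#' @param config an [ra_config()].
#' @return named numeric vector of predictions, with attribute `"close"`:
#'   a list (one data.frame per query: source id, similarity, response).
#' @export
ra_predict <- function(query, sources_x, sources_y, config) {
  query <- as_descriptor_matrix(query)
  sources_x <- as_descriptor_matrix(sources_x)
  if (config$n_close > nrow(sources_x)) {
    stop("n_close exceeds the number of source compounds", call. = FALSE)
  }
  params <- autoscale_params(sources_x)
  src_scaled <- apply_autoscale(sources_x, params)
  q_scaled <- apply_autoscale(query[, colnames(sources_x), drop = FALSE],
                              params)
  src_ids <- rownames(sources_x)
  preds <- numeric(nrow(query))
  close <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    ls <- log_similarities_to_sources(q_scaled[i, ], src_scaled, config)
    if (all(!is.finite(ls))) {
      stop("all similarities numerically zero for query '",
           rownames(query)[i], "': outside applicability", call. = FALSE)
    }
    sel <- select_close(ls, src_ids, config$n_close)
    w <- exp(ls[sel] - max(ls[sel]))  # stabilized similarity weights
    preds[i] <- sum(w * sources_y[sel]) / sum(w)
    close[[i]] <- data.frame(source_id = src_ids[sel],
                             similarity = exp(ls[sel]),
                             response = sources_y[sel],
                             stringsAsFactors = FALSE)
  }
  names(preds) <- rownames(query)
  names(close) <- rownames(query)
  attr(preds, "close") <- close
  preds
}

#' Default Read-Across hyperparameter grid
#'
#' Kernel widths `sigma, gamma` in \{0.25, 0.5, 1, 2, 4\} and
#' `n_close` in 2..8, crossed per kernel (the euclidean kernel has no
#' width). A small bounded lattice keeps optimization at desk scale.
#'
#' @param sigmas,gammas candidate kernel widths.
#' @param n_close candidate close-compound counts.
#' @return data.frame with columns `kernel`, `sigma`, `gamma`, `n_close`.
#' @export
default_ra_grid <- function(sigmas = c(0.25, 0.5, 1, 2, 4),
                            gammas = c(0.25, 0.5, 1, 2, 4),
                            n_close = 2:8) {
  rbind(
    expand.grid(kernel = "euclidean", sigma = NA_real_, gamma = NA_real_,
                n_close = n_close, stringsAsFactors = FALSE),
    expand.grid(kernel = "gaussian", sigma = sigmas, gamma = NA_real_,
                n_close = n_close, stringsAsFactors = FALSE),
    expand.grid(kernel = "laplacian", sigma = NA_real_, gamma = gammas,
                n_close = n_close, stringsAsFactors = FALSE)
  )
}

grid_row_config <- function(row) {
  ra_config(kernel = row$kernel,
            sigma = if (is.na(row$sigma)) 1 else row$sigma,
            gamma = if (is.na(row$gamma)) 1 else row$gamma,
            n_close = row$n_close)
}

#' Read-Across hyperparameter optimization by grid search
#'
#' Splits the training rows into sub-training and validation sets with a
#' seeded shuffle, generates Read-Across predictions of the validation
#' responses from sub-training sources for every grid point, and returns
#' the configuration minimizing validation RMSE (ties -> first in grid
#' order). Grid points with `n_close` larger than the sub-training size
#' are skipped.
#'
#' @param X_train,y_train training descriptors and responses.
#' @param grid data.frame as from [default_ra_grid()].
#' @param split_fraction fraction of training rows kept as sub-training,
#'   default 0.75.
#' @param seed RNG seed for the split.
#' @return list with `best_config` (an [ra_config()]), `best_rmse` and
#'   `report` (grid data.frame with an `rmse` column).
#' @export
optimize_hyperparameters <- function(X_train, y_train,
                                     grid = default_ra_grid(),
                                     split_fraction = 0.75, seed = 1L) {
  if (!nrow(grid)) stop("empty hyperparameter grid", call. = FALSE)
  X_train <- as_descriptor_matrix(X_train)
  n <- nrow(X_train)
  n_sub <- floor(split_fraction * n)
  if (n_sub < 5L) stop("sub-training set below 5 compounds", call. = FALSE)
  sub_idx <- sort(withr_seed(seed, sample.int(n, n_sub)))
  val_idx <- setdiff(seq_len(n), sub_idx)
  rmse <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, ]
    if (row$n_close > n_sub) next
    cfg <- grid_row_config(row)
    pred <- ra_predict(X_train[val_idx, , drop = FALSE],
                       X_train[sub_idx, , drop = FALSE],
                       y_train[sub_idx], cfg)
    rmse[g] <- sqrt(mean((y_train[val_idx] - pred)^2))
  }
  if (all(is.na(rmse))) stop("no admissible grid point", call. = FALSE)
  best <- which.min(rmse)  # first minimum in grid order
  report <- grid
  report$rmse <- rmse
  list(best_config = grid_row_config(grid[best, ]),
       best_rmse = rmse[best], report = report)
}

#' Similarity and error-based RASAR descriptors
#'
#' For each query compound, over its `n_close` close source compounds:
#' `RA_function` (the Read-Across weighted prediction), `AvgSim`/`SDSim`
#' (mean and standard deviation of the close similarities), `MaxPos`
#' (maximum similarity to a close source in the higher-response half of
#' the sources, 0 if none is close), `MaxNeg` (likewise for the
#' lower-response half) and the binary concordance indicator
#' `gm = 1 if MaxPos >= MaxNeg else 0`. Source compounds are labeled
#' higher/lower response by the training-median split (`y >
#' response_split` is higher).
#'
#' @inheritParams ra_predict
#' @param response_split response threshold separating higher- from
#'   lower-response sources; defaults to `median(sources_y)`.
#' @return data.frame with columns `RA_function`, `AvgSim`, `SDSim`,
#'   `MaxPos`, `MaxNeg`, `gm`, rownames = query ids.
#' @export
compute_rasar_descriptors <- function(query, sources_x, sources_y, config,
                                      response_split =
                                        stats::median(sources_y)) {
  query <- as_descriptor_matrix(query)
  sources_x <- as_descriptor_matrix(sources_x)
  if (config$n_close > nrow(sources_x)) {
    stop("n_close exceeds the number of source compounds", call. = FALSE)
  }
  params <- autoscale_params(sources_x)
  src_scaled <- apply_autoscale(sources_x, params)
  q_scaled <- apply_autoscale(query[, colnames(sources_x), drop = FALSE],
                              params)
  src_ids <- rownames(sources_x)
  higher <- sources_y > response_split
  out <- matrix(NA_real_, nrow(query), 6L,
                dimnames = list(rownames(query),
                                c("RA_function", "AvgSim", "SDSim",
                                  "MaxPos", "MaxNeg", "gm")))
  for (i in seq_len(nrow(query))) {
    ls <- log_similarities_to_sources(q_scaled[i, ], src_scaled, config)
    if (all(!is.finite(ls))) {
      stop("all similarities numerically zero for query '",
           rownames(query)[i], "': outside applicability", call. = FALSE)
    }
    sel <- select_close(ls, src_ids, config$n_close)
    s <- exp(ls[sel])
    w <- exp(ls[sel] - max(ls[sel]))
    hi_sel <- higher[sel]
    max_pos <- if (any(hi_sel)) max(s[hi_sel]) else 0
    max_neg <- if (any(!hi_sel)) max(s[!hi_sel]) else 0
    out[i, ] <- c(sum(w * sources_y[sel]) / sum(w),
                  mean(s),
                  if (length(s) > 1L) stats::sd(s) else 0,
                  max_pos, max_neg,
                  as.numeric(max_pos >= max_neg))
  }
  as.data.frame(out)
}

#' Build a q-RASAR PLS model
#'
#' The full q-RASAR assembly: RASAR descriptors are computed for every
#' training compound leave-self-out (its own row never serves as a
#' source, preventing leakage into cross-validation) and for every test
#' compound from the full training set; the QSAR descriptors and RASAR
#' features are fused into one pool; [best_subset()] picks the
#' combination with the best leave-one-out Q^2; and a final NIPALS PLS
#' model with `n_latent` latent variables is fitted on the selection.
#'
#' @param dataset a `perm_dataset` with train (and optionally test) roles.
#' @param qsar_descriptors names of the conventional descriptors to fuse.
#' @param config an optimized [ra_config()].
#' @param max_size largest subset size for the best-subset search.
#' @param n_latent latent variables of the final PLS fit (default 2);
#'   must not exceed the selected descriptor count.
#' @param k_folds,seed passed to the validation report.
#' @return list with `model` (`pls_model`), `selected` descriptor names,
#'   `report` (a [validation_report()]), `train_features`,
#'   `test_features` (fused matrices) and `config`.
#' @export
build_qrasar <- function(dataset, qsar_descriptors, config, max_size = 5L,
                         n_latent = 2L, k_folds = 8L, seed = 1L) {
  stopifnot(inherits(dataset, "perm_dataset"))
  X_tr <- train_matrix(dataset)[, qsar_descriptors, drop = FALSE]
  y_tr <- train_response(dataset)
  split <- stats::median(y_tr)
  n_tr <- nrow(X_tr)
  if (config$n_close > n_tr - 1L) {
    stop("n_close too large for leave-self-out sources", call. = FALSE)
  }
  rasar_tr <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    compute_rasar_descriptors(X_tr[i, , drop = FALSE],
                              X_tr[-i, , drop = FALSE], y_tr[-i], config,
                              response_split = split)
  }))
  fused_tr <- cbind(X_tr, as.matrix(rasar_tr))
  has_test <- any(dataset$role == "test")
  fused_te <- NULL
  if (has_test) {
    X_te <- test_matrix(dataset)[, qsar_descriptors, drop = FALSE]
    rasar_te <- compute_rasar_descriptors(X_te, X_tr, y_tr, config,
                                          response_split = split)
    fused_te <- cbind(X_te, as.matrix(rasar_te))
  }
  pool <- prefilter_descriptors(fused_tr)
  cands <- best_subset(fused_tr[, pool, drop = FALSE], y_tr, max_size)
  selected <- cands[[1L]]$descriptors
  if (n_latent > length(selected)) {
    stop("n_latent (", n_latent, ") exceeds selected descriptor count (",
         length(selected), ")", call. = FALSE)
  }
  model <- pls_fit(fused_tr[, selected, drop = FALSE], y_tr, n_latent)
  report <- validation_report(
    fused_tr[, selected, drop = FALSE], y_tr,
    X_test = if (has_test) fused_te[, selected, drop = FALSE],
    y_test = if (has_test) test_response(dataset),
    fit_fun = pls_fitter(n_latent), n_params = n_latent,
    k_folds = k_folds, seed = seed)
  list(model = model, selected = selected, report = report,
       train_features = fused_tr, test_features = fused_te,
       config = config)
}
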