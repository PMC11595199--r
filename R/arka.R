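#' Min-max scaling fitted on a training table
#'
#' Maps every training column to [0, 1] by `(x - min) / (max - min)` and
#' applies the *training* parameters to an optional second table (whose
#' values may therefore fall outside [0, 1]; no clipping). Degenerate
#' columns (max == min on the training set) are errors.
#'
#' @param train_table training descriptor table/matrix.
#' @param apply_table optional table to transform with the training
#'   parameters (e.g. test or screening compounds).
#' @return list with `train_scaled`, `apply_scaled` (or NULL) and
#'   `scaling_params` (data.frame of per-descriptor min/max).
#' @export
scale_minmax <- function(train_table, apply_table = NULL) {
  m <- as_descriptor_matrix(train_table)
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  degen <- colnames(m)[hi - lo <= 0]
  if (length(degen)) {
    stop("degenerate column(s) (max == min): ",
         paste(degen, collapse = ", "), call. = FALSE)
  }
  rescale <- function(x) sweep(sweep(x, 2L, lo), 2L, hi - lo, "/")
  out <- list(train_scaled = rescale(m), apply_scaled = NULL,
              scaling_params = data.frame(descriptor = colnames(m),
                                          min = lo, max = hi,
                                          row.names = NULL))
  if (!is.null(apply_table)) {
    a <- as_descriptor_matrix(apply_table)
    missing <- setdiff(colnames(m), colnames(a))
    if (length(missing)) {
      stop("apply_table lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out$apply_scaled <- rescale(a[, colnames(m), drop = FALSE])
  }
  out
}

#' Assign descriptors to ARKA groups by response-conditional means
#'
#' Training compounds are split at the median response: the
#' higher-response half is `y > median(y)` (ties at the median join the
#' lower half). A descriptor joins `group1` when its mean min-max-scaled
#' value over the higher-response half strictly exceeds its mean over the
#' lower half, otherwise `group2` (equality -> group2). Intuitively,
#' group1 collects descriptors elevated in good placenta penetrators.
#'
#' @param scaled_train min-max scaled training matrix (see
#'   [scale_minmax()]).
#' @param y training responses (log FM).
#' @param split_rule only `"median"` is implemented.
#' @return named character vector: descriptor -> `"group1"`/`"group2"`.
#' @export
assign_groups <- function(scaled_train, y, split_rule = "median") {
  split_rule <- match.arg(split_rule, "median")
  m <- as.matrix(scaled_train)
  if (length(unique(y)) < 2L) {
    stop("all responses identical; cannot split", call. = FALSE)
  }
  hi <- y > stats::median(y)
  if (sum(hi) < 2L || sum(!hi) < 2L) {
    stop("need at least 2 compounds on each side of the median split",
         call. = FALSE)
  }
  mean_hi <- colMeans(m[hi, , drop = FALSE])
  mean_lo <- colMeans(m[!hi, , drop = FALSE])
  stats::setNames(ifelse(mean_hi > mean_lo, "group1", "group2"),
                  colnames(m))
}

#' Compute ARKA descriptors
#'
#' ARKA (arithmetic residuals in K-groups analysis) reduces a modeling
#' descriptor set to K = 2 aggregate descriptors: `ARKA1` is each
#' compound's mean scaled value over group-1 descriptors, `ARKA2` over
#' group-2 descriptors. An empty group yields 0 (with a warning) rather
#' than an error, so screening runs never crash.
#'
#' @param scaled_table min-max scaled matrix (training or apply scale from
#'   [scale_minmax()]).
#' @param group_assignment named vector from [assign_groups()]; must cover
#'   every column.
#' @return data.frame with columns `ARKA1`, `ARKA2`, rownames = compound
#'   ids.
#' @export
compute_arka <- function(scaled_table, group_assignment) {
  m <- as.matrix(scaled_table)
  uncovered <- setdiff(colnames(m), names(group_assignment))
  if (length(uncovered)) {
    stop("group assignment missing for: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  group_mean <- function(g) {
    cols <- names(group_assignment)[group_assignment == g]
    cols <- intersect(cols, colnames(m))
    if (!length(cols)) {
      warning("empty ", g, "; ARKA value set to 0")
      return(rep(0, nrow(m)))
    }
    rowMeans(m[, cols, drop = FALSE])
  }
  data.frame(ARKA1 = group_mean("group1"), ARKA2 = group_mean("group2"),
             row.names = rownames(m))
}

#' Confidence quadrants in the ARKA plane
#'
#' Points in the first (both values > 0) or third (both < 0) quadrant of
#' the ARKA2-vs-ARKA1 plane are flagged `"less_confident"`; all others —
#' including points exactly on an axis — are `"confident"`. Raw min-max
#' ARKA values are non-negative, so the quadrants only become informative
#' after centering (see [arka_pipeline()]'s `center` toggle).
#'
#' @param features data.frame with `ARKA1`, `ARKA2` columns (finite).
#' @return character vector `"confident"`/`"less_confident"` named by
#'   rownames.
#' @export
confidence_quadrants <- function(features) {
  a1 <- features$ARKA1
  a2 <- features$ARKA2
  if (any(!is.finite(a1)) || any(!is.finite(a2))) {
    stop("ARKA values must be finite", call. = FALSE)
  }
  lab <- ifelse((a1 > 0 & a2 > 0) | (a1 < 0 & a2 < 0),
                "less_confident", "confident")
  stats::setNames(lab, rownames(features))
}

#' End-to-end ARKA feature computation for a dataset
#'
#' Scales the chosen descriptors (min-max on the training set), assigns
#' groups from the training responses, computes ARKA1/ARKA2 for every
#' compound and labels confidence quadrants. With `center = TRUE`
#' (default) the quadrant analysis uses training-mean-centred ARKA values
#' so that all four quadrants can be populated; the returned `ARKA1`,
#' `ARKA2` columns are always the uncentred values used by the ARKA
#' regression models.
#'
#' @param dataset a `perm_dataset`.
#' @param descriptors character vector of modeling descriptor names.
#' @param center centre ARKA values (by their training means) before the
#'   quadrant analysis?
#' @return list with `features` (data.frame ARKA1, ARKA2, role, quadrant
#'   label per compound), `group_assignment`, `scaling_params`,
#'   `arka_center` (the training means used, or c(0,0)).
#' @export
arka_pipeline <- function(dataset, descriptors, center = TRUE) {
  stopifnot(inherits(dataset, "perm_dataset"))
  m <- as_descriptor_matrix(dataset$table)
  missing <- setdiff(descriptors, colnames(m))
  if (length(missing)) {
    stop("dataset lacks descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  train_ids <- names(dataset$role)[dataset$role == "train"]
  other_ids <- setdiff(rownames(m), train_ids)
  sc <- scale_minmax(m[train_ids, descriptors, drop = FALSE],
                     if (length(other_ids))
                       m[other_ids, descriptors, drop = FALSE])
  grp <- assign_groups(sc$train_scaled, dataset$response[train_ids])
  feats <- compute_arka(sc$train_scaled, grp)
  if (length(other_ids)) {
    feats <- rbind(feats, compute_arka(sc$apply_scaled, grp))
  }
  feats <- feats[rownames(m), , drop = FALSE]
  ctr <- if (center) {
    colMeans(feats[train_ids, c("ARKA1", "ARKA2"), drop = FALSE])
  } else {
    c(ARKA1 = 0, ARKA2 = 0)
  }
  centred <- data.frame(ARKA1 = feats$ARKA1 - ctr[["ARKA1"]],
                        ARKA2 = feats$ARKA2 - ctr[["ARKA2"]],
                        row.names = rownames(feats))
  feats$role <- dataset$role[rownames(feats)]
  feats$quadrant <- confidence_quadrants(centred)
  list(features = feats, group_assignment = grp,
       scaling_params = sc$scaling_params, arka_center = ctr)
}
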