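#' Configuration for a screening run
#'
#' @param table a [descriptor_table] of compounds to screen (or use
#'   `input` to read one from disk).
#' @param input optional path to a delimited descriptor table.
#' @param models character vector of model-bank ids to apply.
#' @param classify_with model id whose predictions drive the PL1/PL0
#'   call; defaults to the first model.
#' @param fm_cutoff FM classification cutoff, default 0.3.
#' @param filters evaluate the drug-likeness filters?
#' @param tolerance filter tolerance, `"strict"` or `"allow_one"`.
#' @param seed seed recorded in the provenance snapshot (the pipeline
#'   itself is deterministic; the seed feeds any downstream resampling).
#' @param delimiter input delimiter.
#' @param output_dir optional directory for report files.
#' @return list of class `screening_config`.
#' @export
screening_config <- function(table = NULL, input = NULL,
                             models = "eq1", classify_with = models[1L],
                             fm_cutoff = 0.3, filters = TRUE,
                             tolerance = "strict", seed = 1L,
                             delimiter = ",", output_dir = NULL) {
  if (is.null(table) && is.null(input)) {
    stop("provide either a table or an input path", call. = FALSE)
  }
  stopifnot(all(models %in% model_bank_ids()),
            classify_with %in% models)
  structure(list(table = table, input = input, models = models,
                 classify_with = classify_with, fm_cutoff = fm_cutoff,
                 filters = isTRUE(filters), tolerance = tolerance,
                 seed = as.integer(seed), delimiter = delimiter,
                 output_dir = output_dir),
            class = "screening_config")
}

#' Run the screening workflow end-to-end
#'
#' Applies every selected model-bank model to the input table, classifies
#' placental permeability from the designated model's predictions,
#' optionally evaluates the drug-likeness filters, and summarizes the
#' PL1 vs PL0 groups over the key physico-chemical features. The run is
#' deterministic given the configuration; the configuration snapshot is
#' embedded in the report so a run can be replayed exactly.
#'
#' @param config a [screening_config()].
#' @return object of class `screening_report`: list with `per_compound`
#'   (wide data.frame: predictions, FM, classes, filter flags),
#'   `group_summary` (long data.frame from [summarize_groups()]),
#'   `config`.
#' @export
run_screening <- function(config) {
  stopifnot(inherits(config, "screening_config"))
  tab <- if (!is.null(config$table)) config$table
         else read_descriptor_table(config$input, config$delimiter)
  m <- as_descriptor_matrix(tab)
  per <- data.frame(compound_id = rownames(m), stringsAsFactors = FALSE)
  for (id in config$models) {
    model <- get_model(id)
    missing <- setdiff(model$required_inputs, colnames(m))
    if (length(missing)) {
      stop("model '", id, "' cannot run: column(s) ",
           paste(missing, collapse = ", "), " absent from input",
           call. = FALSE)
    }
    per[[paste0("log_fm_", id)]] <- unname(predict_log_fm(model, m))
  }
  call <- classify_permeability(
    per[[paste0("log_fm_", config$classify_with)]], config$fm_cutoff)
  per$fm <- call$fm
  per$crossing_class <- call$crossing_class
  per$pl_score <- call$pl_score
  if (config$filters) {
    verdicts <- evaluate_filters_table(m, config$tolerance)
    colnames(verdicts) <- paste0("filter_", colnames(verdicts))
    per <- cbind(per, verdicts)
  }
  feature_cols <- intersect(c("iLOGP", "M_w", "MR", "TPSA"), colnames(m))
  per <- cbind(per, as.data.frame(m[, feature_cols, drop = FALSE]))
  rownames(per) <- NULL
  report <- structure(list(per_compound = per, group_summary = NULL,
                           config = config),
                      class = "screening_report")
  report$group_summary <- summarize_groups(report, feature_cols)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per, file.path(config$output_dir,
                                    "per_compound.csv"),
                     row.names = FALSE)
    utils::write.csv(report$group_summary,
                     file.path(config$output_dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.screening_report <- function(x, ...) {
  tab <- table(x$per_compound$pl_score)
  cat(sprintf("screening_report: %d compounds (%s)\n",
              nrow(x$per_compound),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Summarize PL1 vs PL0 groups feature by feature
#'
#' For each feature, reports per-group mean/median/min/max and a
#' distribution-free two-sample comparison (Wilcoxon rank-sum, normal
#' approximation) between the PL1 (likely high permeability) and PL0
#' groups. If a group is empty for some feature the summaries are still
#' emitted and the test is skipped with a note.
#'
#' @param report a `screening_report` (or any list with a `per_compound`
#'   data.frame carrying `pl_score` and the feature columns).
#' @param features feature column names, default the available subset of
#'   iLOGP, M_w, MR, TPSA.
#' @return long data.frame: feature, group, n, mean, median, min, max,
#'   w_statistic, p_value, note.
#' @export
summarize_groups <- function(report,
                             features = intersect(
                               c("iLOGP", "M_w", "MR", "TPSA"),
                               colnames(report$per_compound))) {
  per <- report$per_compound
  out <- list()
  for (f in features) {
    v1 <- per[[f]][per$pl_score == "PL1"]
    v0 <- per[[f]][per$pl_score == "PL0"]
    test_ok <- length(v1) >= 1L && length(v0) >= 1L
    w <- p <- NA_real_
    note <- ""
    if (test_ok) {
      ht <- suppressWarnings(stats::wilcox.test(v1, v0, exact = FALSE))
      w <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      note <- "one group empty; test skipped"
    }
    gstats <- function(v, g) {
      data.frame(feature = f, group = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 w_statistic = w, p_value = p, note = note,
                 stringsAsFactors = FALSE)
    }
    out[[f]] <- rbind(gstats(v1, "PL1"), gstats(v0, "PL0"))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
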