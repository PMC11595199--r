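#' Construct a descriptor table
#'
#' A descriptor table is the package's basic container: a numeric matrix
#' with one row per compound and one named column per molecular descriptor
#' (e.g. `M_w` in Da, `TPSA` in A^2, dimensionless topological indices).
#' It is stored as a plain numeric matrix carrying the class
#' `"descriptor_table"`, so all matrix operations work directly on it.
#'
#' @param values numeric matrix (rows = compounds, columns = descriptors).
#' @param compound_ids character vector of unique, non-empty compound
#'   identifiers; defaults to `rownames(values)`. Identifiers are treated
#'   as case-sensitive opaque strings.
#' @param descriptor_names character vector of unique descriptor names;
#'   defaults to `colnames(values)`.
#' @return A `descriptor_table` object.
#' @export
#' @examples
#' m <- matrix(c(228.2, 30.2, 272.4, 80.7), 2, 2,
#'             dimnames = list(c("BP3", "EHMC"), c("M_w", "TPSA")))
#' descriptor_table(m)
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("descriptor values must be numeric", call. = FALSE)
  }
  if (is.null(compound_ids)) {
    stop("compound_ids are required (rownames or explicit argument)",
         call. = FALSE)
  }
  if (is.null(descriptor_names)) {
    stop("descriptor_names are required (colnames or explicit argument)",
         call. = FALSE)
  }
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (nrow(values) < 1L) stop("at least one compound required", call. = FALSE)
  if (length(compound_ids) != nrow(values) ||
      length(descriptor_names) != ncol(values)) {
    stop("id/name lengths do not match matrix dimensions", call. = FALSE)
  }
  if (any(!nzchar(compound_ids)) || anyNA(compound_ids)) {
    stop("compound ids must be non-empty strings", call. = FALSE)
  }
  dup <- compound_ids[duplicated(compound_ids)]
  if (length(dup)) {
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dupd <- descriptor_names[duplicated(descriptor_names)]
  if (length(dupd)) {
    stop("duplicate descriptor name(s): ",
         paste(unique(dupd), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value for compound '%s', descriptor '%s'",
                 compound_ids[bad[1L]], descriptor_names[bad[2L]]),
         call. = FALSE)
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  class(values) <- c("descriptor_table", class(values))
  values
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d compounds x %d descriptors\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more compounds\n")
  invisible(x)
}

#' @rdname descriptor_table
#' @param x object to test or coerce.
#' @export
is_descriptor_table <- function(x) inherits(x, "descriptor_table")

# Accept descriptor_table / matrix / data.frame and return a plain numeric
# matrix with compound rownames. Internal coercion used across modules.
as_descriptor_matrix <- function(x) {
  if (is_descriptor_table(x)) return(unclass(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a descriptor_table, numeric matrix or data.frame",
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  x
}

#' Read a descriptor table from a delimited text file
#'
#' The first row is a header and the first column holds compound
#' identifiers; every other column must parse as a number ("." decimal
#' mark). Missing or non-numeric cells are hard errors naming the offending
#' row and column — no imputation is performed anywhere in the package.
#'
#' @param path path to the file.
#' @param delimiter field separator, default comma.
#' @return A [descriptor_table].
#' @export
read_descriptor_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("need an id column plus at least one descriptor column",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  desc_names <- colnames(raw)[-1L]
  values <- matrix(NA_real_, nrow(raw), length(desc_names))
  for (j in seq_along(desc_names)) {
    cell <- trimws(raw[[j + 1L]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(cell))
    if (length(bad)) {
      stop(sprintf(
        "cannot parse value '%s' in row %d (compound '%s'), column '%s'",
        cell[bad[1L]], bad[1L], ids[bad[1L]], desc_names[j]), call. = FALSE)
    }
    values[, j] <- num
  }
  descriptor_table(values, compound_ids = ids, descriptor_names = desc_names)
}

#' Write a descriptor table to a delimited text file
#'
#' Values are written with full double precision so that
#' `read_descriptor_table(write_descriptor_table(x))` round-trips exactly
#' to at least six decimals.
#'
#' @param table a [descriptor_table].
#' @param path output path.
#' @param delimiter field separator, default comma.
#' @param id_column header name for the identifier column.
#' @export
write_descriptor_table <- function(table, path, delimiter = ",",
                                   id_column = "compound_id") {
  m <- as_descriptor_matrix(table)
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Assemble a modeling dataset with train/test/screen roles
#'
#' Splits a descriptor table into the fixed-role layout used throughout:
#' training compounds (used to build models), test compounds (external
#' validation) and screen compounds (no measured response; prediction
#' targets only). The response column is removed from the descriptor
#' matrix. Compound ids not listed in either split become `"screen"`.
#'
#' @param table a [descriptor_table] containing the response as a column.
#' @param response_name name of the response column (log FM: log10 of the
#'   fetal/maternal blood concentration ratio).
#' @param train_ids,test_ids disjoint character vectors of compound ids.
#' @return An object of class `perm_dataset`: a list with elements `table`
#'   (descriptors only), `response` (named numeric, `NA` for screen
#'   compounds) and `role` (named character in train/test/screen).
#' @export
make_dataset <- function(table, response_name, train_ids,
                         test_ids = character()) {
  m <- as_descriptor_matrix(table)
  if (!response_name %in% colnames(m)) {
    stop("response column '", response_name, "' not found", call. = FALSE)
  }
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  if (length(train_ids) == 0L) stop("train set is empty", call. = FALSE)
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap)) {
    stop("ids in both train and test: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(c(train_ids, test_ids), rownames(m))
  if (length(unknown)) {
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  response <- m[, response_name]
  missing_y <- c(train_ids, test_ids)[!is.finite(response[c(train_ids,
                                                            test_ids)])]
  if (length(missing_y)) {
    stop("missing/non-finite response for train/test compound(s): ",
         paste(missing_y, collapse = ", "), call. = FALSE)
  }
  role <- stats::setNames(rep("screen", nrow(m)), rownames(m))
  role[train_ids] <- "train"
  role[test_ids] <- "test"
  response[role == "screen"] <- NA_real_
  keep <- setdiff(colnames(m), response_name)
  out <- list(
    table = descriptor_table(m[, keep, drop = FALSE]),
    response = response,
    role = role
  )
  class(out) <- "perm_dataset"
  out
}

#' @export
print.perm_dataset <- function(x, ...) {
  tab <- table(factor(x$role, levels = c("train", "test", "screen")))
  cat(sprintf(
    "perm_dataset: %d train / %d test / %d screen, %d descriptors\n",
    tab[["train"]], tab[["test"]], tab[["screen"]], ncol(x$table)))
  invisible(x)
}

#' Role-based dataset accessors
#'
#' Extract the descriptor matrix or response vector for one role of a
#' `perm_dataset`.
#'
#' @param dataset a `perm_dataset` from [make_dataset()].
#' @param role one of `"train"`, `"test"`, `"screen"`.
#' @return a numeric matrix (rows = compounds of that role) or a named
#'   response vector.
#' @export
dataset_matrix <- function(dataset, role) {
  ids <- names(dataset$role)[dataset$role == role]
  as_descriptor_matrix(dataset$table)[ids, , drop = FALSE]
}

#' @rdname dataset_matrix
#' @export
train_matrix <- function(dataset) dataset_matrix(dataset, "train")

#' @rdname dataset_matrix
#' @export
test_matrix <- function(dataset) dataset_matrix(dataset, "test")

#' @rdname dataset_matrix
#' @export
train_response <- function(dataset) {
  dataset$response[names(dataset$role)[dataset$role == "train"]]
}

#' @rdname dataset_matrix
#' @export
test_response <- function(dataset) {
  dataset$response[names(dataset$role)[dataset$role == "test"]]
}

#' Write per-compound predictions alongside permeability calls
#'
#' Writes a delimited file with one row per predicted compound: identifier,
#' predicted log FM, the back-transformed FM ratio and the C/NC and
#' PL1/PL0 permeability classes at the given FM cutoff.
#'
#' @param dataset a `perm_dataset`; every prediction id must be one of its
#'   compounds.
#' @param predictions named numeric vector of predicted log FM values.
#' @param path output path.
#' @param fm_cutoff FM classification cutoff, default 0.3.
#' @param delimiter field separator.
#' @export
write_predictions <- function(dataset, predictions, path, fm_cutoff = 0.3,
                              delimiter = ",") {
  ids <- names(predictions)
  if (length(predictions) && is.null(ids)) {
    stop("predictions must be named by compound id", call. = FALSE)
  }
  unknown <- setdiff(ids, names(dataset$role))
  if (length(unknown)) {
    stop("prediction for unknown compound id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(predictions)) {
    call <- classify_permeability(as.numeric(predictions), fm_cutoff)
    df <- data.frame(compound_id = ids,
                     log_fm = format(call$log_fm, digits = 17, trim = TRUE,
                                     scientific = FALSE),
                     fm = format(call$fm, digits = 17, trim = TRUE,
                                 scientific = FALSE),
                     crossing_class = call$crossing_class,
                     pl_score = call$pl_score,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(compound_id = character(), log_fm = character(),
                     fm = character(), crossing_class = character(),
                     pl_score = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
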