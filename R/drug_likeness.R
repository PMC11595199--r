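# Filter thresholds as printed in the absorption/drug-likeness
# literature. Descriptor columns expected (SwissADME/Mordred-style):
# M_w (Da), TPSA (A^2), MLOGP, cLogP, XLOGP, WLOGP, MR, HA, HD, FRB,
# Atoms, Rings, Carbons, Heteroatoms.

filter_names <- function() {
  c("lipinski_mordred", "lipinski_swiss", "veber", "ghose_mordred",
    "ghose_swiss", "palm", "egan", "muegge")
}

# Each rule returns TRUE (within bounds), FALSE, or NA if the needed
# descriptor is absent.
rule <- function(row, name, test) {
  if (!name %in% names(row) || is.na(row[[name]])) return(NA)
  test(row[[name]])
}

lipinski_subrules <- function(row, logp_variant) {
  logp <- if (logp_variant == "mordred") {
    rule(row, "MLOGP", function(v) v <= 4.15)
  } else {
    rule(row, "cLogP", function(v) v <= 5)
  }
  c(mw = rule(row, "M_w", function(v) v <= 500),
    logp = logp,
    ha = rule(row, "HA", function(v) v <= 10),
    hd = rule(row, "HD", function(v) v <= 5))
}

ghose_subrules <- function(row) {
  c(mw = rule(row, "M_w", function(v) v >= 160 && v <= 480),
    wlogp = rule(row, "WLOGP", function(v) v >= -0.4 && v <= 5.6),
    mr = rule(row, "MR", function(v) v >= 40 && v <= 130),
    atoms = rule(row, "Atoms", function(v) v >= 20 && v <= 70))
}

# Combine sub-rule outcomes under a violation tolerance. Any NA sub-rule
# makes the filter not evaluable (NA) — missing data never counts as a
# violation.
combine_subrules <- function(flags, max_violations) {
  if (anyNA(flags)) return(NA)
  sum(!flags) <= max_violations
}

#' Evaluate absorption/drug-likeness filters for one compound
#'
#' Applies the eight rule filters with their printed thresholds:
#' * Lipinski (Mordred): M_w <= 500, MLOGP <= 4.15, HA <= 10, HD <= 5 —
#'   always the "strict" version (no violation permitted), the variant
#'   most closely linked to placental permeability;
#' * Lipinski (SwissADME): same bounds with cLogP <= 5 as the
#'   lipophilicity sub-rule; honours `tolerance` (`"allow_one"` accepts
#'   one violation);
#' * Veber: TPSA <= 140 and FRB <= 10;
#' * Ghose (Mordred / SwissADME): 160 <= M_w <= 480,
#'   -0.4 <= WLOGP <= 5.6, 40 <= MR <= 130, 20 <= Atoms <= 70; the
#'   Mordred variant is strict, the SwissADME variant honours
#'   `tolerance`;
#' * Palm: TPSA <= 140;
#' * Egan: TPSA <= 131.6 and WLOGP < 5.88 (the WLOGP bound is exclusive,
#'   exactly as printed; all other bounds are inclusive);
#' * Muegge: 200 <= M_w <= 600, -2 <= XLOGP <= 5, Rings <= 7,
#'   Carbons > 4, Heteroatoms > 1, FRB <= 15, HA <= 10.
#'
#' A filter whose required descriptor column is absent is reported `NA`
#' (not evaluable), never failed.
#'
#' @param row named numeric vector (or single-row data.frame/matrix) of
#'   descriptor values.
#' @param tolerance `"strict"` (default) or `"allow_one"`; applies to the
#'   SwissADME filter variants only.
#' @return object of class `filter_verdict`: list with `filters` (named
#'   logical, NA = not evaluable), `lipinski_violations` (0–4, Mordred
#'   sub-rules; NA if not evaluable) and `violation_tolerance`.
#' @export
evaluate_filters <- function(row, tolerance = c("strict", "allow_one")) {
  tolerance <- match.arg(tolerance)
  if (is.matrix(row) || is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    row <- stats::setNames(as.numeric(row[1L, ]), colnames(row))
  }
  row <- as.list(row)
  allow <- if (tolerance == "allow_one") 1L else 0L
  lm_flags <- lipinski_subrules(row, "mordred")
  ls_flags <- lipinski_subrules(row, "swiss")
  gh_flags <- ghose_subrules(row)
  mu_flags <- c(mw = rule(row, "M_w", function(v) v >= 200 && v <= 600),
                xlogp = rule(row, "XLOGP", function(v) v >= -2 && v <= 5),
                rings = rule(row, "Rings", function(v) v <= 7),
                carbons = rule(row, "Carbons", function(v) v > 4),
                het = rule(row, "Heteroatoms", function(v) v > 1),
                frb = rule(row, "FRB", function(v) v <= 15),
                ha = rule(row, "HA", function(v) v <= 10))
  veber_flags <- c(tpsa = rule(row, "TPSA", function(v) v <= 140),
                   frb = rule(row, "FRB", function(v) v <= 10))
  egan_flags <- c(tpsa = rule(row, "TPSA", function(v) v <= 131.6),
                  wlogp = rule(row, "WLOGP", function(v) v < 5.88))
  filters <- c(
    lipinski_mordred = combine_subrules(lm_flags, 0L),
    lipinski_swiss = combine_subrules(ls_flags, allow),
    veber = combine_subrules(veber_flags, 0L),
    ghose_mordred = combine_subrules(gh_flags, 0L),
    ghose_swiss = combine_subrules(gh_flags, allow),
    palm = rule(row, "TPSA", function(v) v <= 140),
    egan = combine_subrules(egan_flags, 0L),
    muegge = combine_subrules(mu_flags, 0L)
  )
  structure(list(filters = filters,
                 lipinski_violations =
                   if (anyNA(lm_flags)) NA_integer_
                   else sum(!lm_flags),
                 violation_tolerance = tolerance),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  show <- ifelse(is.na(x$filters), "NA",
                 ifelse(x$filters, "pass", "FAIL"))
  cat("filter_verdict (", x$violation_tolerance, "):\n", sep = "")
  for (i in seq_along(show)) {
    cat(sprintf("  %-17s %s\n", names(x$filters)[i], show[i]))
  }
  cat("  lipinski_violations:", x$lipinski_violations, "\n")
  invisible(x)
}

#' Evaluate filters for every compound of a table
#'
#' @param table a [descriptor_table], matrix or data.frame.
#' @inheritParams evaluate_filters
#' @return data.frame (compounds x 8 filters) of logical/NA outcomes.
#' @export
evaluate_filters_table <- function(table,
                                   tolerance = c("strict", "allow_one")) {
  tolerance <- match.arg(tolerance)
  m <- as_descriptor_matrix(table)
  out <- t(vapply(seq_len(nrow(m)), function(i) {
    evaluate_filters(m[i, ], tolerance)$filters
  }, stats::setNames(logical(8L), filter_names())))
  as.data.frame(out, row.names = rownames(m))
}

#' Binary filter-by-permeability matrix for clustering
#'
#' Combines per-compound filter verdicts with PL1/PL0 permeability calls
#' into one 0/1 matrix (compounds x up to 9 columns: the 8 filters plus
#' `PL`). Filters that are not evaluable for at least one compound are
#' excluded column-wise with a warning.
#'
#' @param verdicts data.frame from [evaluate_filters_table()] (or a list
#'   of `filter_verdict`s).
#' @param pl_calls per-compound PL scores: `"PL1"`/`"PL0"`, logical or
#'   0/1 numeric.
#' @return binary integer matrix.
#' @export
permeability_filter_matrix <- function(verdicts, pl_calls) {
  if (is.list(verdicts) && !is.data.frame(verdicts) &&
      all(vapply(verdicts, inherits, TRUE, "filter_verdict"))) {
    verdicts <- as.data.frame(do.call(rbind,
                                      lapply(verdicts, `[[`, "filters")))
  }
  if (!nrow(verdicts)) stop("empty verdict input", call. = FALSE)
  if (nrow(verdicts) != length(pl_calls)) {
    stop("verdicts and pl_calls have different lengths", call. = FALSE)
  }
  pl <- if (is.character(pl_calls)) as.integer(pl_calls == "PL1")
        else as.integer(as.logical(pl_calls))
  m <- as.matrix(verdicts) * 1L
  drop_cols <- colnames(m)[colSums(is.na(m)) > 0L]
  if (length(drop_cols)) {
    warning("excluding non-evaluable filter column(s): ",
            paste(drop_cols, collapse = ", "))
    m <- m[, setdiff(colnames(m), drop_cols), drop = FALSE]
  }
  cbind(m, PL = pl)
}

binary_column_dist <- function(m, distance) {
  cols <- colnames(m)
  p <- ncol(m)
  d <- matrix(0, p, p, dimnames = list(cols, cols))
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      x <- m[, i]
      y <- m[, j]
      d[i, j] <- d[j, i] <- if (distance == "jaccard") {
        un <- sum(x | y)
        1 - sum(x & y) / un  # caller guarantees un > 0
      } else {
        mean(x != y)
      }
    }
  }
  stats::as.dist(d)
}

#' Cluster filter profiles against the permeability class
#'
#' Agglomerative hierarchical clustering of the binary columns of a
#' [permeability_filter_matrix()] (filters + PL), revealing which filter
#' is most closely linked to placental permeability. Jaccard distance is
#' the default (`1 - |intersection| / |union|` over compounds flagged 1);
#' if some column pair has an empty union (undefined Jaccard), the
#' function falls back to simple-matching distance with a warning.
#' Reports the filter column that joins PL at the smallest cophenetic
#' height (ties -> earlier column).
#'
#' @param matrix binary matrix from [permeability_filter_matrix()].
#' @param linkage `"complete"` (default), `"single"` or `"average"`.
#' @param distance `"jaccard"` (default) or `"matching"`.
#' @return list with `hclust` (a [stats::hclust] tree over columns),
#'   `distance_used`, `nearest_to_pl` (filter name) and
#'   `nearest_height`.
#' @export
cluster_filter_profiles <- function(matrix,
                                    linkage = c("complete", "single",
                                                "average"),
                                    distance = c("jaccard", "matching")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (distance == "jaccard") {
    empty_union <- outer(seq_len(ncol(m)), seq_len(ncol(m)),
                         Vectorize(function(i, j) {
                           i != j && sum(m[, i] | m[, j]) == 0L
                         }))
    if (any(empty_union)) {
      warning("empty union under jaccard; falling back to matching ",
              "distance")
      distance <- "matching"
    }
  }
  d <- binary_column_dist(m, distance)
  hc <- stats::hclust(d, method = linkage)
  coph <- as.matrix(stats::cophenetic(hc))
  filters <- setdiff(colnames(m), "PL")
  heights <- coph["PL", filters]
  nearest <- filters[which.min(heights)]
  list(hclust = hc, distance_used = distance, nearest_to_pl = nearest,
       nearest_height = unname(min(heights)))
}
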