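# Shared fixture builders. Everything is generated in code; no files on
# disk beyond per-test tempfiles.

# A tiny named descriptor table.
tiny_table <- function(ids = c("BP3", "EHMC", "PABA"),
                       mw = c(228.2, 290.4, 137.1),
                       tpsa = c(46.5, 35.5, 63.3)) {
  descriptor_table(cbind(M_w = mw, TPSA = tpsa),
                   compound_ids = ids)
}

# Write a CSV of raw lines and return its path.
write_lines_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Random descriptor table for property-style loops.
random_table <- function(n = 8, p = 4, seed = 1) {
  set.seed(seed)
  descriptor_table(matrix(rnorm(n * p), n, p,
                          dimnames = list(sprintf("id%02d", seq_len(n)),
                                          paste0("d", seq_len(p)))))
}

# Small train-only dataset with linear truth, for modeling tests.
linear_dataset <- function(n = 30, beta = c(x1 = 2, x2 = -1),
                           noise_sd = 0, seed = 1, n_test = 0) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%03d", seq_len(n)), names(beta)))
  y <- drop(X %*% beta) + 0.5 + rnorm(n, 0, noise_sd)
  tab <- descriptor_table(cbind(X, log_FM = y))
  ids <- rownames(X)
  make_dataset(tab, "log_FM",
               train_ids = ids[seq_len(n - n_test)],
               test_ids = if (n_test > 0) ids[(n - n_test + 1):n]
               else character())
}
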