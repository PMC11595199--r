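#' Specification for a synthetic descriptor table
#'
#' Describes the stated world the generator draws from: descriptor
#' marginals covering the physico-chemical envelope of the reference
#' compounds (lipophilicity roughly -1..6 log units, molecular weight up
#' to ~700 Da, TPSA 0..271 A^2), a linear truth on the log FM scale with
#' Gaussian noise, and optional pairwise descriptor correlation induced
#' by a Gaussian copula.
#'
#' @param n_compounds number of compounds to draw.
#' @param descriptor_specs named list; each element is
#'   `list(dist = "uniform", min =, max =)`,
#'   `list(dist = "uniform_int", min =, max =)` (integer counts) or
#'   `list(dist = "normal", mean =, sd =)`.
#' @param true_model `list(intercept =, coefficients = named numeric,
#'   noise_sd >= 0)`; coefficient names must be generated descriptors.
#' @param correlation optional list of `list(pair = c(name_a, name_b),
#'   r = value)` entries.
#' @param n_train,n_test role split sizes (train first, then test, rest
#'   screen); `n_train = NULL` makes every compound a training compound.
#' @param seed RNG seed; the whole table is reproducible from it.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_compounds,
                           descriptor_specs = default_descriptor_specs(),
                           true_model = default_true_model(),
                           correlation = NULL,
                           n_train = NULL, n_test = 0L, seed = 1L) {
  stopifnot(n_compounds >= 1L, true_model$noise_sd >= 0)
  bad <- setdiff(names(true_model$coefficients),
                 c(names(descriptor_specs), "Lipinski"))
  if (length(bad)) {
    stop("true_model names not among generated descriptors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(n_train)) n_train <- n_compounds - n_test
  stopifnot(n_train >= 1L, n_train + n_test <= n_compounds)
  structure(list(n_compounds = as.integer(n_compounds),
                 descriptor_specs = descriptor_specs,
                 true_model = true_model, correlation = correlation,
                 n_train = as.integer(n_train),
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_descriptor_specs <- function() {
  list(
    M_w = list(dist = "uniform", min = 100, max = 700),
    TPSA = list(dist = "uniform", min = 0, max = 271),
    iLOGP = list(dist = "uniform", min = -1, max = 6),
    MLOGP = list(dist = "normal", mean = 2.5, sd = 1.5),
    HA = list(dist = "uniform_int", min = 0, max = 12),
    HD = list(dist = "uniform_int", min = 0, max = 6)
  )
}

#' @rdname generator_spec
#' @export
default_true_model <- function() {
  # negative size effect, positive polarity effect on log FM, as in the
  # two-descriptor reference model
  list(intercept = 0.14,
       coefficients = c(M_w = -0.0022, TPSA = 0.0040),
       noise_sd = 0.2)
}

# Transform standard-normal draws through a marginal spec.
marginal_transform <- function(z, spec) {
  u <- stats::pnorm(z)
  switch(spec$dist,
         uniform = stats::qunif(u, spec$min, spec$max),
         uniform_int = floor(stats::qunif(u, spec$min, spec$max + 1)),
         normal = spec$mean + spec$sd * z,
         stop("unknown distribution '", spec$dist, "'", call. = FALSE))
}

#' Generate a synthetic dataset from a generator specification
#'
#' Draws every descriptor from its marginal (correlated pairs via a
#' Gaussian copula), derives the binary `Lipinski` descriptor from the
#' drawn M_w/MLOGP/HA/HD through the strict rule-of-five filter (the same
#' code path as [evaluate_filters()], keeping the two modules
#' consistent), and sets
#' `log_FM = intercept + sum(coef * descriptor) + N(0, noise_sd)`.
#'
#' @param spec a [generator_spec()].
#' @return a `perm_dataset` with compound ids `C001`, `C002`, ...
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_compounds
    desc_names <- names(spec$descriptor_specs)
    Z <- matrix(stats::rnorm(n * length(desc_names)), n,
                dimnames = list(NULL, desc_names))
    for (cor_spec in spec$correlation) {
      a <- cor_spec$pair[1L]
      b <- cor_spec$pair[2L]
      r <- cor_spec$r
      stopifnot(all(c(a, b) %in% desc_names), abs(r) <= 1)
      Z[, b] <- r * Z[, a] + sqrt(1 - r^2) * Z[, b]
    }
    values <- vapply(desc_names, function(nm) {
      marginal_transform(Z[, nm], spec$descriptor_specs[[nm]])
    }, numeric(n))
    values <- cbind(values, Lipinski = vapply(seq_len(n), function(i) {
      v <- evaluate_filters(values[i, ])$filters[["lipinski_mordred"]]
      as.numeric(isTRUE(v))
    }, numeric(1)))
    tm <- spec$true_model
    bad <- setdiff(names(tm$coefficients), colnames(values))
    if (length(bad)) {
      stop("true_model names not among generated descriptors: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    signal <- drop(values[, names(tm$coefficients), drop = FALSE] %*%
                     tm$coefficients) + tm$intercept
    log_fm <- signal + stats::rnorm(n, 0, tm$noise_sd)
    ids <- sprintf("C%03d", seq_len(n))
    tab <- descriptor_table(cbind(values, log_FM = log_fm),
                            compound_ids = ids)
    make_dataset(tab, "log_FM",
                 train_ids = ids[seq_len(spec$n_train)],
                 test_ids = if (spec$n_test > 0L)
                   ids[spec$n_train + seq_len(spec$n_test)]
                 else character())
  })
}

#' Generate a reference-like 54-compound dataset
#'
#' Emulates the shape of the experimental reference set: 54 compounds
#' with a 40-train / 14-test split and a log FM truth with a negative
#' molecular-weight coefficient and a positive TPSA coefficient
#' (the two-descriptor reference model), Gaussian noise sd 0.2.
#'
#' @param seed RNG seed.
#' @param noise_sd response noise, default 0.2.
#' @return a `perm_dataset`.
#' @export
generate_reference_like <- function(seed = 1L, noise_sd = 0.2) {
  tm <- default_true_model()
  tm$noise_sd <- noise_sd
  generate_dataset(generator_spec(54L, true_model = tm, n_train = 40L,
                                  n_test = 14L, seed = seed))
}
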