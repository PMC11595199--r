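test_that("kernel similarities follow their closed forms", {
  for (k in c("euclidean", "gaussian", "laplacian")) {
    cfg <- ra_config(kernel = k, sigma = 2, gamma = 3, n_close = 1)
    expect_equal(similarity(c(1, 2), c(1, 2), cfg), 1)
  }
  expect_equal(similarity(c(0, 0), c(2, 0),
                          ra_config("gaussian", sigma = 2)),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(similarity(c(0, 0), c(3, 0),
                          ra_config("laplacian", gamma = 3)),
               exp(-1), tolerance = 1e-12)
  expect_equal(similarity(c(0, 0), c(1, 0), ra_config("euclidean")),
               0.5, tolerance = 1e-12)
  expect_error(similarity(c(1, 2), c(1, 2, 3), ra_config("gaussian")),
               "lengths")
})

test_that("ra_predict interpolates the close-source responses", {
  src <- descriptor_table(cbind(d1 = c(0, 1, 5), d2 = c(0, 1, 5)),
                          compound_ids = c("s1", "s2", "s3"))
  y <- c(s1 = 0, s2 = 1, s3 = 10)
  cfg <- ra_config("gaussian", sigma = 1, n_close = 1)
  pred <- ra_predict(src[1, , drop = FALSE], src, y, cfg)
  expect_equal(as.numeric(pred), 0)  # query == source -> exact response

  # symmetric query between two equally similar sources with y = (0, 1)
  mid <- descriptor_table(cbind(d1 = 0.5, d2 = 0.5), compound_ids = "q")
  cfg2 <- ra_config("gaussian", sigma = 1, n_close = 2)
  pred2 <- ra_predict(mid, src[1:2, ], y[1:2], cfg2)
  expect_equal(as.numeric(pred2), 0.5, tolerance = 1e-12)
})

test_that("ra_predict equals a brute-force weighted mean on 8 compounds", {
  set.seed(8)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("s", 1:8),
                                               c("d1", "d2")))
  y <- rnorm(8)
  q <- matrix(rnorm(2), 1, 2, dimnames = list("q", c("d1", "d2")))
  cfg <- ra_config("laplacian", gamma = 1.5, n_close = 4)
  # independent oracle: manual autoscale, distances, top-4, weighted mean
  mu <- colMeans(X); sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  qs <- (q[1, ] - mu) / sds
  d <- sqrt(colSums((t(Xs) - qs)^2))
  s <- exp(-d / 1.5)
  top <- order(-s, names(d))[1:4]
  oracle <- sum(s[top] * y[top]) / sum(s[top])
  expect_equal(as.numeric(ra_predict(q, X, y, cfg)), oracle,
               tolerance = 1e-12)
})

test_that("similarity ties break to the lexicographically lower id", {
  X <- matrix(c(1, -1, 0, 0), 2, 2,
              dimnames = list(c("zb", "aa"), c("d1", "d2")))
  y <- c(zb = 5, aa = -5)
  q <- matrix(0, 1, 2, dimnames = list("q", c("d1", "d2")))
  cfg <- ra_config("gaussian", sigma = 1, n_close = 1)
  pred <- ra_predict(q, X, y, cfg)
  expect_equal(as.numeric(pred), -5)  # "aa" beats "zb" at equal similarity
})

test_that("ra_predict stays within the close-set response range", {
  set.seed(9)
  for (rep in 1:5) {
    X <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), c("a", "b")))
    y <- rnorm(10)
    q <- matrix(rnorm(2), 1, 2, dimnames = list("q", c("a", "b")))
    cfg <- ra_config("gaussian", sigma = 1, n_close = 5)
    pred <- ra_predict(q, X, y, cfg)
    close <- attr(pred, "close")[["q"]]
    expect_gte(as.numeric(pred), min(close$response))
    expect_lte(as.numeric(pred), max(close$response))
  }
})

test_that("kernel width limits: nearest-neighbour vs unweighted mean", {
  set.seed(10)
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("s", 1:10), c("a", "b")))
  y <- rnorm(10)
  q <- matrix(rnorm(2), 1, 2, dimnames = list("q", c("a", "b")))
  for (k in c("gaussian", "laplacian")) {
    tight <- ra_config(k, sigma = 1e-3, gamma = 1e-3, n_close = 5)
    wide <- ra_config(k, sigma = 1e8, gamma = 1e8, n_close = 5)
    p_tight <- ra_predict(q, X, y, tight)
    close <- attr(p_tight, "close")[["q"]]
    expect_equal(as.numeric(p_tight), close$response[1], tolerance = 1e-6)
    p_wide <- ra_predict(q, X, y, wide)
    expect_equal(as.numeric(p_wide),
                 mean(attr(p_wide, "close")[["q"]]$response),
                 tolerance = 1e-6)
  }
})

test_that("hyperparameter optimization matches an exhaustive loop", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20),
                                                c("a", "b")))
  y <- X[, 1] + rnorm(20, 0, 0.2)
  grid <- default_ra_grid(sigmas = c(0.5, 2), gammas = c(0.5, 2),
                          n_close = c(2, 4))
  res <- optimize_hyperparameters(X, y, grid, seed = 3)

  # oracle: independent exhaustive loop over the same seeded split
  n_sub <- floor(0.75 * 20)
  set.seed(3)
  sub <- sort(sample.int(20, n_sub))
  val <- setdiff(1:20, sub)
  rmse_oracle <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- ra_config(grid$kernel[g],
                     sigma = ifelse(is.na(grid$sigma[g]), 1,
                                    grid$sigma[g]),
                     gamma = ifelse(is.na(grid$gamma[g]), 1,
                                    grid$gamma[g]),
                     n_close = grid$n_close[g])
    pred <- ra_predict(X[val, , drop = FALSE], X[sub, , drop = FALSE],
                       y[sub], cfg)
    sqrt(mean((y[val] - pred)^2))
  }, numeric(1))
  expect_equal(res$report$rmse, rmse_oracle, tolerance = 1e-12)
  expect_equal(res$best_rmse, min(rmse_oracle), tolerance = 1e-12)

  # single-point grid returns that configuration; same seed -> same pick
  single <- grid[5, ]
  res1 <- optimize_hyperparameters(X, y, single, seed = 3)
  expect_equal(res1$best_config$kernel, single$kernel)
  expect_equal(res1$best_config$n_close, single$n_close)
  res_again <- optimize_hyperparameters(X, y, grid, seed = 3)
  expect_identical(res$best_config, res_again$best_config)

  expect_error(optimize_hyperparameters(X, y, grid[0, ]), "empty")
})

test_that("RASAR descriptors encode close-set similarity structure", {
  # 3 sources: s_hi above the split, s_lo1/s_lo2 below
  X <- matrix(c(0, 5, 5.2, 0, 5, 5.2), 3, 2,
              dimnames = list(c("s_hi", "s_lo1", "s_lo2"), c("a", "b")))
  y <- c(s_hi = 2, s_lo1 = -1, s_lo2 = -1.2)
  q <- matrix(c(0.05, 0.05), 1, 2, dimnames = list("q", c("a", "b")))
  cfg <- ra_config("gaussian", sigma = 1, n_close = 1)
  f <- compute_rasar_descriptors(q, X, y, cfg, response_split = 0)
  expect_gt(f$MaxPos, 0)      # the single close source is high-response
  expect_equal(f$MaxNeg, 0)
  expect_equal(f$gm, 1)
  expect_equal(f$SDSim, 0)    # single close compound

  # close set entirely low-response -> MaxPos 0, gm 0
  q2 <- matrix(c(5.1, 5.1), 1, 2, dimnames = list("q2", c("a", "b")))
  cfg2 <- ra_config("gaussian", sigma = 1, n_close = 2)
  f2 <- compute_rasar_descriptors(q2, X, y, cfg2, response_split = 0)
  expect_equal(f2$MaxPos, 0)
  expect_equal(f2$gm, 0)
  expect_equal(f2$RA_function,
               as.numeric(ra_predict(q2, X, y, cfg2)), tolerance = 1e-12)
})

test_that("uniform similarities reduce RA_function to the close-set mean", {
  # equidistant sources under a huge sigma: weights effectively uniform
  X <- matrix(c(1, -1, 0, 0, 0, 1, -1, 0), 4, 2,
              dimnames = list(paste0("s", 1:4), c("a", "b")))
  y <- c(0.2, 0.6, 1.0, -0.4)
  q <- matrix(0, 1, 2, dimnames = list("q", c("a", "b")))
  cfg <- ra_config("gaussian", sigma = 1e8, n_close = 4)
  f <- compute_rasar_descriptors(q, X, y, cfg)
  expect_equal(f$RA_function, mean(y), tolerance = 1e-8)
  expect_equal(f$AvgSim, 1, tolerance = 1e-8)
})

test_that("build_qrasar selects the true descriptors and predicts well", {
  set.seed(77)
  n <- 60
  X <- cbind(u1 = rnorm(n), u2 = rnorm(n), junk1 = rnorm(n),
             junk2 = rnorm(n))
  rownames(X) <- sprintf("c%03d", 1:n)
  y <- 1 + 0.9 * X[, "u1"] - 0.7 * X[, "u2"] + rnorm(n, 0, 0.05)
  tab <- descriptor_table(cbind(X, log_FM = y))
  ds <- make_dataset(tab, "log_FM", rownames(X)[1:45], rownames(X)[46:60])
  cfg <- ra_config("gaussian", sigma = 1, n_close = 5)
  res <- build_qrasar(ds, colnames(X), cfg, max_size = 3)
  expect_true(all(c("u1", "u2") %in% res$selected))
  expect_gt(res$report$q2_f1, 0.9)

  res2 <- build_qrasar(ds, colnames(X), cfg, max_size = 3)
  expect_identical(res$selected, res2$selected)  # deterministic rerun

  expect_error(build_qrasar(ds, colnames(X), cfg, max_size = 1,
                            n_latent = 2), "n_latent")
})

test_that("training RASAR features are computed leave-self-out", {
  # one far-away training compound with an extreme response: if its own
  # row leaked into its source set, RA_function would sit near its own y
  set.seed(78)
  n <- 20
  X <- rbind(matrix(rnorm(2 * (n - 1)), n - 1, 2),
             c(50, 50))  # outlier row, far from the cluster
  colnames(X) <- c("a", "b")
  rownames(X) <- sprintf("c%02d", 1:n)
  y <- c(rnorm(n - 1, 0, 0.2), 25)
  tab <- descriptor_table(cbind(X, log_FM = y))
  ds <- make_dataset(tab, "log_FM", rownames(X))
  cfg <- ra_config("euclidean", n_close = 3)
  res <- build_qrasar(ds, c("a", "b"), cfg, max_size = 2, n_latent = 1)
  ra_self <- res$train_features["c20", "RA_function"]
  expect_lt(abs(ra_self - 0), 5)   # near the cluster responses
  expect_gt(abs(ra_self - 25), 20) # nowhere near its own response
})
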