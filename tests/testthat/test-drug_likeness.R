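# A descriptor row that satisfies every filter.
good_row <- function() {
  c(M_w = 300, TPSA = 80, MLOGP = 2, cLogP = 2.5, XLOGP = 2, WLOGP = 2,
    MR = 80, HA = 5, HD = 2, FRB = 4, Atoms = 30, Rings = 2,
    Carbons = 15, Heteroatoms = 4)
}

test_that("filters apply their printed thresholds", {
  v <- evaluate_filters(good_row())
  expect_true(all(v$filters))
  expect_equal(v$lipinski_violations, 0L)

  r <- good_row(); r["M_w"] <- 450; r["MLOGP"] <- 3; r["HA"] <- 8
  r["HD"] <- 2
  expect_true(evaluate_filters(r)$filters[["lipinski_mordred"]])

  r <- good_row(); r["TPSA"] <- 150
  v <- evaluate_filters(r)
  expect_false(v$filters[["veber"]])
  expect_false(v$filters[["palm"]])
  expect_false(v$filters[["egan"]])

  r <- good_row(); r["M_w"] <- 150
  v <- evaluate_filters(r)
  expect_false(v$filters[["muegge"]])
  expect_false(v$filters[["ghose_mordred"]])  # below 160 as well
})

test_that("Egan's WLOGP bound is exclusive, others inclusive", {
  r <- good_row(); r["WLOGP"] <- 5.88
  expect_false(evaluate_filters(r)$filters[["egan"]])
  r["WLOGP"] <- 5.879
  expect_true(evaluate_filters(r)$filters[["egan"]])
  # inclusive examples at the boundary
  r <- good_row(); r["M_w"] <- 500; r["TPSA"] <- 140
  v <- evaluate_filters(r)
  expect_true(v$filters[["lipinski_mordred"]])
  expect_true(v$filters[["veber"]])
  expect_true(v$filters[["palm"]])
})

test_that("allow_one tolerance applies to the SwissADME variants only", {
  r <- good_row(); r["cLogP"] <- 6  # one Swiss-Lipinski violation
  strict <- evaluate_filters(r, "strict")
  loose <- evaluate_filters(r, "allow_one")
  expect_false(strict$filters[["lipinski_swiss"]])
  expect_true(loose$filters[["lipinski_swiss"]])
  expect_true(strict$filters[["lipinski_mordred"]])  # MLOGP fine

  r2 <- good_row(); r2["MR"] <- 135  # one Ghose violation
  expect_false(evaluate_filters(r2, "strict")$filters[["ghose_swiss"]])
  expect_true(evaluate_filters(r2, "allow_one")$filters[["ghose_swiss"]])
  expect_false(evaluate_filters(r2,
                                "allow_one")$filters[["ghose_mordred"]])
})

test_that("missing descriptors make a filter not-evaluable, not failed", {
  r <- good_row()
  r <- r[setdiff(names(r), "XLOGP")]
  v <- evaluate_filters(r)
  expect_true(is.na(v$filters[["muegge"]]))
  expect_true(v$filters[["lipinski_mordred"]])
})

test_that("TPSA-gated filters are threshold-monotone", {
  set.seed(90)
  for (rep in 1:10) {
    r <- good_row()
    r["TPSA"] <- runif(1, 0, 271)
    r["WLOGP"] <- runif(1, -1, 7)
    low <- evaluate_filters(r)$filters
    r2 <- r
    r2["TPSA"] <- r["TPSA"] + runif(1, 0, 150)
    high <- evaluate_filters(r2)$filters
    for (f in c("veber", "palm", "egan")) {
      # increasing TPSA can only switch pass -> fail
      expect_false(isFALSE(low[[f]]) && isTRUE(high[[f]]))
    }
  }
})

test_that("permeability_filter_matrix assembles binary columns", {
  set.seed(91)
  rows <- do.call(rbind, lapply(1:5, function(i) {
    r <- good_row()
    r["TPSA"] <- runif(1, 50, 200)
    r
  }))
  rownames(rows) <- paste0("c", 1:5)
  verdicts <- evaluate_filters_table(rows)
  pl <- c("PL1", "PL0", "PL1", "PL1", "PL0")
  m <- permeability_filter_matrix(verdicts, pl)
  expect_equal(dim(m), c(5L, 9L))
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(unname(m[, "PL"]), c(1L, 0L, 1L, 1L, 0L))

  # drop a required column -> that filter excluded with a warning
  rows2 <- rows[, setdiff(colnames(rows), "XLOGP")]
  verdicts2 <- evaluate_filters_table(rows2)
  expect_warning(m2 <- permeability_filter_matrix(verdicts2, pl),
                 "muegge")
  expect_equal(ncol(m2), 8L)

  expect_error(permeability_filter_matrix(verdicts[0, ], character()),
               "empty")
  expect_error(permeability_filter_matrix(verdicts, pl[1:3]), "lengths")
})

test_that("clustering merges identical columns first, complements last", {
  m <- cbind(f1 = c(1, 0, 1, 0, 1), f2 = c(1, 0, 1, 0, 1),
             f3 = c(0, 1, 1, 0, 0), PL = c(1, 0, 1, 0, 1))
  res <- cluster_filter_profiles(m)
  expect_equal(res$nearest_to_pl, "f1")
  expect_equal(res$nearest_height, 0)

  comp <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1),
                PL = c(1, 0, 1, 0))
  res2 <- cluster_filter_profiles(comp, distance = "matching")
  merged_last <- res2$hclust$merge[nrow(res2$hclust$merge), ]
  heights <- res2$hclust$height
  # the complementary pair a/b attains the maximal merge height
  expect_equal(max(heights), 1)
})

test_that("a PL-consistent filter is PL's nearest neighbour throughout", {
  # PL derived from the strict Lipinski rule itself: the corresponding
  # filter column must join PL first for every linkage x distance combo
  set.seed(92)
  rows <- do.call(rbind, lapply(1:20, function(i) {
    r <- good_row()
    r["M_w"] <- runif(1, 300, 700)
    r["TPSA"] <- runif(1, 20, 200)
    r
  }))
  rownames(rows) <- sprintf("c%02d", 1:20)
  verdicts <- evaluate_filters_table(rows)
  pl <- ifelse(verdicts$lipinski_mordred, "PL1", "PL0")
  m <- permeability_filter_matrix(verdicts, pl)
  for (linkage in c("single", "complete", "average")) {
    for (distance in c("jaccard", "matching")) {
      res <- cluster_filter_profiles(m, linkage, distance)
      expect_equal(res$nearest_to_pl, "lipinski_mordred")
      expect_equal(res$nearest_height, 0)
    }
  }
})
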