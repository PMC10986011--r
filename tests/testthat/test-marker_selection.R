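## Build a metric_matrix shell around explicit value/coverage matrices so
## filter/screen mechanics can be tested on exact numbers.
mm_shell <- function(values, coverage) {
  blocks <- unique(sub(":.*", "", colnames(values)))
  structure(list(values = values, coverage = coverage,
                 samples = rownames(values), block_ids = blocks,
                 metrics = unique(sub(".*:", "", colnames(values))),
                 params = list()),
            class = "metric_matrix")
}

test_that("coverage filter applies the >=10X, <500X, >=80% rule inclusively", {
  cov <- cbind(B1 = c(rep(12, 8), 5, 5),        # 0.8 in window -> retained
               B2 = c(rep(600, 3), rep(12, 7)), # 0.7 -> dropped
               B3 = rep(10, 10),                # boundary 10X counts
               B4 = rep(500, 10))               # 500X is outside (strict <)
  rownames(cov) <- sprintf("S%02d", 1:10)
  vals <- matrix(0.5, 10, 4, dimnames = list(rownames(cov),
                                             paste0("B", 1:4, ":AMF")))
  mm <- mm_shell(vals, cov)
  expect_equal(filter_blocks_by_coverage(mm), c("B1", "B3"))
  expect_equal(filter_blocks_by_coverage(mm, min_frac = 0),
               c("B1", "B2", "B3", "B4"))
  ## tightening the window never adds blocks
  expect_true(all(filter_blocks_by_coverage(mm, min_cov = 12) %in%
                    filter_blocks_by_coverage(mm)))
})

test_that("Mann-Whitney wrapper: exact small-sample p, symmetry, ties", {
  mt <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mt$p, 0.1, tolerance = 1e-12)
  expect_equal(mt$p, mw_exact_p_enum(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(mt$U, 0)

  ## two-sided symmetry under group swap
  set.seed(2)
  x <- rnorm(12); y <- rnorm(15)
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(y, x)$p, tolerance = 1e-12)

  ## complete ties are a defined, non-significant result
  mt <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_true(mt$defined)
  expect_equal(mt$p, 1)

  ## a fully missing group is flagged undefined
  expect_false(mann_whitney_u(c(NA_real_, NA), c(1, 2))$defined)
})

test_that("the screen keeps the lowest-p metric per block and respects alpha", {
  set.seed(4)
  n <- 40
  ids <- sprintf("S%03d", 1:n)
  lab <- setNames(rep(c("BTN", "MTN"), each = n / 2), ids)
  shift <- ifelse(lab == "MTN", 0.3, 0)
  mk <- function(base) pmin(1, pmax(0, base))
  vals <- cbind(
    "B1:AMF" = mk(rnorm(n, 0.4, 0.05) + shift),  # strongly differential
    "B1:PDR" = mk(rnorm(n, 0.5, 0.05) + shift / 3),
    "B2:AMF" = mk(rnorm(n, 0.5, 0.05)),          # null
    "B2:PDR" = mk(rnorm(n, 0.5, 0.05)))
  rownames(vals) <- ids
  cov <- matrix(30, n, 2, dimnames = list(ids, c("B1", "B2")))
  mm <- mm_shell(vals, cov)
  mm$metrics <- c("AMF", "PDR")

  sc <- screen_markers(mm, lab, alpha = 0.001)
  expect_equal(sc$block_id, "B1")
  expect_equal(sc$metric, "AMF")
  expect_equal(sc$direction, 1)
  ## determinism, including tie-breaks
  expect_identical(sc, screen_markers(mm, lab, alpha = 0.001))
  ## alpha = 1 emits every block with a defined test
  expect_equal(nrow(screen_markers(mm, lab, alpha = 1.0000001)), 2L)
  ## lowering alpha never adds markers
  expect_true(all(screen_markers(mm, lab, alpha = 1e-6)$block_id %in% sc$block_id))
})

test_that("KNN imputation: identity, nearest-duplicate forcing, beats column means", {
  x <- matrix(rnorm(50), 10, 5,
              dimnames = list(sprintf("S%02d", 1:10), paste0("m", 1:5)))
  out <- impute_missing_knn(x, k = 5)
  expect_identical(out$completed, x)

  ## an exact duplicate row forces the imputed value at k = 1
  xd <- x
  xd["S02", ] <- xd["S01", ]
  xd["S02", 3] <- NA
  out <- impute_missing_knn(xd, k = 1)
  expect_equal(out$completed["S02", 3], xd["S01", 3])

  ## random masking: KNN RMSE below column-mean-imputation RMSE
  set.seed(66)
  n <- 60; p <- 8
  base <- matrix(rnorm(n), n, 1)[, rep(1, p)] + matrix(rnorm(n * p, sd = 0.3), n, p)
  dimnames(base) <- list(sprintf("S%03d", 1:n), paste0("m", 1:p))
  mask <- matrix(runif(n * p) < 0.1, n, p)
  xm <- base; xm[mask] <- NA
  knn <- impute_missing_knn(xm, k = 5)$completed
  cm <- xm
  for (j in 1:p) cm[is.na(cm[, j]), j] <- mean(xm[, j], na.rm = TRUE)
  rmse <- function(a) sqrt(mean((a[mask] - base[mask])^2))
  expect_lt(rmse(knn), rmse(cm))

  ## all-missing column is a named error
  xa <- x; xa[, 2] <- NA
  expect_error(impute_missing_knn(xa), "m2")

  ## apply mode: a held-out sample imputed one at a time against the
  ## fitted reference equals imputing it against those rows directly
  state <- impute_missing_knn(xm, k = 5)$state
  newx <- base[1:2, , drop = FALSE] + 0.01
  rownames(newx) <- c("N1", "N2")
  newx[1, 4] <- NA; newx[2, 7] <- NA
  both <- impute_missing_knn(newx, reference = state)$completed
  one <- rbind(
    impute_missing_knn(newx[1, , drop = FALSE], reference = state)$completed,
    impute_missing_knn(newx[2, , drop = FALSE], reference = state)$completed)
  expect_equal(both, one)
})

test_that("RFECV recovers planted informative features and is reproducible", {
  set.seed(8)
  pf <- planted_features(n_per_group = 60, p = 20, n_inf = 2, delta = 2)
  ms <- rfecv_select(pf$x, pf$labels, folds = 10, seed = 42, ntree = 200)
  expect_true(all(c("f01", "f02") %in% ms$markers))
  ms2 <- rfecv_select(pf$x, pf$labels, folds = 10, seed = 42, ntree = 200)
  expect_identical(ms$markers, ms2$markers)
  expect_identical(ms$cv, ms2$cv)
  ## per-size CV log covers every visited size down to 1
  expect_equal(sort(ms$cv$size), 1:20)
})

test_that("RFECV on shuffled labels scores near chance", {
  set.seed(13)
  pf <- planted_features(n_per_group = 40, p = 8, n_inf = 0, delta = 0)
  lab <- setNames(sample(pf$labels), names(pf$labels))
  ms <- rfecv_select(pf$x, lab, folds = 5, step = 2, seed = 9, ntree = 200)
  ## the full-feature CV AUC (no selection bias) sits within 0.5 +/- 3 SE,
  ## using the theoretical null SE of the rank AUC on one fold
  full <- ms$cv[ms$cv$size == 8, ]
  se_fold <- sqrt((8 + 8 + 1) / (12 * 8 * 8))  # ~16 held out, 8 per class
  expect_lt(abs(full$mean_score - 0.5), 3 * se_fold / sqrt(5))
})

test_that("RFECV rejects degenerate inputs", {
  pf <- planted_features(20, 5, 1, 1)
  one <- setNames(rep("BTN", 40), rownames(pf$x))
  expect_error(rfecv_select(pf$x, one, seed = 1), "both classes")
  expect_error(rfecv_select(pf$x, pf$labels, folds = 25, seed = 1),
               "per class")
})
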