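test_that("z-score standardization uses the population-SD convention", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "m1"))
  zs <- standardize(x)
  expect_equal(unname(zs$z[, 1]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(zs$state$convention, "population_sd")
  ## apply mode on the training matrix reproduces fit-mode output
  expect_equal(standardize(x, fitted = zs$state)$z, zs$z)
  ## constant column is an error naming the marker
  xc <- cbind(x, m2 = c(4, 4, 4))
  expect_error(standardize(xc), "m2")
})

test_that("forest training is seeded-deterministic and separates a toy set", {
  set.seed(1)
  pf <- planted_features(n_per_group = 25, p = 2, n_inf = 2, delta = 6)
  fit <- train_forest(pf$x, pf$labels, cv_folds = 5, seed = 3, ntree = 200)
  pr <- predict(fit, as.data.frame(pf$x), type = "prob")[, "MTN"]
  expect_equal(roc_auc(pr, pf$labels)$auc, 1.0)
  fit2 <- train_forest(pf$x, pf$labels, cv_folds = 5, seed = 3, ntree = 200)
  pr2 <- predict(fit2, as.data.frame(pf$x), type = "prob")[, "MTN"]
  expect_identical(pr, pr2)
  expect_error(train_forest(pf$x, pf$labels, cv_folds = 30, seed = 1),
               "cv_folds")
})

test_that("Youden threshold matches the exhaustive-scan oracle", {
  ## clean separation: any t in (0.2, 0.8] is optimal; midpoint returned
  s <- c(A = 0.9, B = 0.8, C = 0.1, D = 0.2)
  lab <- c(A = "MTN", B = "MTN", C = "BTN", D = "BTN")
  t <- youden_optimal_threshold(s, lab)
  expect_equal(as.numeric(t), 0.5)
  expect_equal(attr(t, "J"), 1)

  ## identical distributions give J = 0
  s2 <- c(0.3, 0.7, 0.3, 0.7)
  names(s2) <- letters[1:4]
  lab2 <- setNames(c("MTN", "MTN", "BTN", "BTN"), letters[1:4])
  expect_equal(attr(youden_optimal_threshold(s2, lab2), "J"), 0)

  set.seed(55)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    sc <- round(runif(n), sample(1:3, 1))  # ties on purpose
    lb <- sample(c("MTN", "BTN"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    t <- youden_optimal_threshold(sc, lb)
    expect_equal(attr(t, "J"), youden_scan_oracle(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC matches pairwise brute force and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("MTN", "MTN", "BTN", "BTN"))$auc, 1.0)
  set.seed(70)
  for (i in 1:200) {
    n <- sample(4:15, 1)
    sc <- round(runif(n), 2)
    lb <- sample(c("MTN", "BTN"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_bruteforce(sc, lb), tolerance = 1e-12)
    ## strictly monotone transform leaves AUC unchanged
    expect_equal(roc_auc(sc^3 + 2 * sc, lb)$auc,
                 roc_auc(sc, lb)$auc, tolerance = 1e-12)
  }
  ## large-sample null
  set.seed(71)
  sc <- runif(2000); lb <- sample(c("MTN", "BTN"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.05)
  expect_error(roc_auc(c(1, 2), c("MTN", "MTN")), "both classes")
})

test_that("AUC agrees with pROC and the bootstrap CI brackets the estimate", {
  skip_if_not_installed("pROC")
  set.seed(81)
  sc <- runif(60)
  lb <- ifelse(runif(60) < plogis(4 * (sc - 0.5)), "MTN", "BTN")
  if (length(unique(lb)) == 2) {
    ref <- as.numeric(suppressMessages(pROC::auc(lb == "MTN", sc)))
    got <- roc_auc(sc, lb, ci = TRUE, seed = 4)
    expect_equal(got$auc, ref, tolerance = 1e-12)
    expect_true(got$ci_lo <= got$auc && got$auc <= got$ci_hi)
  }
})

test_that("confusion metrics reproduce the reference two-cohort arithmetic", {
  m <- confusion_metrics(list(tp = 35, fn = 7, tn = 50, fp = 5))
  expect_equal(round(as.vector(m), 2),
               c(83.33, 90.91, 87.50, 87.72, 87.63))
  m <- confusion_metrics(list(tp = 29, fn = 6, tn = 47, fp = 6))
  expect_equal(round(as.vector(m), 2),
               c(82.86, 88.68, 82.86, 88.68, 86.36))
  ## perfect classifier
  m <- confusion_metrics(list(tp = 10, fn = 0, tn = 0, fp = 0))
  expect_equal(unname(m[c("sensitivity", "ppv", "accuracy")]), c(100, 100, 100))
  expect_true(all(c("specificity", "npv") %in% attr(m, "undefined")))
})

test_that("confusion identities hold for random non-negative counts", {
  set.seed(90)
  for (i in 1:50) {
    cc <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                           c("tp", "fp", "tn", "fn")))
    if (sum(unlist(cc)) == 0) next
    m <- confusion_metrics(cc)
    with(cc, {
      if (tp + fn > 0) expect_equal(unname(m["sensitivity"]), 100 * tp / (tp + fn))
      if (tn + fp > 0) expect_equal(unname(m["specificity"]), 100 * tn / (tn + fp))
      if (tp + fp > 0) expect_equal(unname(m["ppv"]), 100 * tp / (tp + fp))
      if (tn + fn > 0) expect_equal(unname(m["npv"]), 100 * tn / (tn + fn))
      expect_equal(unname(m["accuracy"]), 100 * (tp + tn) / sum(unlist(cc)))
    })
  }
})

test_that("sample-size formula matches its closed form", {
  expect_equal(minimum_sample_size(0.90, 0.1, 0.95), 35L)
  expect_equal(minimum_sample_size(0.5, 0.5, 0.95), 4L)
  expect_equal(minimum_sample_size(1.0, 0.1, 0.95), 0L)
  expect_equal(minimum_sample_size(0, 0.1, 0.95), 0L)
  expect_error(minimum_sample_size(0.9, 0), "d must be")
})

test_that("ultrasonography comparator binarizes at TI-RADS >= 4", {
  meta <- data.frame(sample_id = paste0("S", 1:4), tirads = c(5L, 3L, 4L, NA))
  expect_warning(us <- ultrasound_comparator(meta), "missing TI-RADS")
  expect_equal(us, c(S1 = TRUE, S2 = FALSE, S3 = TRUE))
  expect_warning(expect_length(
    ultrasound_comparator(data.frame(sample_id = "S1", tirads = NA_integer_)), 0))
})

test_that("subgroup report stratifies, aggregates, and flags empty strata", {
  ## suspicious-but-benign patients: TR4 20 (19 correct) + TR5 11 (10) +
  ## TR4 17 (15) + TR5 11 (9); specificity of the pooled stratum = 53/59
  n <- c(20, 11, 17, 11); correct <- c(19, 10, 15, 9)
  meta <- data.frame(
    sample_id = sprintf("P%02d", 1:59),
    label = "BTN",
    tirads = rep(rep(c(4L, 5L, 4L, 5L), n), 1)[1:59],
    size_mm = 12)
  meta$tirads <- rep(c(4L, 5L, 4L, 5L), n)
  calls <- setNames(unlist(mapply(function(nn, cc) c(rep(FALSE, cc), rep(TRUE, nn - cc)),
                                  n, correct, SIMPLIFY = FALSE)), meta$sample_id)
  scores <- setNames(ifelse(calls, 0.9, 0.1), meta$sample_id)
  rep <- subgroup_report(scores, calls, meta)
  r4 <- rep[rep$stratum == "tirads>=4", ]
  expect_equal(r4$n, 59L)
  expect_equal(round(r4$specificity, 2), 89.83)
  ## all-benign stratum: sensitivity undefined, AUC undefined
  expect_true(is.na(r4$sensitivity) && is.na(r4$auc))
  ## micronodule + non-micronodule partition the cohort when sizes complete
  expect_equal(rep$n[rep$stratum == "size<=10mm"] +
                 rep$n[rep$stratum == "size>10mm"], 59L)
  expect_equal(rep$n[rep$stratum == "size<=10mm"], 0L)
})
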