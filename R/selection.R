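## Marker selection funnel: coverage filter -> per-block best-metric
## Mann-Whitney screen -> KNN imputation -> recursive feature elimination
## with cross-validation.

#' Retain blocks by per-sample coverage
#'
#' A block is retained iff the fraction of samples whose mean per-CpG
#' depth satisfies `min_cov <= coverage < max_cov` is at least `min_frac`
#' (both boundary conventions follow the usual ">= 10X and < 500X in
#' >= 80% of samples" filter).
#'
#' @param mm a `metric_matrix`.
#' @param min_cov,max_cov depth window in X (lower inclusive, upper
#'   exclusive).
#' @param min_frac minimum fraction of samples inside the window
#'   (inclusive).
#' @param samples optional sample ids to evaluate the fractions on
#'   (default: all rows).
#' @return Character vector of retained block ids.
#' @export
filter_blocks_by_coverage <- function(mm, min_cov = 10, max_cov = 500,
                                      min_frac = 0.8, samples = NULL) {
  cv <- mm$coverage
  if (!is.null(samples)) cv <- cv[samples, , drop = FALSE]
  if (!nrow(cv)) return(character(0))
  frac <- colMeans(cv >= min_cov & cv < max_cov)
  colnames(cv)[frac >= min_frac]
}

#' Mann-Whitney U test between two groups
#'
#' Thin wrapper over [stats::wilcox.test()] with a fixed exactness rule:
#' the exact null distribution when both groups have at most 8 non-missing
#' values and no ties are present; otherwise the tie-corrected normal
#' approximation with continuity correction. Missing values are dropped.
#' When all pooled values are identical the normal approximation is
#' degenerate (zero variance) and p = 1 is returned.
#'
#' @param x,y numeric vectors (group values; `NA` ignored).
#' @param alternative passed to `wilcox.test` (default two-sided).
#' @return List with `U` (statistic for `x` vs `y`), `p`, `defined`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    return(list(U = NA_real_, p = NA_real_, defined = FALSE))
  }
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1, defined = TRUE))
  }
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  p <- min(1, wt$p.value)
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p = p, defined = TRUE)
}

#' Screen blocks for differential methylation
#'
#' For each block, all six measurements are tested between the two label
#' groups with the Mann-Whitney U test; the measurement with the smallest
#' p-value is chosen (ties broken by the fixed precedence AMF, MHL, UMHL,
#' MHL3, UMHL3, PDR), and blocks whose chosen p is strictly below `alpha`
#' pass the screen. Values are used as observed (pairwise deletion);
#' imputation happens after screening.
#'
#' @param mm a `metric_matrix`.
#' @param labels named character/factor vector (`BTN`/`MTN`) with names
#'   matching rows of `mm$values`, or unnamed in row order.
#' @param alpha screening threshold (strictly-less comparison).
#' @param blocks block ids to screen (e.g. the coverage-retained set);
#'   default all.
#' @return A data.frame of passing markers: `block_id`, `metric`, `U`,
#'   `p`, `direction` (sign of the MTN - BTN median shift). The full
#'   per-block results table (pass or fail) is in the `"all_results"`
#'   attribute.
#' @export
screen_markers <- function(mm, labels, alpha = 0.001, blocks = NULL) {
  v <- mm$values
  lab <- align_labels(labels, rownames(v))
  if (is.null(blocks)) blocks <- mm$block_ids
  res <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    best <- NULL
    for (metric in mm$metrics) {
      col <- v[, paste(b, metric, sep = ":")]
      mt <- mann_whitney_u(col[lab == "MTN"], col[lab == "BTN"])
      if (!mt$defined) next
      if (is.null(best) || mt$p < best$p) {
        dirn <- sign(median(col[lab == "MTN"], na.rm = TRUE) -
                       median(col[lab == "BTN"], na.rm = TRUE))
        best <- list(block_id = b, metric = metric, U = mt$U, p = mt$p,
                     direction = dirn)
      }
    }
    if (!is.null(best)) res[[bi]] <- as.data.frame(best)
  }
  all_res <- do.call(rbind, res)
  if (is.null(all_res)) {
    all_res <- data.frame(block_id = character(0), metric = character(0),
                          U = numeric(0), p = numeric(0),
                          direction = numeric(0))
  }
  pass <- all_res[all_res$p < alpha, , drop = FALSE]
  rownames(pass) <- NULL
  attr(pass, "all_results") <- all_res
  attr(pass, "alpha") <- alpha
  pass
}

align_labels <- function(labels, ids) {
  nm <- names(labels)
  labels <- as.character(labels)
  if (!is.null(nm) && !is.null(ids)) {
    labels <- setNames(labels, nm)[ids]
  } else if (!is.null(ids) && length(labels) != length(ids)) {
    stop("labels must be named by sample_id or match the row count")
  }
  bad <- !is.na(labels) & !labels %in% c("BTN", "MTN")
  if (any(bad)) stop("labels must be BTN or MTN")
  labels
}

#' K-nearest-neighbour imputation with masked Euclidean distances
#'
#' Each missing cell is replaced by the mean of that column over the `k`
#' reference rows nearest to the incomplete row, where distance is the
#' Euclidean distance over co-observed columns rescaled by
#' `sqrt(p / n_shared)` (so rows sharing few columns are not
#' spuriously close). In fit mode the matrix is its own reference (a row
#' never donates to itself); in apply mode each row is imputed one at a
#' time against the fitted reference — i.e. a new sample is combined with
#' all reference samples and completed from them.
#'
#' @param x numeric matrix with `NA` for missing values.
#' @param k number of donor neighbours (default 5). Fewer donors than `k`
#'   fall back to all available; a column with donors in no row falls back
#'   to the reference column mean.
#' @param reference a fitted state from a previous call, or `NULL` to fit
#'   on `x`.
#' @return List with `completed` (matrix) and `state` (reference matrix +
#'   `k`), reusable for held-out samples.
#' @export
impute_missing_knn <- function(x, k = 5, reference = NULL) {
  x <- as.matrix(x)
  fit_mode <- is.null(reference)
  ref <- if (fit_mode) x else reference$reference
  if (!identical(colnames(ref), colnames(x))) {
    stop("column sets of x and reference must match")
  }
  all_missing <- colSums(!is.na(ref)) == 0L
  if (any(all_missing)) {
    stop("column(s) with no observed reference value: ",
         paste(colnames(ref)[all_missing], collapse = ", "))
  }
  col_means <- colMeans(ref, na.rm = TRUE)
  p <- ncol(x)
  obs_ref <- !is.na(ref)

  completed <- x
  for (i in which(rowSums(is.na(x)) > 0L)) {
    xi <- x[i, ]
    oi <- !is.na(xi)
    ## masked euclidean distance to every reference row
    d2 <- rep(Inf, nrow(ref))
    for (r in seq_len(nrow(ref))) {
      if (fit_mode && r == i) next
      sh <- oi & obs_ref[r, ]
      ns <- sum(sh)
      if (ns == 0L) next
      d2[r] <- (p / ns) * sum((xi[sh] - ref[r, sh])^2)
    }
    ord <- order(d2)
    for (j in which(!oi)) {
      donors <- ord[is.finite(d2[ord]) & obs_ref[ord, j]]
      completed[i, j] <- if (length(donors)) {
        mean(ref[donors[seq_len(min(k, length(donors)))], j])
      } else {
        col_means[j]
      }
    }
  }
  list(completed = completed,
       state = list(reference = ref, k = k))
}

## Stratified k-fold assignment (each fold holds both classes whenever
## class counts allow).
make_stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

rf_fit <- function(x, y, ntree = 500, mtry = NULL, nodesize = 1) {
  y <- factor(y, levels = c("BTN", "MTN"))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n_min <- min(table(y))
  randomForest::randomForest(
    x = as.data.frame(x), y = y, ntree = ntree, mtry = min(mtry, ncol(x)),
    nodesize = nodesize, strata = y, sampsize = rep(n_min, 2L))
}

rf_prob <- function(fit, x) {
  unname(predict(fit, as.data.frame(x), type = "prob")[, "MTN"])
}

## Mean cross-validated score of a random forest on a fixed feature set.
cv_score <- function(x, labels, folds, ntree, mtry, metric = c("auc", "accuracy")) {
  metric <- match.arg(metric)
  scores <- numeric(max(folds))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    fit <- rf_fit(x[tr, , drop = FALSE], labels[tr], ntree = ntree, mtry = mtry)
    pr <- rf_prob(fit, x[te, , drop = FALSE])
    scores[f] <- if (metric == "auc") {
      roc_auc(pr, labels[te])$auc
    } else {
      mean((pr >= 0.5) == (labels[te] == "MTN"))
    }
  }
  scores
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Starting from all features, the current set is scored by stratified
#' k-fold cross-validation of a random forest, the least important
#' features (Gini importance of a forest fit on all rows) are dropped
#' `step` at a time, and the process repeats down to a single feature.
#' The retained set is the one maximizing the mean CV score, ties going to
#' the smaller set. Fully reproducible given `seed`.
#'
#' @param x numeric feature matrix (samples x markers, complete).
#' @param labels `BTN`/`MTN` labels (named or in row order).
#' @param folds number of CV folds (default 10).
#' @param step features eliminated per iteration (default 1).
#' @param seed integer seed.
#' @param ntree forest size (default 500).
#' @param metric CV score: `"auc"` (default) or `"accuracy"`.
#' @return A `marker_set`: list with `markers` (retained column names in
#'   elimination-survival order), `cv` (per-size mean/sd score log),
#'   `seed`, `metric`.
#' @export
rfecv_select <- function(x, labels, folds = 10, step = 1, seed = 1,
                         ntree = 500, metric = "auc") {
  x <- as.matrix(x)
  labels <- align_labels(labels, rownames(x))
  if (length(unique(labels)) < 2L) stop("both classes required for RFECV")
  if (min(table(labels)) < folds) {
    stop("need at least `folds` samples per class")
  }
  if (anyNA(x)) stop("x must be complete (impute first)")

  set.seed(seed)
  fold <- make_stratified_folds(labels, folds)
  current <- colnames(x)
  log_rows <- list()
  sets <- list()
  while (length(current) >= 1L) {
    sc <- cv_score(x[, current, drop = FALSE], labels, fold, ntree,
                   mtry = max(1L, floor(sqrt(length(current)))), metric = metric)
    sets[[length(sets) + 1L]] <- current
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(size = length(current), mean_score = mean(sc), sd_score = sd(sc))
    if (length(current) == 1L) break
    fit <- rf_fit(x[, current, drop = FALSE], labels, ntree = ntree)
    imp <- fit$importance[, "MeanDecreaseGini"]
    drop_n <- min(step, length(current) - 1L)
    current <- current[order(-imp)][seq_len(length(current) - drop_n)]
  }
  cv <- do.call(rbind, log_rows)
  best <- max(cv$mean_score)
  pick <- which(cv$mean_score == best)
  pick <- pick[which.min(cv$size[pick])]
  structure(list(markers = sets[[pick]], cv = cv, seed = seed,
                 metric = metric),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers (CV %s %.3f at size %d)\n",
              length(x$markers), x$metric,
              max(x$cv$mean_score), length(x$markers)))
  invisible(x)
}
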