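## Diagnostic model: z-score standardization, random-forest training with
## hyperparameter selection by cross-validation, Youden-derived decision
## threshold, and the frozen model bundle used to score new samples.

#' Z-score standardization with frozen parameters
#'
#' Fit mode computes per-column location (mean) and scale (population
#' standard deviation, i.e. the 1/n convention) on the training matrix;
#' apply mode reuses a previous fit. Fitted columns have mean 0 and
#' population SD 1 in fit mode.
#'
#' @param x numeric matrix (complete).
#' @param fitted optional fitted state from a previous call.
#' @return List with `z` (standardized matrix) and `state`
#'   (`center`, `scale`, convention tag).
#' @export
standardize <- function(x, fitted = NULL) {
  x <- as.matrix(x)
  if (is.null(fitted)) {
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2, center)^2))
    zero <- scale <= .Machine$double.eps
    if (any(zero)) stop("zero-variance marker(s): ",
                        paste(colnames(x)[zero], collapse = ", "))
    fitted <- list(center = center, scale = scale, convention = "population_sd")
  } else {
    if (!identical(names(fitted$center), colnames(x))) {
      stop("column mismatch between x and fitted standardization")
    }
  }
  z <- sweep(sweep(x, 2, fitted$center), 2, fitted$scale, "/")
  list(z = z, state = fitted)
}

#' Train the random-forest classifier with CV-chosen hyperparameters
#'
#' Evaluates each grid point by stratified `cv_folds`-fold
#' cross-validation (AUC), picks the best (ties go to the first grid row
#' in declared order), and refits on the full training set. Class
#' imbalance is handled by balanced per-class bootstrap sampling.
#'
#' @param x numeric feature matrix (complete, standardized).
#' @param labels `BTN`/`MTN` labels.
#' @param cv_folds folds for hyperparameter selection (default 10).
#' @param grid data.frame of candidates with columns `mtry` and
#'   `nodesize`; default tries `mtry = sqrt(p)` and `p/3` at nodesize 1.
#' @param seed integer seed.
#' @param ntree trees per forest (default 500).
#' @return The fitted `randomForest` with attributes `cv` (grid log) and
#'   `chosen` (selected row).
#' @export
train_forest <- function(x, labels, cv_folds = 10, grid = NULL, seed = 1,
                         ntree = 500) {
  x <- as.matrix(x)
  labels <- align_labels(labels, rownames(x))
  if (length(unique(labels)) < 2L) stop("both classes required")
  if (min(table(labels)) < cv_folds) stop("need at least `cv_folds` samples per class")
  p <- ncol(x)
  if (is.null(grid)) {
    grid <- unique(data.frame(mtry = c(max(1L, floor(sqrt(p))),
                                       max(1L, floor(p / 3))),
                              nodesize = 1L))
  }
  set.seed(seed)
  fold <- make_stratified_folds(labels, cv_folds)
  grid$cv_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    set.seed(seed + g)
    grid$cv_auc[g] <- mean(cv_score(x, labels, fold, ntree,
                                    mtry = grid$mtry[g], metric = "auc"))
  }
  best <- which.max(grid$cv_auc)  # ties -> first in declared order
  set.seed(seed)
  fit <- rf_fit(x, labels, ntree = ntree, mtry = grid$mtry[best],
                nodesize = grid$nodesize[best])
  attr(fit, "cv") <- grid
  attr(fit, "chosen") <- grid[best, , drop = FALSE]
  fit
}

#' Youden-optimal decision threshold
#'
#' Maximizes J(t) = sensitivity(t) + specificity(t) - 1 under the call
#' rule `score >= t` is positive (MTN). Candidate thresholds are the
#' midpoints of adjacent distinct scores plus the two boundary candidates
#' (everything positive / everything negative); ties are broken toward the
#' smallest threshold.
#'
#' @param scores numeric scores.
#' @param labels `BTN`/`MTN` labels.
#' @return The threshold, with the achieved `J` as attribute `"J"`.
#' @export
youden_optimal_threshold <- function(scores, labels) {
  labels <- align_labels(labels, names(scores))
  pos <- labels == "MTN"
  if (!any(pos) || all(pos)) stop("both classes required")
  s <- sort(unique(scores))
  cand <- c(s[1],
            if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  J <- vapply(cand, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, 0)
  best <- cand[which.max(J)]  # which.max takes the first (smallest) maximum
  structure(best, J = max(J))
}

#' Derive the model cutoff by repeated cross-validation
#'
#' Runs `reps` repetitions of stratified `folds`-fold cross-validation on
#' the (complete) discovery marker matrix: in each split the
#' standardization and forest are refit on the training part, held-out
#' samples are scored, and the held-out Youden-optimal threshold is
#' recorded. The returned cutoff is the mean of the reps x folds fold
#' thresholds (all logged in attribute `"fold_thresholds"`).
#'
#' @param x complete discovery marker matrix.
#' @param labels `BTN`/`MTN` labels.
#' @param reps repetitions (default 3).
#' @param folds folds (default 5).
#' @param seed integer seed.
#' @param ntree,mtry forest parameters (refits use the already-chosen
#'   hyperparameters).
#' @return The averaged threshold.
#' @export
derive_threshold <- function(x, labels, reps = 3, folds = 5, seed = 1,
                             ntree = 500, mtry = NULL) {
  x <- as.matrix(x)
  labels <- align_labels(labels, rownames(x))
  if (min(table(labels)) < folds) {
    stop("each class needs at least `folds` samples (every fold must hold both classes)")
  }
  set.seed(seed)
  th <- numeric(0)
  for (r in seq_len(reps)) {
    fold <- make_stratified_folds(labels, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      zs <- standardize(x[tr, , drop = FALSE])
      fit <- rf_fit(zs$z, labels[tr], ntree = ntree, mtry = mtry)
      zte <- standardize(x[!tr, , drop = FALSE], fitted = zs$state)$z
      pr <- rf_prob(fit, zte)
      th <- c(th, as.numeric(youden_optimal_threshold(pr, labels[!tr])))
    }
  }
  structure(mean(th), fold_thresholds = th)
}

#' Fit the full diagnostic model on a discovery cohort
#'
#' Runs the complete funnel on the discovery rows of a metric matrix:
#' coverage filtering, per-block best-metric Mann-Whitney screening at
#' `alpha`, KNN imputation of the screened marker matrix, RFECV marker
#' selection, z-score standardization, random-forest training with
#' CV-chosen hyperparameters, and cutoff derivation by `reps` x `folds`
#' repeated cross-validation of the Youden-optimal threshold.
#'
#' If fewer than `min_markers` blocks pass the screen, the `min_markers`
#' smallest-p markers are used instead (with a warning) so the downstream
#' stages remain defined.
#'
#' @param mm a `metric_matrix` over all samples.
#' @param samples sample sheet data.frame (`sample_id`, `label`,
#'   `cohort`).
#' @param config a configuration list ([default_config()]); individual
#'   elements can be overridden via `...`.
#' @param seed integer seed controlling every stochastic step.
#' @param ... config overrides (e.g. `alpha = 0.01`).
#' @return A `model_bundle`: markers, screen table, imputation state,
#'   standardization, forest, threshold (+ per-fold thresholds), seed and
#'   config.
#' @export
fit_diagnostic_model <- function(mm, samples, config = default_config(),
                                 seed = 1, ...) {
  over <- list(...)
  config[names(over)] <- over
  disc <- samples$sample_id[samples$cohort == "discovery"]
  if (!length(disc)) stop("no discovery samples")
  labels <- setNames(samples$label, samples$sample_id)[disc]

  keep_blocks <- filter_blocks_by_coverage(
    mm, min_cov = config$min_cov, max_cov = config$max_cov,
    min_frac = config$min_frac, samples = disc)
  if (!length(keep_blocks)) stop("no blocks pass the coverage filter")

  sub <- mm
  sub$values <- mm$values[disc, , drop = FALSE]
  screen <- screen_markers(sub, labels, alpha = config$alpha,
                           blocks = keep_blocks)
  all_res <- attr(screen, "all_results")
  min_markers <- if (!is.null(config$min_markers)) config$min_markers else 5L
  if (nrow(screen) < min_markers) {
    warning(sprintf(
      "only %d marker(s) passed the screen at alpha=%g; falling back to the %d smallest-p markers",
      nrow(screen), config$alpha, min_markers))
    ord <- all_res[order(all_res$p), , drop = FALSE]
    screen_used <- head(ord, min_markers)
  } else {
    screen_used <- screen
  }
  markers <- paste(screen_used$block_id, screen_used$metric, sep = ":")

  xd <- mm$values[disc, markers, drop = FALSE]
  imp <- impute_missing_knn(xd, k = config$impute_k)

  ms <- rfecv_select(imp$completed, labels, folds = config$rfecv_folds,
                     step = config$rfecv_step, seed = seed,
                     ntree = config$ntree, metric = config$rfecv_metric)
  final <- ms$markers

  x_final <- imp$completed[, final, drop = FALSE]
  zs <- standardize(x_final)
  forest <- train_forest(zs$z, labels, cv_folds = config$rfecv_folds,
                         seed = seed, ntree = config$ntree)
  mtry <- attr(forest, "chosen")$mtry
  thr <- derive_threshold(x_final, labels, reps = config$threshold_reps,
                          folds = config$threshold_folds, seed = seed,
                          ntree = config$ntree, mtry = mtry)

  structure(list(
    markers = final,
    screen = screen_used,
    screen_all = all_res,
    rfecv = ms,
    impute_state = list(reference = xd[, final, drop = FALSE],
                        k = config$impute_k),
    standardization = zs$state,
    forest = forest,
    threshold = as.numeric(thr),
    fold_thresholds = attr(thr, "fold_thresholds"),
    discovery_samples = disc,
    seed = seed,
    config = config
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle: %d markers, threshold %.3f (mean of %d fold thresholds), seed %d\n",
              length(x$markers), x$threshold, length(x$fold_thresholds),
              x$seed))
  invisible(x)
}

#' Score samples with a fitted model bundle
#'
#' Each sample's marker vector is imputed one at a time against the pooled
#' discovery reference, standardized with the frozen discovery parameters,
#' and scored as the forest's MTN class probability (the methylation
#' score, in `[0, 1]`). Deterministic per bundle.
#'
#' @param bundle a `model_bundle`.
#' @param mm a `metric_matrix` (or a plain matrix already restricted to
#'   the bundle's markers).
#' @param sample_ids rows to score (default: all).
#' @return Named numeric vector of scores.
#' @export
score_samples <- function(bundle, mm, sample_ids = NULL) {
  x <- if (inherits(mm, "metric_matrix")) mm$values else as.matrix(mm)
  missing_m <- setdiff(bundle$markers, colnames(x))
  if (length(missing_m)) {
    stop("missing marker column(s): ", paste(missing_m, collapse = ", "))
  }
  x <- x[, bundle$markers, drop = FALSE]
  if (!is.null(sample_ids)) x <- x[sample_ids, , drop = FALSE]
  if (any(rowSums(!is.na(x)) == 0L)) {
    warning("sample(s) with no observed marker value; imputing all markers")
  }
  imp <- impute_missing_knn(x, k = bundle$impute_state$k,
                            reference = bundle$impute_state)
  z <- standardize(imp$completed, fitted = bundle$standardization)$z
  setNames(rf_prob(bundle$forest, z), rownames(x))
}

#' Save / load a model bundle
#'
#' Serialization round-trips: a reloaded bundle produces identical scores.
#'
#' @param bundle a `model_bundle`.
#' @param path file path (RDS).
#' @export
save_model_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "model_bundle")) stop("not a model_bundle: ", path)
  b
}
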