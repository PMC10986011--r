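## Diagnostic evaluation: confusion metrics, AUC with bootstrap CI,
## ultrasonography comparator, subgroup strata, sample-size formula.

#' Confusion counts from calls and labels
#'
#' @param calls logical or `BTN`/`MTN` vector of predicted classes
#'   (positive = MTN).
#' @param labels true `BTN`/`MTN` labels.
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(calls, labels) {
  if (!is.logical(calls)) calls <- as.character(calls) == "MTN"
  truth <- as.character(labels) == "MTN"
  keep <- !is.na(calls) & !is.na(truth)
  calls <- calls[keep]; truth <- truth[keep]
  structure(list(tp = sum(calls & truth), fp = sum(calls & !truth),
                 tn = sum(!calls & !truth), fn = sum(!calls & truth)),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity = 100 tp/(tp+fn), specificity = 100 tn/(tn+fp),
#' PPV = 100 tp/(tp+fp), NPV = 100 tn/(tn+fn), accuracy =
#' 100 (tp+tn)/total — all percentages at full precision (round only at
#' presentation). A metric with an empty denominator is `NA` and flagged
#' in the `"undefined"` attribute, never silently 0.
#'
#' @param counts a `confusion_counts` (or list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return Named numeric vector of percentages with attribute
#'   `"undefined"`.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    total <- tp + fp + tn + fn
    if (total == 0) stop("empty confusion table")
    ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    out <- c(sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp),
             ppv = ratio(tp, tp + fp),
             npv = ratio(tn, tn + fn),
             accuracy = ratio(tp + tn, total))
    attr(out, "undefined") <- names(out)[is.na(out)]
    out
  })
}

#' Area under the ROC curve (rank formulation)
#'
#' AUC via the Mann-Whitney rank statistic with midrank tie handling
#' (equal scores count 1/2), identical to the trapezoidal ROC area. The
#' optional confidence interval is a stratified bootstrap percentile
#' interval (resampling within each class).
#'
#' @param scores numeric scores (higher = more MTN-like).
#' @param labels `BTN`/`MTN` labels.
#' @param ci compute a bootstrap CI?
#' @param conf confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap.
#' @return List with `auc` and, when `ci`, `ci_lo`/`ci_hi` plus method
#'   metadata.
#' @export
roc_auc <- function(scores, labels, ci = FALSE, conf = 0.95, n_boot = 2000,
                    seed = 1) {
  labels <- align_labels(labels, names(scores))
  pos <- labels == "MTN"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("both classes required for AUC")
  auc_of <- function(s, p) {
    r <- rank(s, ties.method = "average")
    (sum(r[p]) - sum(p) * (sum(p) + 1) / 2) / (sum(p) * sum(!p))
  }
  out <- list(auc = auc_of(scores, pos))
  if (ci) {
    set.seed(seed)
    ip <- which(pos); inn <- which(!pos)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, nP, replace = TRUE), sample(inn, nN, replace = TRUE))
      auc_of(scores[idx], pos[idx])
    }, 0)
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, type = 7)
    out$ci_lo <- qs[1]; out$ci_hi <- qs[2]
    out$ci_method <- "stratified bootstrap percentile"
    out$n_boot <- n_boot
  }
  out
}

#' Ultrasonography comparator calls from TI-RADS categories
#'
#' Positive (suspected malignant) iff ACR TI-RADS category is at least
#' `positive_at` (default 4, the triage boundary at which a confirmatory
#' blood test is recommended). Samples with missing TI-RADS are excluded
#' with a warning.
#'
#' @param meta sample sheet data.frame with `sample_id` and `tirads`.
#' @param positive_at positivity boundary (default 4).
#' @return Named logical vector over samples with a TI-RADS category.
#' @export
ultrasound_comparator <- function(meta, positive_at = 4) {
  miss <- is.na(meta$tirads)
  if (any(miss)) {
    warning(sum(miss), " sample(s) with missing TI-RADS excluded from the comparator")
  }
  m <- meta[!miss, , drop = FALSE]
  setNames(m$tirads >= positive_at, m$sample_id)
}

#' Minimum per-group sample size for a sensitivity/specificity estimate
#'
#' n = ceiling(z^2 P (1 - P) / d^2) with z the standard-normal quantile at
#' 1 - (1 - conf)/2, P the anticipated sensitivity or specificity and d
#' the half-width of the confidence interval. Boundary P in {0, 1} has
#' zero variance and yields n = 0.
#'
#' @param P anticipated proportion in `[0, 1]`.
#' @param d CI half-width (> 0).
#' @param conf confidence level (default 0.95).
#' @return Required per-group count (integer).
#' @export
minimum_sample_size <- function(P, d = 0.1, conf = 0.95) {
  if (d <= 0) stop("d must be > 0")
  if (P < 0 || P > 1) stop("P must be in [0, 1]")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  z <- qnorm(1 - (1 - conf) / 2)
  as.integer(ceiling(z^2 * P * (1 - P) / d^2))
}

default_strata <- function(meta, micronodule_mm = 10) {
  list(
    "tirads>=4" = !is.na(meta$tirads) & meta$tirads >= 4,
    "tirads=4" = !is.na(meta$tirads) & meta$tirads == 4,
    "tirads=5" = !is.na(meta$tirads) & meta$tirads == 5,
    "size<=10mm" = !is.na(meta$size_mm) & meta$size_mm <= micronodule_mm,
    "size>10mm" = !is.na(meta$size_mm) & meta$size_mm > micronodule_mm
  )
}

#' Stratified diagnostic report
#'
#' Confusion metrics plus AUC per clinical stratum. The default strata are
#' TI-RADS >= 4 (suspicious on ultrasonography), TI-RADS 4 and 5
#' separately, and micronodules vs non-micronodules at the inclusive
#' 10 mm boundary. An empty stratum is reported with `n = 0`, not an
#' error; a metric with an empty denominator (e.g. sensitivity in a
#' stratum without positives) is `NA`.
#'
#' @param scores named methylation scores.
#' @param calls named predicted classes (logical or `BTN`/`MTN`).
#' @param meta sample sheet rows for the scored samples.
#' @param strata named list of logical masks over `meta` rows; default
#'   [default_strata()].
#' @return data.frame: one row per stratum with `n`, counts, percentages
#'   and `auc` (`NA` when one class is absent).
#' @export
subgroup_report <- function(scores, calls, meta, strata = NULL) {
  if (is.null(strata)) strata <- default_strata(meta)
  rows <- lapply(names(strata), function(nm) {
    sel <- meta$sample_id[strata[[nm]]]
    sel <- sel[sel %in% names(scores) & !is.na(meta$label[match(sel, meta$sample_id)])]
    if (!length(sel)) {
      return(data.frame(stratum = nm, n = 0L, tp = NA, fp = NA, tn = NA,
                        fn = NA, sensitivity = NA, specificity = NA,
                        ppv = NA, npv = NA, accuracy = NA, auc = NA))
    }
    lab <- meta$label[match(sel, meta$sample_id)]
    cc <- confusion_counts(calls[sel], lab)
    m <- confusion_metrics(cc)
    auc <- if (length(unique(lab)) == 2L) roc_auc(scores[sel], setNames(lab, sel))$auc
           else NA_real_
    data.frame(stratum = nm, n = length(sel), tp = cc$tp, fp = cc$fp,
               tn = cc$tn, fn = cc$fn, sensitivity = m["sensitivity"],
               specificity = m["specificity"], ppv = m["ppv"],
               npv = m["npv"], accuracy = m["accuracy"], auc = auc,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Evaluate a fitted model on one cohort
#'
#' Scores every sample of the requested cohort split, calls MTN at the
#' bundle threshold (`score >= t`), and assembles the full diagnostic
#' battery: confusion metrics, AUC with bootstrap CI, the ultrasonography
#' comparator's metrics on the same samples, and the clinical subgroup
#' strata.
#'
#' @param bundle a `model_bundle`.
#' @param mm the `metric_matrix` holding the cohort's measurements.
#' @param samples full sample sheet.
#' @param cohort which split to evaluate (`"validation"`, `"test"`, ...).
#' @param seed seed for the AUC bootstrap.
#' @return A `diagnostic_report` list: `scores`, `calls`, `counts`,
#'   `metrics`, `auc`, `comparator`, `subgroups`.
#' @export
evaluate_cohort <- function(bundle, mm, samples, cohort = "validation",
                            seed = 1) {
  meta <- samples[samples$cohort == cohort, , drop = FALSE]
  if (!nrow(meta)) stop("no samples in cohort: ", cohort)
  scores <- score_samples(bundle, mm, sample_ids = meta$sample_id)
  calls <- scores >= bundle$threshold
  lab <- setNames(meta$label, meta$sample_id)
  labelled <- names(lab)[!is.na(lab)]

  counts <- confusion_counts(calls[labelled], lab[labelled])
  metrics <- confusion_metrics(counts)
  auc <- roc_auc(scores[labelled], lab[labelled], ci = TRUE, seed = seed)

  us <- suppressWarnings(ultrasound_comparator(meta))
  us_ids <- intersect(names(us), labelled)
  us_metrics <- if (length(us_ids)) {
    confusion_metrics(confusion_counts(us[us_ids], lab[us_ids]))
  } else NULL

  structure(list(
    cohort = cohort,
    scores = scores,
    calls = ifelse(calls, "MTN", "BTN"),
    threshold = bundle$threshold,
    counts = counts,
    metrics = metrics,
    auc = auc,
    comparator = us_metrics,
    subgroups = subgroup_report(scores, calls, meta)
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  f <- function(v) ifelse(is.na(v), "undef", sprintf("%.2f%%", v))
  cat(sprintf("diagnostic_report [%s]: n=%d, threshold=%.3f\n", x$cohort,
              length(x$scores), x$threshold))
  with(x$counts, cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", tp, fp, tn, fn)))
  m <- x$metrics
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s  accuracy %s\n",
              f(m["sensitivity"]), f(m["specificity"]), f(m["ppv"]),
              f(m["npv"]), f(m["accuracy"])))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f, %s)\n", x$auc$auc, x$auc$ci_lo,
              x$auc$ci_hi, x$auc$ci_method))
  if (!is.null(x$comparator)) {
    cat(sprintf("  ultrasonography: sensitivity %s  specificity %s\n",
                f(x$comparator["sensitivity"]), f(x$comparator["specificity"])))
  }
  invisible(x)
}
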