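## Sample sheets, BED region files, configuration.

#' Read a clinical sample sheet
#'
#' Comma- or tab-separated with a header. Required columns: `sample_id`,
#' `label` (`BTN`/`MTN`, may be empty for non-discovery samples), `cohort`
#' (`discovery`/`validation`/`test`). Optional: `age` (years), `sex`
#' (`F`/`M`), `tirads` (ACR TI-RADS category 1-5), `size_mm` (nodule
#' maximum diameter, mm). Missing values are empty fields, never sentinel
#' numbers.
#'
#' @param path path to the sheet.
#' @return A `data.frame` with typed columns; missing values are `NA`.
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, header = TRUE, colClasses = list(character = "sample_id"),
              na.strings = c("", "NA"))
  need <- c("sample_id", "label", "cohort")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))

  dt[, sample_id := as.character(sample_id)]
  dup <- unique(dt$sample_id[duplicated(dt$sample_id)])
  if (length(dup)) stop("duplicated sample_id(s): ", paste(dup, collapse = ", "))

  bad_lab <- !is.na(dt$label) & !dt$label %in% c("BTN", "MTN")
  if (any(bad_lab)) stop("label must be BTN or MTN (or empty): ",
                         paste(unique(dt$label[bad_lab]), collapse = ", "))
  bad_coh <- is.na(dt$cohort) | !dt$cohort %in% c("discovery", "validation", "test")
  if (any(bad_coh)) stop("cohort must be one of discovery/validation/test")
  no_lab <- is.na(dt$label) & dt$cohort == "discovery"
  if (any(no_lab)) stop("discovery samples require a label: ",
                        paste(dt$sample_id[no_lab], collapse = ", "))

  for (col in c("age", "size_mm")) {
    if (col %in% names(dt)) dt[[col]] <- as.numeric(dt[[col]]) else dt[[col]] <- NA_real_
  }
  if ("sex" %in% names(dt)) {
    bad <- !is.na(dt$sex) & !dt$sex %in% c("F", "M")
    if (any(bad)) stop("sex must be F or M (or empty)")
  } else dt$sex <- NA_character_
  if ("tirads" %in% names(dt)) {
    dt$tirads <- suppressWarnings(as.integer(dt$tirads))
    bad <- !is.na(dt$tirads) & !dt$tirads %in% 1:5
    if (any(bad)) stop("tirads must be an integer in 1..5: samples ",
                       paste(dt$sample_id[bad], collapse = ", "))
  } else dt$tirads <- NA_integer_
  bad_sz <- !is.na(dt$size_mm) & dt$size_mm <= 0
  if (any(bad_sz)) stop("size_mm must be > 0 when present")

  as.data.frame(dt[, c("sample_id", "label", "cohort", "age", "sex",
                       "tirads", "size_mm"), with = FALSE])
}

#' Write a sample sheet
#' @param samples a data.frame as returned by [read_sample_sheet()].
#' @param path output path; `.csv` writes comma-separated, otherwise tabs.
#' @export
write_sample_sheet <- function(samples, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  fwrite(as.data.table(samples), path, sep = sep, na = "", quote = FALSE)
  invisible(path)
}

#' Read a BED region file (BED3/BED4)
#'
#' 0-based half-open intervals; a fourth column, when present, is the
#' region name. Overlapping regions are preserved as-is (no merging).
#'
#' @param path path to the BED file.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3) stop("BED file needs >= 3 columns: ", path)
  out <- data.table(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]),
    end = as.integer(dt[[3]]),
    name = if (ncol(dt) >= 4) as.character(dt[[4]]) else NA_character_
  )
  if (any(is.na(out$start) | is.na(out$end))) stop("non-integer BED coordinates in ", path)
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    stop(sprintf("BED interval with end <= start at data line %s of %s",
                 paste(head(bad, 10), collapse = ","), path))
  }
  if (all(is.na(out$name))) out[, name := sprintf("region_%d", .I)]
  out[]
}

#' Write regions to BED4
#' @param regions data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  dt <- as.data.table(regions)
  if (!all(c("chrom", "start", "end") %in% names(dt))) {
    stop("regions must have chrom, start, end")
  }
  if (any(dt$end <= dt$start)) stop("region with end <= start refused")
  nm <- if ("name" %in% names(dt)) dt$name else if ("block_id" %in% names(dt)) dt$block_id
        else sprintf("region_%d", seq_len(nrow(dt)))
  writeLines(sprintf("%s\t%d\t%d\t%s", dt$chrom, as.integer(dt$start),
                     as.integer(dt$end), nm), path)
  invisible(path)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Unknown keys are rejected so typos surface early; values override the
#' package defaults returned by `default_config()`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    r2_min = 0.5, min_cpgs = 3L, min_pairs = 10L, max_gap_bp = 200L,
    mhl_exponent = 1, mhl3_exponent = 3, pdr_min_cpgs = 3L,
    min_cov = 10, max_cov = 500, min_frac = 0.8,
    alpha = 0.001, impute_k = 5L, rfecv_folds = 10L, rfecv_step = 1L,
    rfecv_metric = "auc", ntree = 500L,
    threshold_reps = 3L, threshold_folds = 5L,
    tirads_positive = 4L, micronodule_mm = 10
  )
}
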