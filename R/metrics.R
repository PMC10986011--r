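## Haplotype-level block measurements.
##
## Six measurements per (sample, block):
##   AMF   — average methylation fraction: methylated CpG calls / all calls.
##   MHL   — methylated haplotype load: length-weighted average over
##           substring lengths l of P(M_l), the count-weighted fraction of
##           fully methylated length-l contiguous substrings among all
##           length-l substrings of the clipped read patterns, with
##           weights w_l = l^k (k = 1).
##   UMHL  — the fully-unmethylated analogue of MHL.
##   MHL3 / UMHL3 — the same loads with cubic weights (w_l = l^3).
##   PDR   — proportion of discordant reads: among reads whose clipped
##           pattern has >= min_cpgs_per_read CpGs, the count-weighted
##           fraction containing both a 0 and a 1.
## Substrings are contiguous within a read and never span reads; reads
## clipped to partial block coverage contribute substrings only over their
## covered range (haplotype load is defined on observed co-methylation,
## never imputed).

METRIC_NAMES <- c("AMF", "MHL", "UMHL", "MHL3", "UMHL3", "PDR")

#' Read patterns clipped to one block
#'
#' @param patterns character vector of 0/1 strings, each aligned to a
#'   contiguous range of block CpG indices.
#' @param counts positive integer multiplicities.
#' @param offsets 0-based index of each pattern's first covered block CpG.
#' @param L number of CpGs in the block.
#' @return A `block_haplotypes` object.
#' @export
block_haplotypes <- function(patterns, counts = rep(1L, length(patterns)),
                             offsets = rep(0L, length(patterns)), L = NULL) {
  stopifnot(length(patterns) == length(counts),
            length(patterns) == length(offsets))
  if (length(patterns) && !all(grepl("^[01]+$", patterns))) {
    stop("patterns must be non-empty 0/1 strings")
  }
  counts <- as.integer(counts); offsets <- as.integer(offsets)
  if (any(counts < 1L)) stop("counts must be >= 1")
  if (is.null(L)) L <- if (length(patterns)) max(offsets + nchar(patterns)) else 0L
  L <- as.integer(L)
  if (any(offsets < 0L) || any(offsets + nchar(patterns) > L)) {
    stop("pattern index range must lie within [0, L)")
  }
  structure(list(patterns = patterns, counts = counts, offsets = offsets,
                 L = L),
            class = "block_haplotypes")
}

## Per-pattern substring statistics for a set of 0/1 strings:
## len, n1 (methylated calls), and for l = 1..Lmax the number of fully
## methylated (M1) and fully unmethylated (M0) length-l substrings.
## A run of r equal characters holds r - l + 1 length-l substrings.
pattern_stats <- function(patterns, Lmax = NULL) {
  n <- length(patterns)
  len <- nchar(patterns)
  if (is.null(Lmax)) Lmax <- if (n) max(len) else 0L
  M1 <- matrix(0, n, Lmax)
  M0 <- matrix(0, n, Lmax)
  n1 <- integer(n)
  chars <- strsplit(patterns, "", fixed = TRUE)
  for (i in seq_len(n)) {
    v <- chars[[i]] == "1"
    n1[i] <- sum(v)
    r <- rle(v)
    for (k in seq_along(r$values)) {
      rl <- r$lengths[k]
      ls <- seq_len(min(rl, Lmax))
      if (r$values[k]) M1[i, ls] <- M1[i, ls] + (rl - ls + 1L)
      else M0[i, ls] <- M0[i, ls] + (rl - ls + 1L)
    }
  }
  list(len = len, n1 = n1, M1 = M1, M0 = M0, Lmax = Lmax)
}

## Haplotype load from aggregated substring tallies.
## meth_l, tot_l: vectors over l; only lengths with >= 1 observed substring
## enter both the numerator and the normalizer.
load_from_tallies <- function(meth_l, tot_l, k) {
  use <- tot_l > 0
  if (!any(use)) return(NA_real_)
  l <- which(use)
  w <- l^k
  sum(w * meth_l[use] / tot_l[use]) / sum(w)
}

#' Methylated haplotype load (MHL)
#'
#' @param bh a [block_haplotypes()] object.
#' @param weight_exponent k in the length weights w_l = l^k (1 for MHL,
#'   3 for MHL3).
#' @return Value in `[0, 1]`, or `NA` for an empty block.
#' @export
compute_mhl <- function(bh, weight_exponent = 1) {
  if (!length(bh$patterns)) return(NA_real_)
  st <- pattern_stats(bh$patterns)
  tot <- vapply(seq_len(st$Lmax),
                function(l) sum(bh$counts * pmax(0L, st$len - l + 1L)), 0)
  meth <- as.numeric(crossprod(bh$counts, st$M1))
  load_from_tallies(meth, tot, weight_exponent)
}

#' Unmethylated haplotype load (UMHL)
#'
#' Identical to [compute_mhl()] with fully unmethylated substrings; for
#' any weight exponent, `umhl(x) == mhl(complement(x))`.
#'
#' @inheritParams compute_mhl
#' @export
compute_umhl <- function(bh, weight_exponent = 1) {
  if (!length(bh$patterns)) return(NA_real_)
  st <- pattern_stats(bh$patterns)
  tot <- vapply(seq_len(st$Lmax),
                function(l) sum(bh$counts * pmax(0L, st$len - l + 1L)), 0)
  unmeth <- as.numeric(crossprod(bh$counts, st$M0))
  load_from_tallies(unmeth, tot, weight_exponent)
}

#' Average methylation fraction (AMF)
#'
#' Count-weighted methylated CpG calls over all CpG calls in the block.
#'
#' @inheritParams compute_mhl
#' @export
compute_amf <- function(bh) {
  if (!length(bh$patterns)) return(NA_real_)
  st <- pattern_stats(bh$patterns)
  sum(bh$counts * st$n1) / sum(bh$counts * st$len)
}

#' Proportion of discordant reads (PDR)
#'
#' A read is eligible iff its clipped pattern covers at least
#' `min_cpgs_per_read` block CpGs; it is discordant iff that pattern
#' contains both a 0 and a 1. Returns the count-weighted discordant
#' fraction among eligible reads, or `NA` when no read is eligible.
#'
#' @inheritParams compute_mhl
#' @param min_cpgs_per_read eligibility floor (default 3).
#' @export
compute_pdr <- function(bh, min_cpgs_per_read = 3) {
  if (!length(bh$patterns)) return(NA_real_)
  st <- pattern_stats(bh$patterns)
  elig <- st$len >= min_cpgs_per_read
  if (!any(elig)) return(NA_real_)
  disc <- st$n1 > 0L & st$n1 < st$len
  sum(bh$counts[elig & disc]) / sum(bh$counts[elig])
}

#' Mean per-CpG read depth over the block ("X" coverage)
#'
#' @inheritParams compute_mhl
#' @param L number of CpGs in the block (defaults to `bh$L`).
#' @export
block_coverage <- function(bh, L = bh$L) {
  if (!length(bh$patterns) || L == 0L) return(0)
  sum(bh$counts * nchar(bh$patterns)) / L
}

#' All six measurements for one block
#' @inheritParams compute_pdr
#' @param mhl_exponent,mhl3_exponent length-weight exponents.
#' @return Named numeric vector `AMF, MHL, UMHL, MHL3, UMHL3, PDR`.
#' @export
compute_metric_vector <- function(bh, mhl_exponent = 1, mhl3_exponent = 3,
                                  min_cpgs_per_read = 3) {
  c(AMF = compute_amf(bh),
    MHL = compute_mhl(bh, mhl_exponent),
    UMHL = compute_umhl(bh, mhl_exponent),
    MHL3 = compute_mhl(bh, mhl3_exponent),
    UMHL3 = compute_umhl(bh, mhl3_exponent),
    PDR = compute_pdr(bh, min_cpgs_per_read))
}

#' Clip one sample's reads to a block
#'
#' Each read overlapping the block contributes its pattern restricted to
#' the block CpGs it covers; reads covering no block CpG contribute
#' nothing.
#'
#' @param haplotypes one sample's haplotype records.
#' @param mhbs an `mhb_set`.
#' @param block_id which block.
#' @param sites reference CpG sites.
#' @return A [block_haplotypes()] object.
#' @export
extract_block_haplotypes <- function(haplotypes, mhbs, block_id, sites) {
  b <- which(mhbs$block_id == block_id)
  if (!length(b)) stop("unknown block_id: ", block_id)
  cp <- mhb_cpgs(mhbs)[[block_id]]
  ch <- mhbs$chrom[b]
  p <- site_index(sites)[[ch]]
  j0 <- match(cp[1], p); j1 <- match(cp[length(cp)], p)
  if (is.na(j0) || is.na(j1)) stop("block CpGs missing from reference set")

  dt <- as.data.table(haplotypes)[chrom == ch]
  if (!nrow(dt)) return(block_haplotypes(character(0), integer(0), integer(0), L = length(cp)))
  span <- record_site_span(dt, sites)
  keep <- span$i1 <= span$i2 & span$i1 <= j1 & span$i2 >= j0
  dt <- dt[keep]
  if (!nrow(dt)) return(block_haplotypes(character(0), integer(0), integer(0), L = length(cp)))
  i1 <- span$i1[keep]; i2 <- span$i2[keep]
  a <- pmax(i1, j0); bb <- pmin(i2, j1)
  block_haplotypes(substr(dt$pattern, a - i1 + 1L, bb - i1 + 1L),
                   dt$count, a - j0, L = length(cp))
}

#' Compute the sample-by-(block, metric) measurement matrix
#'
#' Builds all six measurements plus per-(sample, block) coverage for every
#' sample of a cohort over a frozen block set. Implemented with a single
#' vectorized pass over all clipped reads; agrees exactly with the
#' per-block functions ([compute_mhl()] etc.).
#'
#' @param cohort a list with `samples` (a sample sheet data.frame) and
#'   `haplotypes` (a named list of per-sample record tables).
#' @param mhbs an `mhb_set`.
#' @param sites reference CpG sites.
#' @param mhl_exponent,mhl3_exponent length-weight exponents for
#'   MHL/UMHL and MHL3/UMHL3.
#' @param pdr_min_cpgs PDR read-eligibility floor.
#' @return A `metric_matrix`: list with `values` (samples x
#'   `"block:metric"` columns, `NA` where undefined), `coverage` (samples x
#'   blocks, in X), `samples`, `block_ids`, `metrics`, `params`.
#' @export
build_metric_matrix <- function(cohort, mhbs, sites, mhl_exponent = 1,
                                mhl3_exponent = 3, pdr_min_cpgs = 3) {
  ids <- cohort$samples$sample_id
  missing_h <- setdiff(ids, names(cohort$haplotypes))
  empty <- vapply(cohort$haplotypes[intersect(ids, names(cohort$haplotypes))],
                  function(h) nrow(h) == 0L, TRUE)
  if (length(missing_h) || any(empty)) {
    warning("sample(s) with no haplotypes (all-missing row): ",
            paste(c(missing_h, names(empty)[empty]), collapse = ", "))
  }
  extra <- setdiff(names(cohort$haplotypes), ids)
  if (length(extra)) stop("haplotype key(s) absent from sample sheet: ",
                          paste(extra, collapse = ", "))

  nb <- nrow(mhbs)
  vals <- matrix(NA_real_, length(ids), nb * length(METRIC_NAMES),
                 dimnames = list(ids, paste(rep(mhbs$block_id, each = length(METRIC_NAMES)),
                                            METRIC_NAMES, sep = ":")))
  covm <- matrix(0, length(ids), nb, dimnames = list(ids, mhbs$block_id))
  params <- list(mhl_exponent = mhl_exponent, mhl3_exponent = mhl3_exponent,
                 pdr_min_cpgs = pdr_min_cpgs)
  out <- structure(list(values = vals, coverage = covm, samples = ids,
                        block_ids = mhbs$block_id, metrics = METRIC_NAMES,
                        params = params),
                   class = "metric_matrix")

  all_h <- rbindlist(
    lapply(intersect(ids, names(cohort$haplotypes)), function(s) {
      h <- cohort$haplotypes[[s]]
      if (!nrow(h)) return(NULL)
      cbind(as.data.table(h), sample_id = s)
    }))
  if (is.null(all_h) || !nrow(all_h)) return(out)

  span <- record_site_span(all_h, sites)
  all_h[, `:=`(i1 = span$i1, i2 = span$i2)]
  all_h <- all_h[i1 <= i2]
  if (!nrow(all_h)) return(out)

  ## block site-index ranges per chromosome
  idx <- site_index(sites)
  cp <- mhb_cpgs(mhbs)
  B <- data.table(
    chrom = mhbs$chrom,
    j0 = vapply(seq_len(nb), function(b) match(cp[[b]][1], idx[[mhbs$chrom[b]]]), 0L),
    j1 = vapply(seq_len(nb), function(b) match(cp[[b]][mhbs$n_cpgs[b]], idx[[mhbs$chrom[b]]]), 0L),
    block_id = mhbs$block_id, L = mhbs$n_cpgs
  )
  setkey(B, chrom, j0, j1)
  R <- all_h[, .(chrom, i1, i2, pattern, count, sample_id)]
  hits <- foverlaps(R, B, by.x = c("chrom", "i1", "i2"),
                    by.y = c("chrom", "j0", "j1"), type = "any", nomatch = NULL)
  if (!nrow(hits)) return(out)

  hits[, `:=`(a = pmax(i1, j0), b = pmin(i2, j1))]
  hits[, `:=`(clip = substr(pattern, a - i1 + 1L, b - i1 + 1L),
              offset = a - j0)]
  X <- hits[, .(count = sum(count)), by = .(sample_id, block_id, L, clip)]

  up <- unique(X$clip)
  Lmax <- max(nchar(up))
  st <- pattern_stats(up, Lmax)
  pidx <- match(X$clip, up)
  len <- st$len[pidx]
  n1 <- st$n1[pidx]
  w <- X$count

  gid <- paste(X$sample_id, X$block_id, sep = "\r")
  meth <- rowsum(w * st$M1[pidx, , drop = FALSE], gid)
  unmeth <- rowsum(w * st$M0[pidx, , drop = FALSE], gid)
  tot <- rowsum(w * outer(len, seq_len(Lmax),
                          function(a, l) pmax(0L, a - l + 1L)), gid)
  calls1 <- rowsum(w * n1, gid)[, 1]
  calls <- rowsum(w * len, gid)[, 1]
  elig <- len >= pdr_min_cpgs
  disc <- n1 > 0L & n1 < len
  pdr_den <- rowsum(w * elig, gid)[, 1]
  pdr_num <- rowsum(w * (elig & disc), gid)[, 1]

  glab <- rownames(meth)
  parts <- strsplit(glab, "\r", fixed = TRUE)
  g_sample <- vapply(parts, `[`, "", 1L)
  g_block <- vapply(parts, `[`, "", 2L)
  Lb <- B$L[match(g_block, B$block_id)]

  weighted_load <- function(num, k) {
    W <- matrix(seq_len(Lmax)^k, nrow(num), Lmax, byrow = TRUE)
    use <- tot > 0
    P <- ifelse(use, num / ifelse(use, tot, 1), 0)
    rowSums(W * P * use) / rowSums(W * use)
  }
  amf <- calls1 / calls
  mhl <- weighted_load(meth, mhl_exponent)
  umhl <- weighted_load(unmeth, mhl_exponent)
  mhl3 <- weighted_load(meth, mhl3_exponent)
  umhl3 <- weighted_load(unmeth, mhl3_exponent)
  pdr <- ifelse(pdr_den > 0, pdr_num / pdr_den, NA_real_)

  ri <- match(g_sample, ids)
  set_col <- function(metric, v) {
    out$values[cbind(ri, match(paste(g_block, metric, sep = ":"),
                               colnames(out$values)))] <<- v
  }
  set_col("AMF", amf); set_col("MHL", mhl); set_col("UMHL", umhl)
  set_col("MHL3", mhl3); set_col("UMHL3", umhl3); set_col("PDR", pdr)
  out$coverage[cbind(ri, match(g_block, colnames(out$coverage)))] <- calls / Lb
  out
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat(sprintf("metric_matrix: %d samples x %d blocks x %d metrics (%.1f%% missing)\n",
              nrow(x$values), length(x$block_ids), length(x$metrics),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write a metric matrix as wide-format TSV (missing encoded as "NA")
#' @param mm a `metric_matrix`.
#' @param path output path (values); coverage is written alongside with a
#'   `.coverage.tsv` suffix.
#' @export
write_metric_matrix <- function(mm, path) {
  v <- data.table(sample_id = rownames(mm$values), as.data.table(mm$values))
  fwrite(v, path, sep = "\t", na = "NA", quote = FALSE)
  cv <- data.table(sample_id = rownames(mm$coverage), as.data.table(mm$coverage))
  fwrite(cv, sub("(\\.tsv)?(\\.gz)?$", ".coverage.tsv", path), sep = "\t",
         na = "NA", quote = FALSE)
  invisible(path)
}
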