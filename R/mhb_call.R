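## Methylation haplotype block (MHB) calling.
##
## Blocks are runs of adjacent CpGs whose methylation states are strongly
## co-inherited on individual reads.  Co-methylation is quantified by r2,
## the squared Pearson correlation of the two binary methylation states
## over reads covering both sites (count-weighted), the methylation
## analogue of genetic linkage disequilibrium.  A block is a maximal
## stretch in which every consecutive CpG pair has defined r2 >= r2_min.

pool_haplotypes <- function(haplotypes) {
  if (is.data.frame(haplotypes)) return(as.data.table(haplotypes))
  rbindlist(haplotypes, use.names = TRUE)
}

## Count-weighted squared Pearson correlation of two 0/1 vectors.
weighted_r2 <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx <= .Machine$double.eps * sw || syy <= .Machine$double.eps * sw) {
    return(NA_real_)
  }
  sxy <- sum(w * (x - mx) * (y - my))
  min(1, sxy^2 / (sxx * syy))
}

#' Pairwise methylation linkage disequilibrium between two CpG sites
#'
#' Computes r2, the squared Pearson correlation of the binary methylation
#' states at two reference CpGs over the reads covering both (weighted by
#' read multiplicity). The estimate is flagged undefined when fewer than
#' `min_pairs` (count-weighted) reads cover both sites or when either site
#' is constant across those reads.
#'
#' @param haplotypes pooled haplotype records (a `data.table` or a list of
#'   per-sample tables).
#' @param sites reference CpG sites ([cpg_sites()]).
#' @param site_a,site_b lists with `chrom` and `pos`, or two-element
#'   vectors `c(chrom, pos)`.
#' @param min_pairs minimum count-weighted number of covering reads.
#' @return A list with `site_a`, `site_b`, `n_pairs`, `r2`, `defined`.
#' @export
pairwise_r2 <- function(haplotypes, sites, site_a, site_b, min_pairs = 10) {
  norm_site <- function(s) {
    if (is.list(s)) list(chrom = as.character(s$chrom), pos = as.integer(s$pos))
    else list(chrom = as.character(s[1]), pos = as.integer(s[2]))
  }
  a <- norm_site(site_a); b <- norm_site(site_b)
  if (a$chrom != b$chrom) stop("sites must be on the same chromosome")
  p <- site_index(sites)[[a$chrom]]
  ia <- match(a$pos, p); ib <- match(b$pos, p)
  if (is.na(ia) || is.na(ib)) stop("site not in the reference CpG set")

  dt <- pool_haplotypes(haplotypes)
  dt <- dt[chrom == a$chrom]
  est <- list(site_a = a, site_b = b, n_pairs = 0L, r2 = NA_real_, defined = FALSE)
  if (!nrow(dt)) return(est)
  span <- record_site_span(dt, sites)
  cover <- span$i1 <= min(ia, ib) & span$i2 >= max(ia, ib)
  if (!any(cover)) return(est)
  dt <- dt[cover]
  off <- span$i1[cover]
  x <- as.integer(substr(dt$pattern, ia - off + 1L, ia - off + 1L))
  y <- as.integer(substr(dt$pattern, ib - off + 1L, ib - off + 1L))
  est$n_pairs <- sum(dt$count)
  if (est$n_pairs < min_pairs) return(est)
  r2 <- weighted_r2(x, y, dt$count)
  est$r2 <- r2
  est$defined <- !is.na(r2)
  est
}

## Per-adjacent-pair count-weighted joint read support within one
## chromosome, given record spans (i1, i2) into the site vector.
pair_support <- function(i1, i2, counts, n_sites) {
  if (n_sites < 2L) return(numeric(0))
  d <- numeric(n_sites)       # difference array over pair indices 1..n-1
  lo <- i1
  hi <- i2 - 1L
  keep <- hi >= lo & hi >= 1L & lo <= n_sites - 1L
  lo <- pmax(lo[keep], 1L); hi <- pmin(hi[keep], n_sites - 1L)
  w <- counts[keep]
  for (k in seq_along(lo)) {
    d[lo[k]] <- d[lo[k]] + w[k]
    d[hi[k] + 1L] <- d[hi[k] + 1L] - w[k]
  }
  cumsum(d)[seq_len(n_sites - 1L)]
}

#' Segment reference CpGs into candidate runs
#'
#' Candidate runs are maximal stretches of consecutive reference CpGs in
#' which every adjacent pair is at most `max_gap_bp` apart and is jointly
#' covered by at least one read. Block search is restricted to runs since
#' RRBS coverage is patchy.
#'
#' @param sites reference CpG sites.
#' @param haplotypes pooled haplotype records.
#' @param max_gap_bp maximum distance (bp) between adjacent CpGs in a run.
#' @return A list of runs, each a list with `chrom` and `pos` (ordered
#'   member positions).
#' @export
segment_candidate_runs <- function(sites, haplotypes, max_gap_bp = 200) {
  dt <- pool_haplotypes(haplotypes)
  idx <- site_index(sites)
  runs <- list()
  for (ch in names(idx)) {
    p <- idx[[ch]]
    n <- length(p)
    if (!n) next
    sub <- dt[chrom == ch]
    if (nrow(sub)) {
      span <- record_site_span(sub, sites)
      sup <- pair_support(span$i1, span$i2, sub$count, n)
    } else {
      sup <- numeric(max(0L, n - 1L))
    }
    ## break between i and i+1 if gap too large or no joint support
    brk <- if (n > 1L) (diff(p) > max_gap_bp) | (sup <= 0) else logical(0)
    grp <- cumsum(c(0L, as.integer(brk)))
    for (g in split(p, grp)) {
      runs[[length(runs) + 1L]] <- list(chrom = ch, pos = as.integer(g))
    }
  }
  runs
}

#' Call methylation haplotype blocks
#'
#' Within each candidate run ([segment_candidate_runs()]), consecutive-pair
#' r2 is computed on the pooled reads and maximal stretches where every
#' consecutive pair has a defined r2 >= `r2_min` are emitted as blocks when
#' they contain at least `min_cpgs` CpGs. A pair whose r2 is undefined
#' (insufficient coverage or a constant site) breaks a block. Emitted
#' blocks are disjoint and the output is deterministic given its inputs.
#'
#' Blocks are conventionally called once on pooled discovery-cohort reads,
#' then frozen and reused for downstream cohorts.
#'
#' @param haplotypes pooled haplotype records (list of per-sample tables or
#'   one table).
#' @param sites reference CpG sites.
#' @param r2_min minimum consecutive-pair r2 (default 0.5).
#' @param min_cpgs minimum CpGs per block (default 3).
#' @param min_pairs minimum count-weighted joint coverage per pair
#'   (default 10).
#' @param max_gap_bp maximum adjacent-CpG distance within a run
#'   (default 200).
#' @return An `mhb_set`: a `data.table` with `chrom`, `start`, `end`
#'   (half-open span from first to last member CpG + 1), `block_id`,
#'   `n_cpgs`, and a `cpgs` attribute (named list of member positions).
#' @export
call_mhbs <- function(haplotypes, sites, r2_min = 0.5, min_cpgs = 3,
                      min_pairs = 10, max_gap_bp = 200) {
  dt <- pool_haplotypes(haplotypes)
  runs <- segment_candidate_runs(sites, dt, max_gap_bp = max_gap_bp)
  idx <- site_index(sites)

  blocks <- list()
  for (run in runs) {
    np <- length(run$pos)
    if (np < min_cpgs) next
    ok <- consecutive_pair_ok(dt, sites, idx, run, r2_min, min_pairs)
    ## maximal stretches of TRUE in `ok` -> blocks of (len + 1) CpGs
    r <- rle(ok)
    at <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      first <- at[k]
      ncpg <- r$lengths[k] + 1L
      if (ncpg < min_cpgs) next
      posn <- run$pos[first:(first + ncpg - 1L)]
      blocks[[length(blocks) + 1L]] <-
        list(chrom = run$chrom, pos = posn)
    }
  }
  new_mhb_set(blocks)
}

## r2 >= r2_min (and defined) for each adjacent pair of one run.
consecutive_pair_ok <- function(dt, sites, idx, run, r2_min, min_pairs) {
  p <- idx[[run$chrom]]
  j <- match(run$pos, p)
  sub <- dt[chrom == run$chrom]
  np <- length(j)
  if (!nrow(sub)) return(rep(FALSE, np - 1L))
  span <- record_site_span(sub, sites)
  ok <- logical(np - 1L)
  for (k in seq_len(np - 1L)) {
    ia <- j[k]; ib <- j[k + 1L]
    cover <- which(span$i1 <= ia & span$i2 >= ib)
    if (!length(cover)) next
    w <- sub$count[cover]
    if (sum(w) < min_pairs) next
    off <- span$i1[cover]
    x <- as.integer(substr(sub$pattern[cover], ia - off + 1L, ia - off + 1L))
    y <- as.integer(substr(sub$pattern[cover], ib - off + 1L, ib - off + 1L))
    r2 <- weighted_r2(x, y, w)
    ok[k] <- !is.na(r2) && r2 >= r2_min
  }
  ok
}

new_mhb_set <- function(blocks) {
  if (!length(blocks)) {
    out <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), block_id = character(0),
                      n_cpgs = integer(0))
    setattr(out, "cpgs", list())
    setattr(out, "class", c("mhb_set", class(out)))
    return(out)
  }
  out <- data.table(
    chrom = vapply(blocks, `[[`, "", "chrom"),
    start = vapply(blocks, function(b) b$pos[1], 0L),
    end = vapply(blocks, function(b) b$pos[length(b$pos)] + 1L, 0L),
    n_cpgs = vapply(blocks, function(b) length(b$pos), 0L)
  )
  setorder(out, chrom, start)
  out[, block_id := sprintf("MHB_%05d", .I)]
  setcolorder(out, c("chrom", "start", "end", "block_id", "n_cpgs"))
  cp <- lapply(blocks, `[[`, "pos")
  ## reorder cpgs to match the sorted table
  o <- order(vapply(blocks, `[[`, "", "chrom"), vapply(blocks, function(b) b$pos[1], 0L))
  cp <- cp[o]
  names(cp) <- out$block_id
  setattr(out, "cpgs", cp)
  setattr(out, "class", c("mhb_set", class(out)))
  out
}

#' Member CpG positions of an MHB set
#' @param mhbs an `mhb_set`.
#' @return Named list (by `block_id`) of ordered integer positions.
#' @export
mhb_cpgs <- function(mhbs) attr(mhbs, "cpgs", exact = TRUE)

#' Rebuild an `mhb_set` from regions plus a reference CpG set
#'
#' Used to reload frozen blocks written with [write_regions_bed()]: each
#' region's member CpGs are the reference sites falling inside it.
#'
#' @param regions a BED-like table (`chrom`, `start`, `end`, `name`).
#' @param sites reference CpG sites.
#' @return An `mhb_set` (block ids taken from region names).
#' @export
mhb_set_from_regions <- function(regions, sites) {
  idx <- site_index(sites)
  blocks <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    p <- idx[[regions$chrom[i]]]
    if (is.null(p)) stop("no reference CpGs on ", regions$chrom[i])
    sel <- p[p >= regions$start[i] & p < regions$end[i]]
    if (!length(sel)) stop("region ", i, " contains no reference CpGs")
    blocks[[i]] <- list(chrom = regions$chrom[i], pos = sel)
  }
  out <- new_mhb_set(blocks)
  if ("name" %in% names(regions) && !anyNA(regions$name)) {
    ## preserve caller ids, matching on coordinates
    key <- paste(out$chrom, out$start)
    ord <- match(key, paste(regions$chrom, regions$start))
    cp <- mhb_cpgs(out)
    out[, block_id := regions$name[ord]]
    names(cp) <- out$block_id
    setattr(out, "cpgs", cp)
  }
  out
}
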