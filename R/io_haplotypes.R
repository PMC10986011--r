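## mHap-style haplotype file IO.
##
## Dialect: tab-separated, >= 6 columns per non-comment line:
##   chrom  start  end  pattern  count  strand
## Coordinates are 0-based half-open (BED convention); a CpG is located by
## the position of its C on the forward strand.  `pattern` is a string over
## {0,1} (0 = unmethylated, 1 = methylated), one character per covered CpG
## in genomic order; `count` is the read multiplicity.

#' Construct a reference CpG site table
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions of the C of each CpG on
#'   the forward strand.
#' @return A `data.table` with columns `chrom` and `pos`, sorted by
#'   `(chrom, pos)`, with duplicates rejected.
#' @export
cpg_sites <- function(chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 0L)) {
    stop("CpG positions must be non-negative integers")
  }
  dt <- data.table(chrom = as.character(chrom), pos = pos)
  if (anyDuplicated(dt)) stop("duplicated (chrom, pos) in CpG site set")
  setkey(dt, chrom, pos)
  dt[]
}

## Split a site table into per-chromosome sorted position vectors.
site_index <- function(sites) {
  split(sites$pos, sites$chrom)
}

## For each record, the reference-site index range it covers (per-chrom,
## 1-based into the chromosome's sorted position vector).  A site at
## position p is covered iff start <= p < end.
record_site_span <- function(records, sites) {
  idx <- site_index(sites)
  i1 <- integer(nrow(records))
  i2 <- integer(nrow(records))
  for (ch in unique(records$chrom)) {
    sel <- which(records$chrom == ch)
    p <- idx[[ch]]
    if (is.null(p)) {
      i1[sel] <- 1L
      i2[sel] <- 0L
      next
    }
    i1[sel] <- findInterval(records$start[sel] - 1L, p) + 1L
    i2[sel] <- findInterval(records$end[sel] - 1L, p)
  }
  list(i1 = i1, i2 = i2)
}

validate_haplotype_fields <- function(dt, where = "record") {
  probs <- character(0)
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      sprintf("%s %s: %s", where, paste(head(i, 10), collapse = ","), msg)
    } else {
      character(0)
    }
  }
  probs <- c(
    probs,
    bad(is.na(dt$start) | is.na(dt$end) | dt$end <= dt$start,
        "end must be > start"),
    bad(!grepl("^[01]+$", dt$pattern), "pattern must be a non-empty 0/1 string"),
    bad(is.na(dt$count) | dt$count < 1L, "count must be a positive integer"),
    bad(!dt$strand %in% c("+", "-", "."), "strand must be one of +, -, .")
  )
  probs
}

#' Read an mHap-style methylation haplotype file
#'
#' Reads a tab-separated file of read-level methylation haplotypes
#' (columns: chrom, start, end, pattern, count, strand; `#` comment lines
#' and blank lines are ignored; `.gz` files are transparently
#' decompressed). Records are returned in canonical order, sorted by
#' `(chrom, start, end, pattern)`, so parsing is insensitive to input line
#' order.
#'
#' @param path path to the file.
#' @param reference_sites optional `data.table` from [cpg_sites()]; when
#'   supplied, each record's pattern length must equal the number of
#'   reference CpGs falling in `[start, end)`.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `pattern`,
#'   `count`, `strand`.
#' @export
read_haplotype_file <- function(path, reference_sites = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_haplotypes())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed haplotype line(s) (need >= 6 tab-separated fields) at line %s of %s",
                 paste(head(lineno[nf < 6L], 10), collapse = ","), path))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  dt <- data.table(
    chrom = m[, 1],
    start = suppressWarnings(as.integer(m[, 2])),
    end = suppressWarnings(as.integer(m[, 3])),
    pattern = m[, 4],
    count = suppressWarnings(as.integer(m[, 5])),
    strand = m[, 6]
  )
  probs <- validate_haplotype_fields(dt, where = "line")
  if (length(probs)) {
    ## report original line numbers, not row indices
    probs <- vapply(probs, function(p) {
      gsub("line ([0-9,]+):", "line", p)
    }, "")
    rows <- which(
      is.na(dt$start) | is.na(dt$end) | dt$end <= dt$start |
        !grepl("^[01]+$", dt$pattern) | is.na(dt$count) | dt$count < 1L |
        !dt$strand %in% c("+", "-", ".")
    )
    stop(sprintf("malformed haplotype record(s) at line %s of %s",
                 paste(head(lineno[rows], 10), collapse = ","), path))
  }
  if (!is.null(reference_sites)) {
    span <- record_site_span(dt, reference_sites)
    n_sites <- span$i2 - span$i1 + 1L
    bad <- which(n_sites != nchar(dt$pattern))
    if (length(bad)) {
      stop(sprintf(
        "pattern length does not match reference CpG count at line %s of %s (e.g. %s:%d-%d pattern '%s' vs %d reference CpGs)",
        paste(head(lineno[bad], 10), collapse = ","), path,
        dt$chrom[bad[1]], dt$start[bad[1]], dt$end[bad[1]],
        dt$pattern[bad[1]], n_sites[bad[1]]))
    }
  }
  setorder(dt, chrom, start, end, pattern, count, strand)
  dt[]
}

empty_haplotypes <- function() {
  data.table(chrom = character(0), start = integer(0), end = integer(0),
             pattern = character(0), count = integer(0), strand = character(0))
}

#' Write methylation haplotype records to an mHap-style file
#'
#' Records are validated and written sorted by `(chrom, start, end,
#' pattern)`; `read_haplotype_file(write_haplotype_file(x))` is the
#' identity on valid inputs.
#'
#' @param records a `data.table`/`data.frame` of haplotype records.
#' @param path output path (`.gz` writes gzip-compressed).
#' @return `path`, invisibly.
#' @export
write_haplotype_file <- function(records, path) {
  dt <- as.data.table(records)
  need <- c("chrom", "start", "end", "pattern", "count", "strand")
  if (!all(need %in% names(dt))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  probs <- validate_haplotype_fields(dt)
  if (length(probs)) stop("invalid haplotype record(s): ", probs[1])
  setorder(dt, chrom, start, end, pattern, count, strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   dt$chrom, dt$start, dt$end, dt$pattern, dt$count, dt$strand)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
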