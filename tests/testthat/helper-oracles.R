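## Independent brute-force oracles. These deliberately use naive
## enumeration (substring(), pairwise loops, exhaustive scans) and share
## no code with the implementation paths they check.

## Haplotype load by literal enumeration of every contiguous substring of
## every read, weighting substrings by read count; target = "1" for the
## methylated load, "0" for the unmethylated load.
load_bruteforce <- function(patterns, counts, k, target = "1") {
  Lmax <- max(nchar(patterns))
  num <- den <- numeric(Lmax)
  for (i in seq_along(patterns)) {
    p <- patterns[i]
    for (l in seq_len(nchar(p))) {
      for (s in seq_len(nchar(p) - l + 1)) {
        sub <- substring(p, s, s + l - 1)
        den[l] <- den[l] + counts[i]
        if (sub == strrep(target, l)) num[l] <- num[l] + counts[i]
      }
    }
  }
  use <- den > 0
  w <- (seq_len(Lmax)^k)[use]
  sum(w * num[use] / den[use]) / sum(w)
}

amf_bruteforce <- function(patterns, counts) {
  ones <- calls <- 0
  for (i in seq_along(patterns)) {
    ch <- strsplit(patterns[i], "")[[1]]
    ones <- ones + counts[i] * sum(ch == "1")
    calls <- calls + counts[i] * length(ch)
  }
  ones / calls
}

pdr_bruteforce <- function(patterns, counts, min_cpgs = 3) {
  num <- den <- 0
  for (i in seq_along(patterns)) {
    if (nchar(patterns[i]) < min_cpgs) next
    ch <- strsplit(patterns[i], "")[[1]]
    den <- den + counts[i]
    if (any(ch == "0") && any(ch == "1")) num <- num + counts[i]
  }
  if (den == 0) NA_real_ else num / den
}

## AUC by pairwise comparison with ties counting 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == "MTN"]
  neg <- scores[labels == "BTN"]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

## Best Youden J by exhaustive scan over a dense threshold set.
youden_scan_oracle <- function(scores, labels) {
  pos <- labels == "MTN"
  s <- sort(unique(scores))
  cand <- sort(unique(c(s, s - 1e-9, s + 1e-9, (s[-1] + s[-length(s)]) / 2,
                        min(s) - 1, max(s) + 1)))
  max(vapply(cand, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, 0))
}

## Exact two-sided Mann-Whitney p by full enumeration of rank
## assignments (no-tie case only).
mw_exact_p_enum <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  picks <- utils::combn(n, length(x))
  us <- apply(picks, 2, function(ix) sum(seq_len(n)[ix]) - length(x) * (length(x) + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

## Exhaustive MHB search: all maximal contiguous sub-runs (>= min_cpgs)
## of a site run in which every consecutive pair has defined r2 >= r2_min.
mhb_exhaustive_oracle <- function(haps, sites, run_pos, chrom, r2_min = 0.5,
                                  min_cpgs = 3, min_pairs = 10) {
  np <- length(run_pos)
  ok_pair <- function(i) {
    est <- pairwise_r2(haps, sites,
                       list(chrom = chrom, pos = run_pos[i]),
                       list(chrom = chrom, pos = run_pos[i + 1]),
                       min_pairs = min_pairs)
    est$defined && est$r2 >= r2_min
  }
  admissible <- list()
  for (a in seq_len(np)) for (b in a:np) {
    if (b - a + 1 < min_cpgs) next
    if (a == b || all(vapply(a:(b - 1), ok_pair, TRUE))) {
      admissible[[length(admissible) + 1]] <- c(a, b)
    }
  }
  ## maximal by inclusion
  keep <- Filter(function(ab) {
    !any(vapply(admissible, function(cd) {
      (cd[1] < ab[1] && cd[2] >= ab[2]) || (cd[1] <= ab[1] && cd[2] > ab[2])
    }, TRUE))
  }, admissible)
  lapply(keep, function(ab) run_pos[ab[1]:ab[2]])
}

## Random clipped-pattern block for metric oracles.
random_block <- function(L = sample(1:6, 1), n_reads = sample(1:8, 1)) {
  patterns <- character(n_reads)
  offsets <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    off <- sample(0:(L - 1), 1)
    len <- sample(1:(L - off), 1)
    patterns[i] <- paste(sample(c("0", "1"), len, replace = TRUE), collapse = "")
    offsets[i] <- off
  }
  block_haplotypes(patterns, sample(1:4, n_reads, replace = TRUE), offsets, L = L)
}

## Random valid haplotype records over a reference site set.
random_records <- function(n, sites) {
  idx <- split(seq_len(nrow(sites)), sites$chrom)
  rows <- lapply(seq_len(n), function(i) {
    ch <- sample(names(idx), 1)
    si <- sort(sample(idx[[ch]], min(length(idx[[ch]]), sample(1:4, 1))))
    si <- si[1]:si[length(si)]
    pos <- sites$pos[si]
    data.frame(chrom = ch, start = pos[1], end = pos[length(pos)] + 1L,
               pattern = paste(sample(c("0", "1"), length(pos), replace = TRUE),
                               collapse = ""),
               count = sample(1:5, 1), strand = sample(c("+", "-", "."), 1))
  })
  do.call(rbind, rows)
}

## Minimal two-group cohort from a feature matrix config: planted shift on
## the first `n_inf` columns.
planted_features <- function(n_per_group, p, n_inf, delta, sd = 1) {
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * p, sd = sd), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("f%02d", 1:p)))
  lab <- rep(c("BTN", "MTN"), each = n_per_group)
  x[lab == "MTN", seq_len(n_inf)] <- x[lab == "MTN", seq_len(n_inf)] + delta
  list(x = x, labels = setNames(lab, rownames(x)))
}
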