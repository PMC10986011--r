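test_that("haplotype loads match hand-derived substring enumeration", {
  bh <- block_haplotypes(c("110", "011"), c(1L, 1L), c(0L, 0L), L = 3)
  ## l=1: 4/6 methylated; l=2: 2/4; l=3: 0/2 -> (1*(4/6)+2*(1/2)+3*0)/6
  expect_equal(compute_mhl(bh, 1), 5 / 18, tolerance = 1e-12)
  expect_equal(compute_amf(bh), 4 / 6, tolerance = 1e-12)

  expect_equal(compute_mhl(block_haplotypes(c("111"), 2L, 0L, 3)), 1.0)
  expect_equal(compute_mhl(block_haplotypes(c("000"), 1L, 0L, 3)), 0.0)
  expect_equal(compute_umhl(block_haplotypes(c("000"), 3L, 0L, 3)), 1.0)
  expect_equal(compute_umhl(block_haplotypes(c("111"), 1L, 0L, 3)), 0.0)
  expect_equal(compute_amf(block_haplotypes(rep("1", 10), rep(1L, 10), rep(0L, 10), 1)), 1.0)
  expect_equal(compute_amf(block_haplotypes("10", 1L, 0L, 2)), 0.5)
})

test_that("PDR counts only eligible reads and flags none-eligible as missing", {
  bh <- block_haplotypes(c("110", "011", "111", "000"), rep(1L, 4), rep(0L, 4), 3)
  expect_equal(compute_pdr(bh, 3), 0.5)
  expect_equal(compute_pdr(block_haplotypes(rep("1111", 5), rep(1L, 5), rep(0L, 5), 4)), 0)
  ## only length-2 clipped reads with a 3-CpG floor -> missing
  bh2 <- block_haplotypes(c("10", "01"), c(1L, 1L), c(0L, 1L), 3)
  expect_true(is.na(compute_pdr(bh2, 3)))
})

test_that("coverage is mean per-CpG depth in X", {
  expect_equal(block_coverage(block_haplotypes(rep("111", 10), rep(1L, 10), rep(0L, 10), 3)), 10)
  expect_equal(block_coverage(block_haplotypes(rep("10", 10), rep(1L, 10), rep(0L, 10), 3)), 20 / 3)
  expect_equal(block_coverage(block_haplotypes(character(0), integer(0), integer(0), 3)), 0)
})

test_that("metrics agree with brute-force oracles on random blocks", {
  set.seed(11)
  for (i in 1:150) {
    bh <- random_block()
    expect_equal(compute_mhl(bh, 1),
                 load_bruteforce(bh$patterns, bh$counts, 1, "1"), tolerance = 1e-12)
    expect_equal(compute_mhl(bh, 3),
                 load_bruteforce(bh$patterns, bh$counts, 3, "1"), tolerance = 1e-12)
    expect_equal(compute_umhl(bh, 1),
                 load_bruteforce(bh$patterns, bh$counts, 1, "0"), tolerance = 1e-12)
    expect_equal(compute_amf(bh), amf_bruteforce(bh$patterns, bh$counts),
                 tolerance = 1e-12)
    expect_equal(compute_pdr(bh, 3), pdr_bruteforce(bh$patterns, bh$counts, 3),
                 tolerance = 1e-12)
  }
})

test_that("UMHL equals MHL of the bit-complemented patterns", {
  set.seed(23)
  flip <- function(p) chartr("01", "10", p)
  for (i in 1:200) {
    bh <- random_block()
    bhc <- block_haplotypes(flip(bh$patterns), bh$counts, bh$offsets, bh$L)
    for (k in c(1, 3)) {
      expect_equal(compute_umhl(bh, k), compute_mhl(bhc, k), tolerance = 1e-12)
    }
  }
})

test_that("single-CpG blocks collapse to AMF = MHL = 1 - UMHL", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    bh <- block_haplotypes(sample(c("0", "1"), n, replace = TRUE),
                           sample(1:4, n, replace = TRUE), rep(0L, n), 1)
    expect_equal(compute_mhl(bh), compute_amf(bh))
    expect_equal(compute_umhl(bh), 1 - compute_amf(bh))
  }
})

test_that("reads are clipped to block CpG indices", {
  sites <- cpg_sites("chr1", c(100, 104, 108, 112))
  blocks <- mhb_set_from_regions(
    data.frame(chrom = "chr1", start = 104L, end = 109L, name = "B1"), sites)
  ## read over CpGs 1..4 restricted to block CpGs {104, 108} -> "10"
  reads <- data.frame(chrom = "chr1", start = 100L, end = 113L,
                      pattern = "1101", count = 3L, strand = ".")
  bh <- extract_block_haplotypes(reads, blocks, "B1", sites)
  expect_equal(bh$patterns, "10")
  expect_equal(bh$counts, 3L)
  expect_equal(bh$offsets, 0L)
  ## disjoint read contributes nothing
  far <- data.frame(chrom = "chr1", start = 112L, end = 113L, pattern = "1",
                    count = 1L, strand = ".")
  expect_length(extract_block_haplotypes(far, blocks, "B1", sites)$patterns, 0)
})

test_that("the vectorized matrix agrees with the per-block functions", {
  set.seed(19)
  sim <- simulate_cohort(sim_config(
    n_blocks = 12, cohorts = list(discovery = c(BTN = 5, MTN = 5)),
    concordance = 0.6, read_full_prob = 0.6, seed = 19))
  pooled <- data.table::rbindlist(sim$cohort$haplotypes)
  mhbs <- call_mhbs(pooled, sim$sites, min_cpgs = 2)
  mm <- build_metric_matrix(sim$cohort, mhbs, sim$sites)
  for (s in sample(sim$cohort$samples$sample_id, 4)) {
    for (b in sample(mhbs$block_id, 4)) {
      bh <- extract_block_haplotypes(sim$cohort$haplotypes[[s]], mhbs, b, sim$sites)
      mv <- compute_metric_vector(bh)
      got <- mm$values[s, paste(b, names(mv), sep = ":")]
      expect_equal(unname(got), unname(mv), tolerance = 1e-12)
      expect_equal(mm$coverage[s, b], block_coverage(bh), tolerance = 1e-12)
    }
  }
})

test_that("metric matrices are shaped, deterministic, bounded, NA-explicit", {
  set.seed(7)
  sim <- simulate_cohort(sim_config(
    n_blocks = 10, cohorts = list(discovery = c(BTN = 6, MTN = 6)),
    dropout = 0.3, seed = 7))
  pooled <- data.table::rbindlist(sim$cohort$haplotypes)
  mhbs <- call_mhbs(pooled, sim$sites, min_cpgs = 2)
  mm1 <- build_metric_matrix(sim$cohort, mhbs, sim$sites)
  mm2 <- build_metric_matrix(sim$cohort, mhbs, sim$sites)
  expect_identical(mm1, mm2)
  expect_equal(dim(mm1$values), c(12L, nrow(mhbs) * 6L))
  expect_equal(dim(mm1$coverage), c(12L, nrow(mhbs)))
  v <- mm1$values[!is.na(mm1$values)]
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(mm1$coverage >= 0))
  ## dropout must appear as explicit missingness, and NA never leaks to file
  expect_true(anyNA(mm1$values))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metric_matrix(mm1, f)
  expect_false(any(grepl("NaN", readLines(f))))

  ## a sample with zero haplotypes yields an all-missing row plus warning
  sim$cohort$samples <- rbind(sim$cohort$samples,
                              data.frame(sample_id = "GHOST", label = "BTN",
                                         cohort = "discovery", age = 50,
                                         sex = "F", tirads = 3, size_mm = 10))
  sim$cohort$haplotypes$GHOST <- NULL
  expect_warning(mm3 <- build_metric_matrix(sim$cohort, mhbs, sim$sites), "GHOST")
  expect_true(all(is.na(mm3$values["GHOST", ])))
})
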