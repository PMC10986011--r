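## Synthetic bisulfite-haplotype cohorts with planted ground truth.
##
## Generative model, per sample and block: a methylation probability p is
## drawn from the block's group-specific Beta distribution; read depth is
## negative-binomial with block dropout; within a read the first CpG is
## Bernoulli(p) and each subsequent CpG copies its left neighbour with
## probability `concordance`, else resamples Bernoulli(p) (a Markov chain
## giving bimodal, haplotype-structured reads as concordance -> 1 and
## noisy reads as it -> 0). Clinical covariates (TI-RADS, nodule size,
## age, sex) are sampled conditionally on the true label. Everything is
## driven by one seed and is exactly reproducible.

#' Simulation configuration
#'
#' @param n_blocks number of CpG blocks.
#' @param cpg_range inclusive range of CpGs per block.
#' @param cohorts named list of per-split class counts
#'   (`c(BTN = ..., MTN = ...)`); the default mirrors a three-phase
#'   discovery/validation/test design of 59/49, 55/42 and 53/35.
#' @param n_differential number of blocks with a planted group shift.
#' @param delta group mean shift on the methylation probability.
#' @param effect_scale `"linear"` (probability scale, default) or
#'   `"logit"`.
#' @param concentration Beta concentration of the per-sample methylation
#'   probability around the block mean.
#' @param concordance within-read Markov copy probability in `[0, 1]`.
#' @param depth_mean,depth_size negative-binomial reads-per-block mean and
#'   dispersion (size).
#' @param depth_max depth clip.
#' @param dropout probability a (sample, block) pair yields no reads.
#' @param read_full_prob probability a read spans the whole block
#'   (otherwise a random contiguous sub-window).
#' @param tirads_probs per-label category probabilities over TI-RADS 1-5
#'   (defaults loosely mimic a high-sensitivity, moderate-specificity
#'   ultrasonography operating point).
#' @param size_meanlog,size_sdlog log-normal nodule diameter (mm).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_blocks = 150, cpg_range = c(3, 8),
                       cohorts = list(discovery = c(BTN = 59, MTN = 49),
                                      validation = c(BTN = 55, MTN = 42),
                                      test = c(BTN = 53, MTN = 35)),
                       n_differential = min(25, floor(n_blocks / 6)),
                       delta = 0.2,
                       effect_scale = c("linear", "logit"),
                       concentration = 15, concordance = 0.9,
                       depth_mean = 30, depth_size = 5, depth_max = 1000,
                       dropout = 0.05, read_full_prob = 0.8,
                       tirads_probs = list(
                         MTN = c(0.01, 0.01, 0.02, 0.40, 0.56),
                         BTN = c(0.05, 0.15, 0.25, 0.35, 0.20)),
                       size_meanlog = log(12), size_sdlog = 0.5,
                       seed = 1) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_differential <= n_blocks, delta >= 0,
            concordance >= 0, concordance <= 1,
            dropout >= 0, dropout <= 1, depth_mean >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Named benchmark scenario presets
#'
#' All presets use the three-phase cohort sizes (59/49, 55/42, 53/35) and
#' differ only in difficulty: `paper_shaped` (delta 0.2), `easy`
#' (delta 0.3), `null` (no differential blocks), `hard` (delta 0.1 at
#' 10X depth).
#'
#' @param seed seed stored into every preset.
#' @return Named list of `sim_config`s.
#' @export
benchmark_scenarios <- function(seed = 1) {
  list(
    paper_shaped = sim_config(delta = 0.2, seed = seed),
    easy = sim_config(delta = 0.3, seed = seed),
    null = sim_config(delta = 0, n_differential = 0, seed = seed),
    hard = sim_config(delta = 0.1, depth_mean = 10, seed = seed)
  )
}

clip01 <- function(x, eps = 0.02) pmin(1 - eps, pmax(eps, x))

#' Simulate a synthetic cohort with planted truth
#'
#' @param config a [sim_config()].
#' @return A list (class `sim_cohort`) with `cohort` (list of `samples`
#'   sheet + per-sample `haplotypes`), `sites` (reference CpG table) and
#'   `truth` (block table with per-group means and differential flags,
#'   plus the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_blocks

  ## --- block layout over a few chromosomes, runs separated by > 200 bp
  chroms <- paste0("chr", ((seq_len(nb) - 1L) %% 5L) + 1L)
  L <- sample(config$cpg_range[1]:config$cpg_range[2], nb, replace = TRUE)
  pos_list <- vector("list", nb)
  cursor <- setNames(rep(10000L, 5L), paste0("chr", 1:5))
  for (b in seq_len(nb)) {
    ch <- chroms[b]
    gaps <- if (L[b] > 1) sample(2:40, L[b] - 1L, replace = TRUE) else integer(0)
    pos_list[[b]] <- cursor[ch] + c(0L, cumsum(gaps))
    cursor[ch] <- pos_list[[b]][L[b]] + 1000L
  }
  sites <- cpg_sites(rep(chroms, L), unlist(pos_list))

  ## --- planted truth: baseline means and group shifts
  comp <- runif(nb) < 0.5
  mu0 <- clip01(ifelse(comp, rbeta(nb, 2, 6), rbeta(nb, 6, 2)))
  differential <- rep(FALSE, nb)
  if (config$n_differential > 0) {
    differential[sample(nb, config$n_differential)] <- TRUE
  }
  shift_sign <- sample(c(-1, 1), nb, replace = TRUE)
  mu_btn <- mu0
  mu_mtn <- mu0
  if (config$delta > 0) {
    d <- ifelse(differential, config$delta, 0)
    if (config$effect_scale == "linear") {
      cand <- mu0 + shift_sign * d
      flip <- cand < 0.02 | cand > 0.98
      cand[flip] <- mu0[flip] - shift_sign[flip] * d[flip]
      out_of_range <- cand < 0.02 | cand > 0.98
      if (any(out_of_range)) {
        warning("clipped ", sum(out_of_range), " shifted block mean(s) into [0.02, 0.98]")
      }
      mu_mtn <- clip01(cand)
    } else {
      lg <- stats::qlogis(mu0) + shift_sign * d * 4  # delta on ~comparable scale
      mu_mtn <- ifelse(differential, clip01(stats::plogis(lg)), mu0)
    }
  }

  ## --- samples and clinical covariates
  meta <- rbindlist(lapply(names(config$cohorts), function(split) {
    cnt <- config$cohorts[[split]]
    lab <- rep(names(cnt), cnt)
    n <- length(lab)
    data.table(
      sample_id = sprintf("%s_%s_%03d", substr(split, 1, 3), lab,
                          unlist(lapply(cnt, seq_len))),
      label = lab, cohort = split,
      age = pmin(85, pmax(18, round(rnorm(n, 48, 12)))),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.75, 0.25)),
      tirads = vapply(lab, function(l)
        sample(1:5, 1, prob = config$tirads_probs[[l]]), 0L),
      size_mm = round(rlnorm(n, config$size_meanlog, config$size_sdlog), 1)
    )
  }))
  ns <- nrow(meta)
  grp_mtn <- meta$label == "MTN"

  ## --- reads, block by block (vectorized across all reads of a block)
  rec_list <- vector("list", nb)
  for (b in seq_len(nb)) {
    mu <- ifelse(grp_mtn, mu_mtn[b], mu_btn[b])
    p <- rbeta(ns, mu * config$concentration, (1 - mu) * config$concentration)
    depth <- rnbinom(ns, size = config$depth_size, mu = config$depth_mean)
    depth <- pmin(depth, config$depth_max)
    depth[runif(ns) < config$dropout] <- 0L
    N <- sum(depth)
    if (N == 0L) next
    pr <- rep(p, depth)
    Lb <- L[b]
    M <- matrix(0L, N, Lb)
    M[, 1] <- rbinom(N, 1L, pr)
    if (Lb > 1) for (k in 2:Lb) {
      copy <- runif(N) < config$concordance
      M[, k] <- ifelse(copy, M[, k - 1L], rbinom(N, 1L, pr))
    }
    full <- runif(N) < config$read_full_prob
    off <- ifelse(full, 0L, floor(runif(N) * Lb))
    rlen <- ifelse(full, Lb, 1L + floor(runif(N) * (Lb - off)))
    pat_full <- do.call(paste0, as.data.frame(M))
    posb <- pos_list[[b]]
    rec_list[[b]] <- data.table(
      sample_id = rep(meta$sample_id, depth),
      chrom = chroms[b],
      start = posb[off + 1L],
      end = posb[off + rlen] + 1L,
      pattern = substr(pat_full, off + 1L, off + rlen)
    )
  }
  recs <- rbindlist(rec_list)
  recs <- recs[, .(count = .N), by = .(sample_id, chrom, start, end, pattern)]
  recs[, strand := "."]
  setorder(recs, sample_id, chrom, start, end, pattern)
  haps <- split(recs[, .(chrom, start, end, pattern, count, strand)],
                recs$sample_id)
  ## samples with zero reads everywhere still get an (empty) table
  for (s in setdiff(meta$sample_id, names(haps))) haps[[s]] <- empty_haplotypes()
  haps <- haps[meta$sample_id]

  truth_blocks <- data.table(
    truth_id = sprintf("TRUE_BLK_%04d", seq_len(nb)),
    chrom = chroms,
    start = vapply(pos_list, `[`, 0L, 1L),
    end = vapply(seq_len(nb), function(b) pos_list[[b]][L[b]] + 1L, 0L),
    n_cpgs = L, differential = differential,
    mu_btn = mu_btn, mu_mtn = mu_mtn
  )

  structure(list(
    cohort = list(samples = as.data.frame(meta), haplotypes = haps),
    sites = sites,
    truth = list(blocks = truth_blocks, config = config)
  ), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits `haplotypes/<sample_id>.mhap.tsv` per sample, `samples.tsv`,
#' `sites.bed`, and `truth.json`; [read_cohort()] reproduces the cohort
#' exactly, and the same seed writes byte-identical files.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory.
#' @param force overwrite a non-empty directory?
#' @export
write_cohort <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory not empty (use force = TRUE): ", dir)
  }
  dir.create(file.path(dir, "haplotypes"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$cohort$haplotypes)) {
    write_haplotype_file(sim$cohort$haplotypes[[s]],
                         file.path(dir, "haplotypes", paste0(s, ".mhap.tsv")))
  }
  write_sample_sheet(sim$cohort$samples, file.path(dir, "samples.tsv"))
  writeLines(sprintf("%s\t%d\t%d", sim$sites$chrom, sim$sites$pos,
                     sim$sites$pos + 1L), file.path(dir, "sites.bed"))
  truth <- list(blocks = as.data.frame(sim$truth$blocks),
                config = unclass(sim$truth$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a cohort written by [write_cohort()]
#' @param dir directory written by [write_cohort()].
#' @return A `sim_cohort` (config restored from `truth.json`).
#' @export
read_cohort <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  bed <- fread(file.path(dir, "sites.bed"), header = FALSE)
  sites <- cpg_sites(bed[[1]], bed[[2]])
  haps <- lapply(samples$sample_id, function(s) {
    read_haplotype_file(file.path(dir, "haplotypes", paste0(s, ".mhap.tsv")),
                        reference_sites = sites)
  })
  names(haps) <- samples$sample_id
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cfg <- truth$config
  truth$blocks <- as.data.table(truth$blocks)
  truth$config <- structure(cfg, class = "sim_config")
  structure(list(cohort = list(samples = samples, haplotypes = haps),
                 sites = sites, truth = truth),
            class = "sim_cohort")
}

#' Fraction of planted differential blocks recovered by the screen
#'
#' A planted block counts as recovered iff some screened marker's called
#' block overlaps it.
#'
#' @param screen output of [screen_markers()] (or a `model_bundle`'s
#'   `screen` element).
#' @param mhbs the called `mhb_set` the screen ran on.
#' @param truth the `truth` element of a `sim_cohort`.
#' @return Recall in `[0, 1]` (`NA` when nothing was planted).
#' @export
planted_marker_recall <- function(screen, mhbs, truth) {
  tb <- truth$blocks[truth$blocks$differential, , drop = FALSE]
  if (!nrow(tb)) return(NA_real_)
  hit <- mhbs[mhbs$block_id %in% screen$block_id, , drop = FALSE]
  rec <- vapply(seq_len(nrow(tb)), function(i) {
    any(hit$chrom == tb$chrom[i] & hit$start < tb$end[i] & hit$end > tb$start[i])
  }, TRUE)
  mean(rec)
}

#' Run the whole pipeline on a simulated (or loaded) cohort
#'
#' Calls MHBs on the pooled discovery reads, freezes them, computes the
#' metric matrix for every sample, and fits the diagnostic model on the
#' discovery split.
#'
#' @param sim a `sim_cohort` (or any list with `cohort` and `sites`).
#' @param config pipeline configuration ([default_config()]).
#' @param seed integer seed for the model-fitting stages.
#' @return List with `mhbs`, `metrics` (the `metric_matrix`) and `bundle`.
#' @export
fit_pipeline <- function(sim, config = default_config(), seed = 1) {
  samples <- sim$cohort$samples
  disc <- samples$sample_id[samples$cohort == "discovery"]
  pooled <- rbindlist(sim$cohort$haplotypes[disc])
  mhbs <- call_mhbs(pooled, sim$sites, r2_min = config$r2_min,
                    min_cpgs = config$min_cpgs, min_pairs = config$min_pairs,
                    max_gap_bp = config$max_gap_bp)
  if (!nrow(mhbs)) stop("no blocks called on the discovery reads")
  mm <- build_metric_matrix(sim$cohort, mhbs, sim$sites,
                            mhl_exponent = config$mhl_exponent,
                            mhl3_exponent = config$mhl3_exponent,
                            pdr_min_cpgs = config$pdr_min_cpgs)
  bundle <- fit_diagnostic_model(mm, samples, config = config, seed = seed)
  list(mhbs = mhbs, metrics = mm, bundle = bundle)
}
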