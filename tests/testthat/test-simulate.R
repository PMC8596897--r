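test_that("truth simulation is seeded, bounded and same-type overlap-free", {
  cfg <- sim_config(seed = 3, genome = c(chr1 = 5e6, chr2 = 5e6),
                    n_variants = 200)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 200)
  expect_true(all(t1$end - t1$start >= cfg$size_range[1]))
  expect_true(all(t1$end - t1$start <= cfg$size_range[2]))
  # brute-force pairwise same-type overlap count
  n_overlap <- 0
  for (i in seq_len(nrow(t1) - 1)) for (j in (i + 1):nrow(t1)) {
    if (t1$type[i] == t1$type[j] && t1$chrom[i] == t1$chrom[j] &&
        t1$start[i] < t1$end[j] && t1$start[j] < t1$end[i]) {
      n_overlap <- n_overlap + 1
    }
  }
  expect_equal(n_overlap, 0)

  cfg0 <- sim_config(seed = 3, n_variants = 0)
  expect_equal(nrow(simulate_truth(cfg0)), 0)
  expect_error(sim_config(), "seed")
})

test_that("copy numbers follow type and genotype on the diploid baseline", {
  cfg <- sim_config(seed = 9, n_variants = 100, het_frac = 0.5)
  tr <- simulate_truth(cfg)
  expect_equal(tr$copy_number[tr$type == "DEL" & tr$genotype == "het"],
               rep(1L, sum(tr$type == "DEL" & tr$genotype == "het")))
  expect_equal(unique(tr$copy_number[tr$type == "DEL" &
                                       tr$genotype == "hom"]), 0L)
  expect_equal(unique(tr$copy_number[tr$type == "DUP" &
                                       tr$genotype == "het"]), 3L)
  expect_equal(unique(tr$copy_number[tr$type == "DUP" &
                                       tr$genotype == "hom"]), 4L)
})

test_that("noise-free callsets reproduce truth; sensitivity 0 leaves only
           false calls", {
  cfg <- tiny_sim_config(seed = 4)
  truth <- simulate_truth(cfg)
  perfect <- data.frame(dataset = "d1", technology = "sr",
                        sensitivity = 1, fp_per_mb = 0, jitter_sd = 0,
                        fp_min = 600, fp_max = 5000,
                        stringsAsFactors = FALSE)
  calls <- simulate_callsets(truth, cfg, perfect)
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(sort(calls$start), sort(truth$start))
  expect_equal(sort(calls$end), sort(truth$end))
  expect_true(all(!is.na(calls$truth_id)))

  blind <- perfect
  blind$sensitivity <- 0; blind$fp_per_mb <- 5
  fps <- simulate_callsets(truth, cfg, blind)
  expect_true(all(is.na(fps$truth_id)))
})

test_that("every true-positive call overlaps its source truth variant", {
  cfg <- sim_config(seed = 12)
  truth <- simulate_truth(cfg)
  calls <- simulate_callsets(truth, cfg)
  tp <- calls[!is.na(calls$truth_id), ]
  src <- truth[match(tp$truth_id, truth$truth_id), ]
  expect_true(all(tp$chrom == src$chrom))
  expect_true(all(tp$start < src$end & src$start < tp$end))
})

test_that("breakpoint jitter magnitude matches the half-normal mean", {
  cfg <- sim_config(seed = 21, genome = c(chr1 = 2e7), n_variants = 500,
                    size_range = c(5000, 20000))
  truth <- simulate_truth(cfg)
  spec <- data.frame(dataset = "d1", technology = "sr", sensitivity = 1,
                     fp_per_mb = 0, jitter_sd = 50, fp_min = 600,
                     fp_max = 5000, stringsAsFactors = FALSE)
  calls <- simulate_callsets(truth, cfg, spec)
  src <- truth[match(calls$truth_id, truth$truth_id), ]
  offsets <- abs(c(calls$start - src$start, calls$end - src$end))
  # E|N(0, sd)| = sd * sqrt(2/pi); sd of |N| = sd * sqrt(1 - 2/pi)
  mu <- 50 * sqrt(2 / pi)
  se <- 50 * sqrt(1 - 2 / pi) / sqrt(length(offsets))
  expect_lt(abs(mean(offsets) - mu), 3 * se + 0.5)  # 0.5 for rounding
})

test_that("noise-free LRR sits exactly on the copy-number shifts", {
  cfg <- sim_config(seed = 5, genome = c(chr1 = 1e6), n_variants = 4,
                    size_range = c(20000, 50000), lrr_sd = 0,
                    het_frac = 1, probe_spacing = c(chipA = 500))
  truth <- simulate_truth(cfg)
  arr <- simulate_array(truth, cfg)$chipA
  pm <- arr$probes
  lrr <- arr$lrr$lrr[match(pm$probe_id, arr$lrr$probe_id)]
  for (i in seq_len(nrow(truth))) {
    inside <- pm$chrom == truth$chrom[i] &
      pm$position >= truth$start[i] & pm$position < truth$end[i]
    expected <- if (truth$type[i] == "DEL") -0.5 else 0.3
    expect_true(all(abs(lrr[inside] - expected) < 1e-12))
  }
  outside <- rep(TRUE, nrow(pm))
  for (i in seq_len(nrow(truth))) {
    outside <- outside & !(pm$chrom == truth$chrom[i] &
                             pm$position >= truth$start[i] &
                             pm$position < truth$end[i])
  }
  expect_true(all(lrr[outside] == 0))
})

test_that("background LRR noise mean obeys the CLT bound", {
  cfg <- sim_config(seed = 6, genome = c(chr1 = 5e6), n_variants = 0,
                    lrr_sd = 0.2, probe_spacing = c(chipA = 500))
  truth <- simulate_truth(cfg)
  arr <- simulate_array(truth, cfg)$chipA
  n <- nrow(arr$lrr)
  expect_gt(n, 9000)
  expect_lt(abs(mean(arr$lrr$lrr)), 3 * 0.2 / sqrt(n))
})

test_that("depth follows Poisson(coverage x cn / 2) in every truth state", {
  cfg <- sim_config(seed = 8, genome = c(chr1 = 5e6), n_variants = 6,
                    size_range = c(100000, 200000), coverage = 30,
                    del_frac = 0.5, het_frac = 1)
  truth <- simulate_truth(cfg)
  track <- simulate_depth(truth, cfg)
  check_mean <- function(bins, lambda) {
    n <- length(bins)
    expect_gt(n, 500)
    expect_lt(abs(mean(bins) - lambda), 3 * sqrt(lambda / n))
  }
  for (i in seq_len(nrow(truth))) {
    inside <- track$chrom == truth$chrom[i] &
      track$start >= truth$start[i] & track$end <= truth$end[i]
    lambda <- 30 * truth$copy_number[i] / 2
    check_mean(track$depth[inside], lambda)
  }
})

test_that("hom deletion expectation is zero depth", {
  cfg <- sim_config(seed = 13, genome = c(chr1 = 1e6), n_variants = 1,
                    size_range = c(50000, 80000), het_frac = 0)
  truth <- simulate_truth(cfg)
  expect_equal(truth$copy_number, ifelse(truth$type == "DEL", 0L, 4L))
  if (truth$type[1] == "DEL") {
    track <- simulate_depth(truth, cfg)
    inside <- track$chrom == truth$chrom[1] &
      track$start >= truth$start[1] & track$end <= truth$end[1]
    expect_true(all(track$depth[inside] == 0))
  }
})

test_that("long-read genotyping is exact at error 0 and calibrated at 0.1", {
  cfg <- sim_config(seed = 14, genome = c(chr1 = 5e7), n_variants = 1000,
                    size_range = c(600, 5000))
  truth <- simulate_truth(cfg)
  gt0 <- simulate_lr_genotypes(truth, truth, error_rate = 0, seed = 1)
  expected <- ifelse(truth$genotype == "het", "0/1", "1/1")
  expect_equal(gt0$genotype, expected)

  off <- data.frame(chrom = "chr1", start = 49.5e6, end = 49.6e6,
                    type = "DEL", stringsAsFactors = FALSE)
  off_gt <- simulate_lr_genotypes(off, truth[truth$end < 49e6, ],
                                  error_rate = 0, seed = 2)
  expect_true(off_gt$genotype %in% c("0/0", "NA"))

  gt10 <- simulate_lr_genotypes(truth, truth, error_rate = 0.1, seed = 3)
  conc <- mean(gt10$genotype == expected)
  expect_lt(abs(conc - 0.9), 3 * sqrt(0.9 * 0.1 / nrow(truth)))
})

test_that("synthetic databases respect inclusion and Beta frequencies", {
  cfg <- sim_config(seed = 15, genome = c(chr1 = 5e7), n_variants = 500,
                    size_range = c(600, 5000),
                    databases = list(
                      all_in = list(inclusion = 1, jitter_sd = 0,
                                    freq_shape = c(1, 9)),
                      none = list(inclusion = 0, jitter_sd = 0,
                                  freq_shape = c(1, 9))))
  truth <- simulate_truth(cfg)
  dbs <- simulate_database(truth, cfg)
  expect_equal(nrow(dbs$all_in), nrow(truth))
  expect_equal(sort(dbs$all_in$start), sort(truth$start))
  expect_equal(nrow(dbs$none), 0)
  # Beta(1, 9): mean 0.1, var = 1*9 / (10^2 * 11)
  se <- sqrt(9 / (100 * 11) / nrow(truth))
  expect_lt(abs(mean(dbs$all_in$frequency) - 0.1), 3 * se)
})

test_that("the full input bundle is deterministic under one seed", {
  cfg <- tiny_sim_config(seed = 99)
  b1 <- simulate_inputs(cfg)
  b2 <- simulate_inputs(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$calls, b2$calls)
  expect_identical(b1$depth$depth, b2$depth$depth)
  expect_identical(as.character(b1$genome_seq), as.character(b2$genome_seq))
  expect_identical(b1$databases, b2$databases)
  expect_identical(b1$annotations, b2$annotations)
})
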