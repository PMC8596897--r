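test_that("Hellinger distance: identity, disjoint supports, closed form", {
  x <- rnorm(50)
  expect_equal(hellinger_distance(x, x), 0)
  expect_equal(hellinger_distance(rep(-5, 40), rep(0, 40)), 1)
  expect_equal(hellinger_distance(rep(1, 10), rep(1, 10)), 0)
  # forced histograms p = (0.5, 0.5), q = (1, 0) with two bins:
  # sqrt(1 - sqrt(0.5))
  expect_equal(hellinger_distance(c(0, 1), c(0, 0), n_bins = 2),
               sqrt(1 - sqrt(0.5)))
  expect_error(hellinger_distance(numeric(0), 1), "empty")
})

test_that("Hellinger distance is symmetric and within [0, 1] on random
           samples", {
  set.seed(91)
  for (k in 1:25) {
    a <- rnorm(sample(5:200, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.1, 2))
    b <- rnorm(sample(5:200, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.1, 2))
    d1 <- hellinger_distance(a, b)
    expect_equal(d1, hellinger_distance(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("Hellinger matches an independent Bhattacharyya implementation
           to 1e-12", {
  set.seed(7)
  inside <- rnorm(200, -0.5, 0.2)
  flank <- rnorm(200, 0, 0.2)
  expect_equal(hellinger_distance(inside, flank, n_bins = 20),
               bf_hellinger(inside, flank, n_bins = 20),
               tolerance = 1e-12)
  for (k in 1:10) {
    a <- runif(100); b <- rnorm(150, 0.5, 0.3)
    expect_equal(hellinger_distance(a, b), bf_hellinger(a, b),
                 tolerance = 1e-12)
  }
})

test_that("array evidence contrasts in-region and flanking probe LRR", {
  pm <- probe_map(data.frame(probe_id = paste0("p", 1:200),
                             chrom = "chr1",
                             position = seq(100, by = 100,
                                            length.out = 200)),
                  "chipT")
  # region covering probes 51..100; identical LRR everywhere -> 0
  lrr <- data.frame(probe_id = pm$probe_id, lrr = 0.25)
  ev <- array_evidence("chr1", 5001, 10001, pm, lrr)
  expect_equal(ev$hellinger, 0)
  expect_equal(ev$median_lrr, 0.25)
  expect_equal(ev$n_inside, 50)

  # disjoint LRR: inside -5, flanks 0 -> 1
  inside_ids <- pm$probe_id[pm$position >= 5001 & pm$position < 10001]
  lrr2 <- lrr
  lrr2$lrr <- ifelse(lrr$probe_id %in% inside_ids, -5, 0)
  ev2 <- array_evidence("chr1", 5001, 10001, pm, lrr2)
  expect_equal(ev2$hellinger, 1)
  expect_equal(ev2$median_lrr, -5)

  # too few in-region probes -> null record with reason
  ev3 <- array_evidence("chr1", 5001, 5300, pm, lrr)
  expect_true(is.na(ev3$hellinger))
  expect_equal(ev3$reason, "too_few_probes")
})

test_that("array evidence uses the 50 nearest probes per flank,
           truncated at ends", {
  pm <- probe_map(data.frame(probe_id = paste0("p", 1:30),
                             chrom = "chr1",
                             position = seq(100, by = 100,
                                            length.out = 30)),
                  "chipT")
  lrr <- data.frame(probe_id = pm$probe_id,
                    lrr = seq(0.01, 0.30, by = 0.01))
  # region over probes 11..20; flanks truncate to 10 + 10 probes
  ev <- array_evidence("chr1", 1001, 2001, pm, lrr, n_flank_probes = 50)
  expect_false(is.na(ev$hellinger))
  # with n_flank_probes = 3, flank = probes 8,9,10 and 21,22,23
  ev3 <- array_evidence("chr1", 1001, 2001, pm, lrr, n_flank_probes = 3)
  flank_vals <- lrr$lrr[c(8:10, 21:23)]
  inside_vals <- lrr$lrr[11:20]
  expect_equal(ev3$hellinger,
               hellinger_distance(inside_vals, flank_vals))
})

test_that("long-read genotype concordance follows the supporting-genotype
           rule", {
  expect_equal(longread_concordance(c("1/1", "0/1", "0/0", "NA")),
               c("concordant", "concordant", "discordant", "discordant"))
  expect_error(longread_concordance("2/1"), "unknown genotype")
})

test_that("probe counts use half-open intervals and report zeros", {
  pm <- probe_map(data.frame(probe_id = c("a", "b", "c"),
                             chrom = "chr1",
                             position = c(100, 200, 300)), "chip1")
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(100, 301, 0),
                        end = c(300, 400, 1000))
  counts <- probe_coverage(regions, list(chip1 = pm))
  # probe at start counted, probe at end excluded; empty -> 0
  expect_equal(counts$n_probes_chip1, c(2, 0, 0))

  set.seed(95)
  pm2 <- probe_map(data.frame(probe_id = paste0("p", 1:500),
                              chrom = sample(c("chr1", "chr2"), 500,
                                             replace = TRUE),
                              position = floor(runif(500, 0, 1e5))),
                   "chip2")
  start <- floor(runif(40, 0, 9e4))
  regions2 <- data.frame(chrom = sample(c("chr1", "chr2"), 40,
                                        replace = TRUE),
                         start = start, end = start + 5000)
  counts2 <- probe_coverage(regions2, list(chip2 = pm2))$n_probes_chip2
  oracle <- vapply(seq_len(40), function(i)
    sum(pm2$chrom == regions2$chrom[i] &
          pm2$position >= regions2$start[i] &
          pm2$position < regions2$end[i]), numeric(1))
  expect_equal(counts2, oracle)
})

test_that("database lookup applies the one-directional 50% rule with
           stated tie-breaking", {
  db <- data.frame(db_id = "d", chrom = "chr1",
                   start = c(1000, 1000, 900), end = c(2000, 1490, 2100),
                   type = c("DEL", "DEL", "DUP"),
                   frequency = c(0.12, 0.30, 0.50),
                   stringsAsFactors = FALSE)
  # identical record qualifies at freq 0.12
  r <- database_lookup("chr1", 1000, 2000, "DEL", db)
  expect_true(r$present); expect_equal(r$frequency, 0.12)
  # 49% overlap fails
  r49 <- database_lookup("chr1", 1000, 2000, "DEL",
                         db[db$end == 1490, , drop = FALSE])
  expect_false(r49$present); expect_true(is.na(r49$frequency))
  # type must match: DUP record never supports a DEL region
  rtype <- database_lookup("chr1", 1000, 2000, "DEL",
                           db[db$type == "DUP", , drop = FALSE])
  expect_false(rtype$present)
  # tie on overlap -> highest frequency
  tie <- data.frame(db_id = "d", chrom = "chr1", start = c(0, 0),
                    end = c(3000, 3000), type = "DEL",
                    frequency = c(0.1, 0.4), stringsAsFactors = FALSE)
  rt <- database_lookup("chr1", 1000, 2000, "DEL", tie)
  expect_equal(rt$frequency, 0.4)
  expect_error(database_lookup("chr1", 0, 10, "DEL", db, min_frac = 0),
               "min_frac")
})

test_that("database lookup equals the brute-force overlap-fraction scan
           on random inputs", {
  set.seed(97)
  n <- 100
  start <- floor(runif(n, 0, 1e5))
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        start = start, end = start + floor(runif(n, 600,
                                                                 8000)),
                        type = sample(c("DEL", "DUP"), n, TRUE))
  ds <- floor(runif(60, 0, 1e5))
  db <- data.frame(db_id = "d", chrom = sample(c("chr1", "chr2"), 60,
                                               TRUE),
                   start = ds, end = ds + floor(runif(60, 600, 8000)),
                   type = sample(c("DEL", "DUP"), 60, TRUE),
                   frequency = round(runif(60), 3),
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    got <- database_lookup(regions$chrom[i], regions$start[i],
                           regions$end[i], regions$type[i], db)
    len <- regions$end[i] - regions$start[i]
    ovs <- vapply(seq_len(nrow(db)), function(k) {
      if (db$chrom[k] != regions$chrom[i] ||
          db$type[k] != regions$type[i]) return(0)
      max(0, min(db$end[k], regions$end[i]) -
            max(db$start[k], regions$start[i]))
    }, numeric(1))
    expect_equal(got$present, any(ovs >= 0.5 * len))
  }
})

test_that("segdup fraction matches the per-base bitmap oracle and guards
           unmerged tracks", {
  segdups <- data.frame(chrom = "chr1", start = c(1000, 5000),
                        end = c(3000, 6000))
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(1500, 8000, 0),
                        end = c(2500, 9000, 1000))
  fr <- segdup_fraction(regions, segdups)
  expect_equal(fr, c(1, 0, 0))  # fully inside, no overlap, other chrom

  set.seed(98)
  rs <- floor(runif(30, 0, 5e4))
  regions2 <- data.frame(chrom = "chr1", start = rs,
                         end = rs + floor(runif(30, 500, 5000)))
  ss <- floor(runif(15, 0, 5e4))
  track <- merge_intervals(data.frame(chrom = "chr1", start = ss,
                                      end = ss + 3000))
  fr2 <- segdup_fraction(regions2, track)
  oracle <- vapply(seq_len(30), function(i)
    bf_covered_bp("chr1", regions2$start[i], regions2$end[i], track) /
      (regions2$end[i] - regions2$start[i]), numeric(1))
  expect_equal(fr2, oracle)

  overlapping <- data.frame(chrom = "chr1", start = c(0, 500),
                            end = c(1000, 1500))
  expect_error(segdup_fraction(regions, overlapping), "merge")
})

test_that("flank GC reads the breakpoint windows of the genome sequence", {
  gseq <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("G", 500), strrep("A", 1000), strrep("G", 500))))
  # flanks of [500, 1500) are all-G
  fc <- flank_context("chr1", 500, 1500, gseq, flank_bp = 100)
  expect_equal(fc$flank_gc, 1)
  # flanks of [100, 1900) with windows inside A-run boundaries
  fc2 <- flank_context("chr1", 600, 1400, gseq, flank_bp = 100)
  expect_equal(fc2$flank_gc, 0)
  # crafted 60% GC: left window 100 bp of G, right window 100 bp of A,
  # plus asymmetric composition
  gseq3 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 60), strrep("A", 40), strrep("T", 100),
    strrep("C", 60), strrep("T", 40))))
  fc3 <- flank_context("chr1", 100, 200, gseq3, flank_bp = 100)
  expect_equal(fc3$flank_gc, 0.6)
  # repeat flag
  reps <- data.frame(chrom = "chr1", start = 450, end = 470)
  fc4 <- flank_context("chr1", 500, 1500, gseq, reps, flank_bp = 100)
  expect_true(fc4$has_flanking_repeat)
  fc5 <- flank_context("chr1", 600, 1400, gseq, reps, flank_bp = 100)
  expect_false(fc5$has_flanking_repeat)
})

test_that("mean mappability is the length-weighted track mean", {
  track <- data.frame(chrom = "chr1", start = c(0, 500),
                      end = c(500, 1000), value = c(0, 1))
  regions <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(mean_mappability(regions, track), 0.5)
  const <- data.frame(chrom = "chr1", start = 0, end = 1e4, value = 1)
  expect_equal(mean_mappability(regions, const), 1)

  set.seed(99)
  starts <- seq(0, 9000, by = 1000)
  rt <- data.frame(chrom = "chr1", start = starts, end = starts + 1000,
                   value = round(runif(10), 3))
  rs <- floor(runif(20, 0, 8000))
  regions2 <- data.frame(chrom = "chr1", start = rs,
                         end = rs + floor(runif(20, 100, 2000)))
  got <- mean_mappability(regions2, rt)
  oracle <- vapply(seq_len(20), function(i) {
    vals <- numeric(0)
    for (p in regions2$start[i]:(regions2$end[i] - 1)) {
      vals <- c(vals, rt$value[rt$start <= p & p < rt$end])
    }
    mean(vals)
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("the evidence table is one row per CNVR and never mutates
           them", {
  cfg <- tiny_sim_config(seed = 23)
  sim <- simulate_inputs(cfg)
  prep <- prepare_callsets(sim$calls, sim$depth,
                           sim$annotations$exclusions)
  cnvrs <- aggregate_all(prep)
  before <- cnvrs
  gts <- simulate_lr_genotypes(cnvrs, sim$truth, 0.05, seed = 24)
  ev <- evidence_table(cnvrs, arrays = sim$arrays, genotypes = gts,
                       databases = sim$databases,
                       segdups = sim$annotations$segdups,
                       mappability = sim$annotations$mappability,
                       genome_seq = sim$genome_seq)
  expect_identical(cnvrs, before)
  expect_equal(nrow(ev), nrow(cnvrs))
  expect_equal(ev$cnvr_id, cnvrs$cnvr_id)
  expect_true(all(ev$segdup_frac >= 0 & ev$segdup_frac <= 1))
  expect_true(all(is.na(ev$array_hellinger) |
                    (ev$array_hellinger >= 0 & ev$array_hellinger <= 1)))
  expect_true(all(ev$db_dbA_present | is.na(ev$db_dbA_freq)))
})
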