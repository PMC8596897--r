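#' Simulation configuration
#'
#' Builds the configuration for the synthetic truth model and every derived
#' raw-data input. Defaults describe a toy diploid genome of two 5-Mb
#' chromosomes carrying 200 CNVs, assayed by three datasets per technology
#' at sensitivity 0.9, 0.5 false calls per Mb and 50-bp breakpoint jitter,
#' a 30x short-read depth track, two array chip designs, and
#' copy-number-driven Log R Ratio shifts of -0.5 (heterozygous deletion)
#' and +0.3 (duplication) around a diploid baseline of 0.
#'
#' @param seed RNG seed (mandatory); every generator derives its stream
#'   from it.
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param n_variants number of truth CNVs to place.
#' @param size_range log-uniform truth size bounds in bp (min >= 500).
#' @param del_frac fraction of truth variants that are deletions.
#' @param het_frac fraction of truth variants that are heterozygous.
#' @param datasets data.frame of dataset specs: dataset, technology,
#'   sensitivity, fp_per_mb, jitter_sd, fp_size_range (list column).
#' @param coverage mean diploid read depth of the simulated depth track.
#' @param bin_width depth-track bin width in bp.
#' @param lrr_sd per-probe Log R Ratio noise sd.
#' @param lrr_shift named vector of expected LRR by copy number 0..4.
#' @param probe_spacing named vector, probe spacing in bp per chip design.
#' @param genotype_error long-read genotyping error rate.
#' @param databases list of synthetic database specs, each with
#'   `inclusion` probability, `jitter_sd`, and Beta `freq_shape` c(a, b).
#' @param gc_content genome-wide GC fraction of the simulated sequence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       n_variants = 200,
                       size_range = c(600, 20000),
                       del_frac = 0.6,
                       het_frac = 0.8,
                       datasets = default_dataset_specs(),
                       coverage = 30,
                       bin_width = 100,
                       lrr_sd = 0.2,
                       lrr_shift = c(`0` = -2, `1` = -0.5, `2` = 0,
                                     `3` = 0.3, `4` = 0.75),
                       probe_spacing = c(chipA = 1200, chipB = 3000),
                       genotype_error = 0.05,
                       databases = default_database_specs(),
                       gc_content = 0.41) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  # structured-text (YAML) configs deliver named lists; flatten them
  genome <- unlist(genome); size_range <- unlist(size_range)
  probe_spacing <- unlist(probe_spacing); lrr_shift <- unlist(lrr_shift)
  if (is.list(datasets)) datasets <- as.data.frame(datasets)
  stopifnot(all(genome > 0), n_variants >= 0,
            size_range[1] >= 500, size_range[2] >= size_range[1],
            del_frac >= 0, del_frac <= 1, het_frac >= 0, het_frac <= 1,
            coverage > 0, bin_width > 0, lrr_sd >= 0,
            all(probe_spacing > 0),
            genotype_error >= 0, genotype_error <= 1)
  stopifnot(all(datasets$sensitivity >= 0 & datasets$sensitivity <= 1),
            all(datasets$fp_per_mb >= 0), all(datasets$jitter_sd >= 0))
  structure(list(
    seed = as.integer(seed), genome = genome, n_variants = n_variants,
    size_range = size_range, del_frac = del_frac, het_frac = het_frac,
    datasets = datasets, coverage = coverage, bin_width = bin_width,
    lrr_sd = lrr_sd, lrr_shift = lrr_shift, probe_spacing = probe_spacing,
    genotype_error = genotype_error, databases = databases,
    gc_content = gc_content
  ), class = "sim_config")
}

#' Default dataset ensemble: three datasets per technology
#'
#' Technology-specific false-call size profiles: array false calls are
#' large (5-100 kb), short-read ones small (0.6-5 kb), long-read ones
#' intermediate (0.6-20 kb).
#' @export
default_dataset_specs <- function() {
  tech <- rep(c("array", "sr", "lr"), each = 3)
  data.frame(
    dataset = paste0(tech, 1:3),
    technology = tech,
    sensitivity = 0.9,
    fp_per_mb = 0.5,
    jitter_sd = 50,
    fp_min = rep(c(5000, 600, 600), each = 3),
    fp_max = rep(c(100000, 5000, 20000), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic database specs
#'
#' Both databases include truth variants only (a false call can never be a
#' real polymorphism), with frequencies drawn Beta(1, 9) (mean 0.1).
#' @export
default_database_specs <- function() {
  list(
    dbA = list(inclusion = 0.7, jitter_sd = 100, freq_shape = c(1, 9)),
    dbB = list(inclusion = 0.5, jitter_sd = 100, freq_shape = c(1, 9))
  )
}

copy_number_for <- function(type, genotype) {
  ifelse(type == "DEL", ifelse(genotype == "het", 1L, 0L),
         ifelse(genotype == "het", 3L, 4L))
}

#' Simulate the truth CNV set
#'
#' Places `n_variants` deletions/duplications on the toy genome with
#' log-uniform sizes. Truth variants of the same type never overlap (so
#' recovery accounting is unambiguous); opposite types may. Placement
#' avoids the fixed telomere/centromere masks of
#' [simulate_annotations()], emulating a confident-region truth set:
#' calls in masked regions are artefacts by construction, never missed
#' truth.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to the config seed.
#' @return data.frame: truth_id, chrom, start, end, type, genotype,
#'   copy_number.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  set.seed(seed)
  g <- config$genome
  n <- config$n_variants
  out <- data.frame(truth_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    type = character(0), genotype = character(0),
                    copy_number = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  placed <- list()
  max_tries <- 200L * n
  tries <- 0L
  while (length(placed) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("simulate_truth: could not place ", n,
           " non-overlapping variants after ", max_tries, " tries")
    }
    size <- round(exp(stats::runif(1, log(config$size_range[1]),
                                   log(config$size_range[2]))))
    chrom <- sample(names(g), 1, prob = g)
    if (size >= g[[chrom]]) next
    start <- floor(stats::runif(1, 0, g[[chrom]] - size))
    masks <- fixed_masks(g[[chrom]])
    if (any(start < masks$end & masks$start < start + size)) next
    type <- if (stats::runif(1) < config$del_frac) "DEL" else "DUP"
    clash <- any(vapply(placed, function(p) {
      p$type == type && p$chrom == chrom &&
        start < p$end && p$start < start + size
    }, logical(1)))
    if (clash) next
    placed[[length(placed) + 1L]] <- list(chrom = chrom, start = start,
                                          end = start + size, type = type)
  }
  df <- do.call(rbind, lapply(placed, as.data.frame,
                              stringsAsFactors = FALSE))
  df$genotype <- ifelse(stats::runif(n) < config$het_frac, "het", "hom")
  df$copy_number <- copy_number_for(df$type, df$genotype)
  df <- sort_intervals(df)
  df$truth_id <- sprintf("T%03d", seq_len(n))
  rownames(df) <- NULL
  df[, c("truth_id", "chrom", "start", "end", "type", "genotype",
         "copy_number")]
}

# deterministic telomere/centromere masks of the toy genome
fixed_masks <- function(chrom_len) {
  mid <- floor(chrom_len / 2)
  data.frame(start = c(0, chrom_len - 50000, mid - 50000),
             end = c(50000, chrom_len, mid + 50000))
}

jitter_interval <- function(start, end, sd, chrom_len) {
  if (sd > 0) {
    start <- start + round(stats::rnorm(length(start), 0, sd))
    end <- end + round(stats::rnorm(length(end), 0, sd))
  }
  start <- pmax(0, pmin(start, chrom_len - 1))
  end <- pmax(start + 1, pmin(end, chrom_len))
  list(start = start, end = end)
}

#' Simulate one callset per dataset spec
#'
#' Each truth variant is re-called by a dataset with probability
#' `sensitivity`, with breakpoints jittered N(0, jitter_sd) per side; false
#' calls arrive as a Poisson process at `fp_per_mb` with the dataset's
#' technology-specific size profile. Long-read calls carry SVIM-style
#' intrinsic scores: truth-derived calls draw high scores (log-normal,
#' median 10), false calls low ones (exponential, mean 0.5, mostly < 1).
#'
#' @param truth truth table from [simulate_truth()].
#' @param config a [sim_config()].
#' @param dataset_specs data.frame as in `config$datasets`.
#' @param seed RNG seed; defaults to config seed + 1.
#' @return canonical callset data.frame (see [as_callset()]) with a
#'   `truth_id` provenance column (NA for false calls).
#' @export
simulate_callsets <- function(truth, config,
                              dataset_specs = config$datasets,
                              seed = config$seed + 1L) {
  set.seed(seed)
  if (!all(dataset_specs$technology %in% TECHNOLOGIES)) {
    stop("simulate_callsets: unknown technology in dataset specs")
  }
  g <- config$genome
  rows <- list()
  for (i in seq_len(nrow(dataset_specs))) {
    spec <- dataset_specs[i, ]
    hit <- which(stats::runif(nrow(truth)) < spec$sensitivity)
    if (length(hit) > 0) {
      tv <- truth[hit, ]
      jj <- jitter_interval(tv$start, tv$end, spec$jitter_sd,
                            unname(g[tv$chrom]))
      tp <- data.frame(chrom = tv$chrom, start = jj$start, end = jj$end,
                       type = tv$type, dataset = spec$dataset,
                       technology = spec$technology,
                       truth_id = tv$truth_id,
                       copy_number = tv$copy_number,
                       stringsAsFactors = FALSE)
    } else tp <- NULL
    n_fp <- stats::rpois(1, spec$fp_per_mb * sum(g) / 1e6)
    if (n_fp > 0) {
      chrom <- sample(names(g), n_fp, replace = TRUE, prob = g)
      size <- round(exp(stats::runif(n_fp, log(spec$fp_min),
                                     log(spec$fp_max))))
      size <- pmin(size, unname(g[chrom]) - 1)
      start <- floor(stats::runif(n_fp, 0, unname(g[chrom]) - size))
      fp <- data.frame(chrom = chrom, start = start, end = start + size,
                       type = sample(CNV_TYPES, n_fp, replace = TRUE),
                       dataset = spec$dataset,
                       technology = spec$technology,
                       truth_id = NA_character_,
                       copy_number = NA_integer_,
                       stringsAsFactors = FALSE)
    } else fp <- NULL
    ds <- rbind(tp, fp)
    if (is.null(ds) || nrow(ds) == 0) next
    if (spec$technology == "lr") {
      is_tp <- !is.na(ds$truth_id)
      sc <- numeric(nrow(ds))
      sc[is_tp] <- pmin(100, stats::rlnorm(sum(is_tp), log(10), 0.8))
      sc[!is_tp] <- pmin(100, stats::rexp(sum(!is_tp), rate = 2))
      ds$score <- sc
    } else {
      ds$score <- NA_real_
    }
    rows[[length(rows) + 1L]] <- ds
  }
  if (length(rows) == 0) {
    return(as_callset(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), type = character(0),
                                 dataset = character(0),
                                 technology = character(0))))
  }
  out <- do.call(rbind, rows)
  truth_id <- out$truth_id
  out <- as_callset(out[, setdiff(names(out), "truth_id")],
                    what = "simulated callset")
  out$truth_id <- truth_id
  out
}

#' Simulate a random genome sequence
#'
#' IID nucleotides at the configured GC fraction; used for GC-matched
#' depth-fold-change bins and flank GC context.
#'
#' @inheritParams simulate_truth
#' @return a [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
simulate_genome_seq <- function(config, seed = config$seed + 2L) {
  set.seed(seed)
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- lapply(config$genome, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Copy number along the genome implied by the truth set
#'
#' @return function(chrom, pos_vector) -> integer copy numbers (diploid
#'   baseline 2 plus summed deviations of overlapping truth variants,
#'   floored at 0).
#' @keywords internal
truth_cn_lookup <- function(truth) {
  function(chrom, pos) {
    cn <- rep(2, length(pos))
    tv <- truth[truth$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(tv))) {
      inside <- pos >= tv$start[j] & pos < tv$end[j]
      cn[inside] <- cn[inside] + (tv$copy_number[j] - 2)
    }
    pmax(cn, 0)
  }
}

#' Simulate a binned short-read depth track
#'
#' Bin depth ~ Poisson(coverage x copy_number / 2), copy number taken at
#' the bin midpoint (diploid baseline 2).
#'
#' @inheritParams simulate_truth
#' @param truth truth table.
#' @return a [depth_track()].
#' @export
simulate_depth <- function(truth, config, seed = config$seed + 3L) {
  set.seed(seed)
  bw <- config$bin_width
  cn_at <- truth_cn_lookup(truth)
  pieces <- lapply(names(config$genome), function(chrom) {
    len <- config$genome[[chrom]]
    starts <- seq(0, len - 1, by = bw)
    ends <- pmin(starts + bw, len)
    cn <- cn_at(chrom, (starts + ends) / 2)
    data.frame(chrom = chrom, start = starts, end = ends,
               depth = as.numeric(stats::rpois(length(starts),
                                               config$coverage * cn / 2)),
               stringsAsFactors = FALSE)
  })
  depth_track(do.call(rbind, pieces), chrom_lengths = config$genome)
}

#' Simulate array probe maps and LRR signal
#'
#' Probes sit on a fixed grid per chip; the Log R Ratio of a probe is the
#' configured copy-number shift at its position (e.g. -0.5 inside a
#' heterozygous deletion, +0.3 inside a heterozygous duplication, 0 in
#' diploid background) plus N(0, lrr_sd) noise.
#'
#' @inheritParams simulate_depth
#' @return named list per chip: list(probes = [probe_map()], lrr =
#'   data.frame(probe_id, lrr)).
#' @export
simulate_array <- function(truth, config, seed = config$seed + 4L) {
  set.seed(seed)
  cn_at <- truth_cn_lookup(truth)
  out <- list()
  for (chip in names(config$probe_spacing)) {
    sp <- config$probe_spacing[[chip]]
    rows <- lapply(names(config$genome), function(chrom) {
      pos <- seq(floor(sp / 2), config$genome[[chrom]] - 1, by = sp)
      data.frame(chrom = chrom, position = pos, stringsAsFactors = FALSE)
    })
    pm <- do.call(rbind, rows)
    pm$probe_id <- sprintf("%s_%s_%06d", chip, pm$chrom,
                           unlist(lapply(rows, function(r) seq_len(nrow(r)))))
    pm <- probe_map(pm[, c("probe_id", "chrom", "position")], chip)
    cn <- unlist(lapply(split(pm, pm$chrom),
                        function(d) cn_at(d$chrom[1], d$position)))
    # split() orders by chrom level; pm already sorted by (chrom, position)
    shift <- config$lrr_shift[as.character(pmin(pmax(cn, 0), 4))]
    lrr <- data.frame(probe_id = pm$probe_id,
                      lrr = shift + stats::rnorm(nrow(pm), 0, config$lrr_sd),
                      stringsAsFactors = FALSE)
    out[[chip]] <- list(probes = pm, lrr = lrr)
  }
  out
}

#' Simulate long-read genotype validation of a set of regions
#'
#' Emulates a VaPoR-style validator run on a region list: a region
#' overlapping a same-type truth variant receives the truth genotype
#' (het -> 0/1, hom -> 1/1) with probability 1 - error_rate and otherwise
#' 0/0 or NA; regions with no truth overlap receive 0/0 or NA.
#'
#' @param regions BED-style data.frame with a `type` column.
#' @param truth truth table.
#' @param error_rate genotyping error rate in \[0,1\].
#' @param seed RNG seed.
#' @return data.frame chrom, start, end, genotype.
#' @export
simulate_lr_genotypes <- function(regions, truth, error_rate = 0.05,
                                  seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(regions)
  gt <- character(n)
  for (i in seq_len(n)) {
    ov <- overlap_bp(regions$chrom[i], regions$start[i], regions$end[i],
                     truth)
    if (!is.null(regions$type)) ov[truth$type != regions$type[i]] <- 0L
    j <- which.max(ov)
    if (length(ov) > 0 && ov[j] > 0) {
      true_gt <- if (truth$genotype[j] == "het") "0/1" else "1/1"
      gt[i] <- if (stats::runif(1) < 1 - error_rate) true_gt
               else sample(c("0/0", "NA"), 1)
    } else {
      gt[i] <- sample(c("0/0", "NA"), 1, prob = c(0.7, 0.3))
    }
  }
  data.frame(chrom = regions$chrom, start = regions$start,
             end = regions$end, genotype = gt, stringsAsFactors = FALSE)
}

#' Simulate public CNV databases
#'
#' Each configured database includes each truth variant independently with
#' its inclusion probability, jitters breakpoints, and draws a population
#' frequency from the configured Beta distribution. False calls are never
#' present, so database presence is truth-linked by construction.
#'
#' @inheritParams simulate_depth
#' @return list of database data.frames (see [read_database()]).
#' @export
simulate_database <- function(truth, config, seed = config$seed + 5L) {
  set.seed(seed)
  out <- list()
  for (db in names(config$databases)) {
    spec <- config$databases[[db]]
    inc <- which(stats::runif(nrow(truth)) < spec$inclusion)
    if (length(inc) == 0) {
      out[[db]] <- data.frame(db_id = character(0), chrom = character(0),
                              start = numeric(0), end = numeric(0),
                              type = character(0), frequency = numeric(0),
                              stringsAsFactors = FALSE)
      next
    }
    tv <- truth[inc, ]
    jj <- jitter_interval(tv$start, tv$end, spec$jitter_sd,
                          unname(config$genome[tv$chrom]))
    out[[db]] <- data.frame(
      db_id = db, chrom = tv$chrom, start = jj$start, end = jj$end,
      type = tv$type,
      frequency = stats::rbeta(length(inc), spec$freq_shape[1],
                               spec$freq_shape[2]),
      stringsAsFactors = FALSE)
  }
  out
}

#' Simulate genome annotation tracks
#'
#' Exclusion regions (telomere-like chromosome ends plus a centromere-like
#' mid-chromosome block and a few random blacklist intervals), a merged
#' segmental-duplication track, and a stepped mappability track (baseline
#' 1.0 with random low-mappability patches).
#'
#' @inheritParams simulate_truth
#' @return list(exclusions, segdups, mappability) of BED-style frames.
#' @export
simulate_annotations <- function(config, seed = config$seed + 6L) {
  set.seed(seed)
  g <- config$genome
  excl <- do.call(rbind, lapply(names(g), function(chrom) {
    len <- g[[chrom]]
    n_bl <- stats::rpois(1, 2)
    bl_start <- floor(stats::runif(n_bl, 0, len - 10000))
    masks <- fixed_masks(len)
    rbind(
      data.frame(chrom = chrom, start = masks$start, end = masks$end,
                 name = c("telomere_p", "telomere_q", "centromere"),
                 stringsAsFactors = FALSE),
      if (n_bl > 0) data.frame(chrom = chrom, start = bl_start,
                               end = bl_start + 10000, name = "blacklist",
                               stringsAsFactors = FALSE)
    )
  }))
  sd_raw <- do.call(rbind, lapply(names(g), function(chrom) {
    n_sd <- stats::rpois(1, 8)
    if (n_sd == 0) return(NULL)
    st <- floor(stats::runif(n_sd, 0, g[[chrom]] - 50000))
    data.frame(chrom = chrom, start = st,
               end = st + round(stats::runif(n_sd, 2000, 50000)),
               stringsAsFactors = FALSE)
  }))
  segdups <- merge_intervals(sd_raw)
  mapp <- do.call(rbind, lapply(names(g), function(chrom) {
    step <- 10000
    starts <- seq(0, g[[chrom]] - 1, by = step)
    val <- rep(1, length(starts))
    low <- stats::runif(length(starts)) < 0.1
    val[low] <- round(stats::runif(sum(low), 0, 0.6), 3)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + step, g[[chrom]]), value = val,
               stringsAsFactors = FALSE)
  }))
  list(exclusions = sort_intervals(excl), segdups = segdups,
       mappability = mapp)
}

#' Collapse overlapping intervals to their union
#'
#' @param df BED-style data.frame.
#' @return sorted data.frame of disjoint intervals (overlapping or
#'   book-ended inputs collapsed).
#' @export
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(intervals_to_gr(df))
  sort_intervals(gr_to_intervals(gr))
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator off one master seed and (optionally) writes the
#' complete fixture set — truth TSV, per-dataset callset TSVs, probe-map
#' and LRR TSVs, depth bedGraph, genotype TSV over truth regions, database
#' TSVs, exclusion/segdup BEDs and mappability wig — into a directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory or NULL to skip writing.
#' @return list(truth, calls, depth, genome_seq, arrays, databases,
#'   annotations, genotypes, config).
#' @export
simulate_inputs <- function(config, dir = NULL) {
  truth <- simulate_truth(config)
  calls <- simulate_callsets(truth, config)
  genome_seq <- simulate_genome_seq(config)
  depth <- simulate_depth(truth, config)
  arrays <- simulate_array(truth, config)
  dbs <- simulate_database(truth, config)
  anns <- simulate_annotations(config)
  gts <- simulate_lr_genotypes(truth, truth,
                               error_rate = config$genotype_error,
                               seed = config$seed + 7L)
  bundle <- list(truth = truth, calls = calls, depth = depth,
                 genome_seq = genome_seq, arrays = arrays,
                 databases = dbs, annotations = anns, genotypes = gts,
                 config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_sorted(truth, file.path(dir, "truth.tsv"))
    for (ds in unique(calls$dataset)) {
      write_callset(calls[calls$dataset == ds, ],
                    file.path(dir, paste0("callset_", ds, ".tsv")))
    }
    write_bedgraph(depth, file.path(dir, "depth.bedGraph"))
    for (chip in names(arrays)) {
      write_tsv_sorted(as.data.frame(arrays[[chip]]$probes),
                       file.path(dir, paste0("probes_", chip, ".tsv")))
      write.table(arrays[[chip]]$lrr,
                  file.path(dir, paste0("lrr_", chip, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (db in names(dbs)) {
      write_tsv_sorted(dbs[[db]], file.path(dir, paste0("db_", db, ".tsv")))
    }
    write_tsv_sorted(gts, file.path(dir, "lr_genotypes.tsv"))
    write_bed(anns$exclusions, file.path(dir, "exclusions.bed"))
    write_bed(anns$segdups, file.path(dir, "segdups.bed"))
    mp <- anns$mappability
    gr <- intervals_to_gr(mp); gr$score <- mp$value
    rtracklayer::export(gr, file.path(dir, "mappability.wig"),
                        format = "wig")
    Biostrings::writeXStringSet(bundle$genome_seq,
                                file.path(dir, "genome.fasta"))
  }
  bundle
}
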