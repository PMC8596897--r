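#' Hellinger distance between two samples
#'
#' Both samples are binned on `n_bins` equal-width bins spanning the
#' pooled min..max, normalized to probability vectors p and q, and the
#' distance is sqrt(1 - sum(sqrt(p * q))) — sqrt(1 - Bhattacharyya
#' coefficient), ranging 0 (identical histograms) to 1 (disjoint
#' supports).
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @param n_bins number of shared equal-width bins (default 20).
#' @export
hellinger_distance <- function(sample_a, sample_b, n_bins = 20) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("hellinger_distance: empty sample")
  }
  lo <- min(sample_a, sample_b); hi <- max(sample_a, sample_b)
  if (lo == hi) return(0)  # all mass in one bin for both samples
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  binit <- function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = n_bins)
  }
  p <- binit(sample_a) / length(sample_a)
  q <- binit(sample_b) / length(sample_b)
  bc <- sum(sqrt(p * q))
  sqrt(max(0, 1 - bc))
}

#' Array raw-data evidence for one region
#'
#' Compares the Log R Ratio distribution of the probes inside the region
#' against the `n_flank_probes` nearest probes immediately up- and
#' downstream (pooled, truncated at chromosome ends) via the Hellinger
#' distance, and reports the median in-region LRR (expected near -0.5 for
#' a heterozygous deletion, +0.3 for a duplication).
#'
#' @param chrom,start,end the region (0-based half-open).
#' @param probes a [probe_map()].
#' @param lrr data.frame(probe_id, lrr).
#' @param n_flank_probes probes per flank (default 50).
#' @param min_probes minimum in-region probe count for a defined assay.
#' @param n_bins histogram bins for the Hellinger distance.
#' @return list(hellinger, median_lrr, n_inside, reason).
#' @export
array_evidence <- function(chrom, start, end, probes, lrr,
                           n_flank_probes = 50, min_probes = 5,
                           n_bins = 20) {
  p <- probes[probes$chrom == chrom, , drop = FALSE]
  p$lrr <- lrr$lrr[match(p$probe_id, lrr$probe_id)]
  p <- p[!is.na(p$lrr), , drop = FALSE]
  inside <- p[p$position >= start & p$position < end, , drop = FALSE]
  if (nrow(inside) < min_probes) {
    return(list(hellinger = NA_real_, median_lrr = NA_real_,
                n_inside = nrow(inside), reason = "too_few_probes"))
  }
  up <- p[p$position < start, , drop = FALSE]
  up <- tail(up[order(up$position), , drop = FALSE], n_flank_probes)
  down <- p[p$position >= end, , drop = FALSE]
  down <- head(down[order(down$position), , drop = FALSE], n_flank_probes)
  flank <- c(up$lrr, down$lrr)
  if (length(flank) == 0) {
    return(list(hellinger = NA_real_,
                median_lrr = stats::median(inside$lrr),
                n_inside = nrow(inside), reason = "no_flank_probes"))
  }
  list(hellinger = hellinger_distance(inside$lrr, flank, n_bins),
       median_lrr = stats::median(inside$lrr),
       n_inside = nrow(inside), reason = NA_character_)
}

#' Long-read genotype concordance
#'
#' Variant-supporting genotypes 0/1 and 1/1 are "concordant" with the
#' presence of the CNV; 0/0 or no assigned genotype ("NA") is
#' "discordant".
#'
#' @param genotype character vector of 0/0, 0/1, 1/1 or "NA".
#' @export
longread_concordance <- function(genotype) {
  bad <- which(!genotype %in% GENOTYPES)
  if (length(bad) > 0) {
    stop("longread_concordance: unknown genotype '", genotype[bad[1]], "'")
  }
  ifelse(genotype %in% c("0/1", "1/1"), "concordant", "discordant")
}

#' Probe counts per chip inside each region
#'
#' A probe at position p is inside \[start, end) iff start <= p < end;
#' zero is reported explicitly for regions with no intersection.
#'
#' @param regions BED-style data.frame.
#' @param probe_maps named list of [probe_map()]s.
#' @return data.frame, one `n_probes_<chip>` column per chip.
#' @export
probe_coverage <- function(regions, probe_maps) {
  out <- data.frame(row.names = seq_len(nrow(regions)))
  for (chip in names(probe_maps)) {
    pm <- probe_maps[[chip]]
    out[[paste0("n_probes_", chip)]] <- vapply(seq_len(nrow(regions)),
      function(i) {
        sum(pm$chrom == regions$chrom[i] &
              pm$position >= regions$start[i] &
              pm$position < regions$end[i])
      }, numeric(1))
  }
  out
}

#' Public-database lookup for one region
#'
#' The region is present in a database iff some same-type record overlaps
#' at least `min_frac` of the region's length (one-directional, not
#' reciprocal). The reported frequency is that of the qualifying record
#' with the largest overlap (ties broken by highest frequency).
#'
#' @param chrom,start,end,type the region.
#' @param database data.frame from [read_database()].
#' @param min_frac minimum overlapped fraction of the region (default
#'   0.5).
#' @return list(present, frequency).
#' @export
database_lookup <- function(chrom, start, end, type, database,
                            min_frac = 0.5) {
  if (!(min_frac > 0 && min_frac <= 1)) {
    stop("database_lookup: min_frac must be in (0, 1]")
  }
  db <- database[database$type == type, , drop = FALSE]
  ov <- overlap_bp(chrom, start, end, db)
  qual <- which(ov >= min_frac * (end - start))
  if (length(qual) == 0) return(list(present = FALSE,
                                     frequency = NA_real_))
  best <- qual[order(-ov[qual], -db$frequency[qual])][1]
  list(present = TRUE, frequency = db$frequency[best])
}

#' Fraction of a region covered by merged segmental duplications
#'
#' @param regions BED-style data.frame.
#' @param segdups merged (non-overlapping) segdup track; overlapping
#'   input is rejected, merge with [merge_intervals()] first.
#' @return numeric vector of covered fractions in \[0, 1\].
#' @export
segdup_fraction <- function(regions, segdups) {
  if (nrow(segdups) > 1) {
    s <- sort_intervals(segdups)
    by_chrom <- split(s, s$chrom)
    for (d in by_chrom) {
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
        stop("segdup_fraction: track has overlapping records; ",
             "merge it first")
      }
    }
  }
  vapply(seq_len(nrow(regions)), function(i) {
    ov <- overlap_bp(regions$chrom[i], regions$start[i], regions$end[i],
                     segdups)
    sum(ov) / (regions$end[i] - regions$start[i])
  }, numeric(1))
}

#' GC and repeat context of the breakpoint flanks
#'
#' GC fraction pooled over the two `flank_bp`-wide windows immediately
#' outside the region's breakpoints (truncated at chromosome ends), and
#' whether either window overlaps the repeat track.
#'
#' @param chrom,start,end the region.
#' @param genome_seq [Biostrings::DNAStringSet] named by chromosome.
#' @param repeats BED-style repeat track or NULL.
#' @param flank_bp flank width per side (default 100).
#' @return list(flank_gc, has_flanking_repeat).
#' @export
flank_context <- function(chrom, start, end, genome_seq, repeats = NULL,
                          flank_bp = 100) {
  stopifnot(flank_bp > 0)
  chrom_len <- length(genome_seq[[chrom]])
  wins <- data.frame(
    start = c(max(0, start - flank_bp), min(end, chrom_len)),
    end = c(max(0, start), min(end + flank_bp, chrom_len)))
  wins <- wins[wins$end > wins$start, , drop = FALSE]
  if (nrow(wins) == 0) {
    return(list(flank_gc = NA_real_, has_flanking_repeat = NA))
  }
  v <- Biostrings::Views(genome_seq[[chrom]], start = wins$start + 1L,
                         end = wins$end)
  f <- Biostrings::letterFrequency(v, letters = c("G", "C"))
  gc <- sum(f) / sum(wins$end - wins$start)
  rep_hit <- if (is.null(repeats)) NA else {
    any(vapply(seq_len(nrow(wins)), function(i)
      any(overlap_bp(chrom, wins$start[i], wins$end[i], repeats) > 0),
      logical(1)))
  }
  list(flank_gc = gc, has_flanking_repeat = rep_hit)
}

#' Length-weighted mean mappability over each region
#'
#' @param regions BED-style data.frame.
#' @param track step track (chrom, start, end, value) covering the
#'   genome, values in \[0, 1\].
#' @return numeric vector of means.
#' @export
mean_mappability <- function(regions, track) {
  vapply(seq_len(nrow(regions)), function(i) {
    w <- overlap_bp(regions$chrom[i], regions$start[i], regions$end[i],
                    track)
    if (sum(w) == 0) return(NA_real_)
    sum(track$value * w) / sum(w)
  }, numeric(1))
}

#' Assemble the wide per-CNVR evidence table
#'
#' Joins every evidence assay onto the CNVR table: array Hellinger score
#' and median LRR from one representative chip, probe counts for all
#' chips, inherited median DHFFC/DHBFC, long-read genotype and
#' concordance, database presence/frequency per database, and genomic
#' context (segdup fraction, flank GC/repeat, mean mappability).
#'
#' @param cnvrs CNVR data.frame.
#' @param arrays named list per chip: list(probes, lrr); the first chip
#'   is the representative array dataset for the Hellinger assay.
#' @param genotypes genotype table matched to the CNVRs by exact
#'   interval (the validator is run on the CNVR list itself).
#' @param databases named list of database tables.
#' @param segdups merged segdup track or NULL.
#' @param mappability step track or NULL.
#' @param genome_seq genome sequence or NULL (skips flank GC).
#' @param repeats repeat track for the flank context (defaults to
#'   `segdups`).
#' @param n_flank_probes,min_probes,n_bins,db_min_frac,flank_bp assay
#'   assay parameters (standard defaults: 50 flank probes, 5 minimum
#'   in-region probes, 20 histogram bins, 50% database overlap, 100-bp
#'   context flanks).
#' @return data.frame keyed by cnvr_id.
#' @export
evidence_table <- function(cnvrs, arrays = NULL, genotypes = NULL,
                           databases = NULL, segdups = NULL,
                           mappability = NULL, genome_seq = NULL,
                           repeats = segdups, n_flank_probes = 50,
                           min_probes = 5, n_bins = 20,
                           db_min_frac = 0.5, flank_bp = 100) {
  n <- nrow(cnvrs)
  ev <- data.frame(cnvr_id = cnvrs$cnvr_id,
                   dhffc = cnvrs$median_dhffc,
                   dhbfc = cnvrs$median_dhbfc,
                   stringsAsFactors = FALSE)
  if (!is.null(arrays) && length(arrays) > 0) {
    rep_chip <- arrays[[1]]
    ae <- lapply(seq_len(n), function(i)
      array_evidence(cnvrs$chrom[i], cnvrs$start[i], cnvrs$end[i],
                     rep_chip$probes, rep_chip$lrr, n_flank_probes,
                     min_probes, n_bins))
    ev$array_hellinger <- vapply(ae, `[[`, numeric(1), "hellinger")
    ev$array_median_lrr <- vapply(ae, `[[`, numeric(1), "median_lrr")
    pm_list <- lapply(arrays, `[[`, "probes")
    ev <- cbind(ev, probe_coverage(cnvrs, pm_list))
  }
  if (!is.null(genotypes)) {
    key <- function(d) paste(d$chrom, d$start, d$end)
    gt <- genotypes$genotype[match(key(cnvrs), key(genotypes))]
    gt[is.na(gt)] <- "NA"
    ev$lr_genotype <- gt
    ev$lr_concordance <- longread_concordance(gt)
  }
  for (db in names(databases)) {
    res <- lapply(seq_len(n), function(i)
      database_lookup(cnvrs$chrom[i], cnvrs$start[i], cnvrs$end[i],
                      cnvrs$type[i], databases[[db]], db_min_frac))
    ev[[paste0("db_", db, "_present")]] <-
      vapply(res, `[[`, logical(1), "present")
    ev[[paste0("db_", db, "_freq")]] <-
      vapply(res, `[[`, numeric(1), "frequency")
  }
  if (!is.null(segdups)) ev$segdup_frac <- segdup_fraction(cnvrs, segdups)
  if (!is.null(genome_seq)) {
    fc <- lapply(seq_len(n), function(i)
      flank_context(cnvrs$chrom[i], cnvrs$start[i], cnvrs$end[i],
                    genome_seq, repeats, flank_bp))
    ev$flank_gc <- vapply(fc, `[[`, numeric(1), "flank_gc")
    ev$has_flanking_repeat <- vapply(fc, function(x)
      as.logical(x$has_flanking_repeat), logical(1))
  }
  if (!is.null(mappability)) {
    ev$mean_mappability <- mean_mappability(cnvrs, mappability)
  }
  ev
}
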