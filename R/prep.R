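#' Depth-fold-change quality thresholds
#'
#' HQ deletion: DHFFC strictly below `del_hq_max`; HQ duplication: DHBFC
#' strictly above `dup_hq_min`. Defaults are the duphold developer's
#' recommended cutoffs (0.7 and 1.3).
#'
#' @param del_hq_max strict upper DHFFC bound for an HQ deletion.
#' @param dup_hq_min strict lower DHBFC bound for an HQ duplication.
#' @export
dfc_thresholds <- function(del_hq_max = 0.7, dup_hq_min = 1.3) {
  if (!(del_hq_max < 1 && 1 < dup_hq_min)) {
    stop("dfc_thresholds: need del_hq_max < 1 < dup_hq_min")
  }
  list(del_hq_max = del_hq_max, dup_hq_min = dup_hq_min)
}

#' Filter calls by size and exclusion regions
#'
#' Keeps calls strictly longer than `min_len_bp` that do not overlap any
#' exclusion interval (centromeres, telomeres, blacklisted regions) by
#' even a single basepair.
#'
#' @param calls canonical callset data.frame.
#' @param min_len_bp minimum length, strict (a call of exactly this length
#'   is removed).
#' @param exclusion_regions BED-style data.frame, or NULL for none.
#' @return the retained subset of `calls`.
#' @export
filter_calls <- function(calls, min_len_bp = 500, exclusion_regions = NULL) {
  stopifnot(min_len_bp >= 0)
  keep <- (calls$end - calls$start) > min_len_bp
  if (!is.null(exclusion_regions) && nrow(exclusion_regions) > 0 &&
      nrow(calls) > 0) {
    hits <- GenomicRanges::findOverlaps(intervals_to_gr(calls),
                                        intervals_to_gr(exclusion_regions),
                                        minoverlap = 1L)
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  calls[keep, , drop = FALSE]
}

interval_in_genome <- function(chrom, start, end, track) {
  lens <- attr(track, "chrom_lengths")
  if (!chrom %in% track$chrom) {
    stop("interval on unknown chromosome ", chrom)
  }
  if (!is.null(lens) && chrom %in% names(lens) && end > lens[[chrom]]) {
    stop("interval ", chrom, ":", start, "-", end, " outside genome")
  }
  invisible(TRUE)
}

depth_median_over <- function(track, chrom, start, end) {
  d <- track[track$chrom == chrom, , drop = FALSE]
  w <- pmin(d$end, end) - pmax(d$start, start)
  weighted_median(d$depth, pmax(w, 0))
}

# numeric core shared by compute_dhffc and the prepare_callsets fast path;
# bins (starts/ends/depths) are one chromosome, sorted by start
dhffc_core <- function(starts, ends, depths, chrom_len, start, end,
                       flank_bp) {
  win <- function(a, b) pmax(pmin(ends, b) - pmax(starts, a), 0)
  inside <- weighted_median(depths, win(start, end))
  w <- win(max(0, start - flank_bp), start) +
       win(end, min(chrom_len, end + flank_bp))
  flank <- weighted_median(depths, w)
  if (is.na(flank) || flank == 0) return(NA_real_)
  inside / flank
}

# background = median depth over GC-matched bins genome-wide (gc/depths
# aligned); inside median and target GC computed on the chromosome slice
dhbfc_core <- function(starts, ends, depths, gc_chrom, all_depths, all_gc,
                       start, end, gc_tolerance, warn_label = NULL) {
  w <- pmax(pmin(ends, end) - pmax(starts, start), 0)
  inside <- weighted_median(depths, w)
  if (is.null(all_gc)) {
    background <- stats::median(all_depths)
  } else {
    if (sum(w) == 0) return(NA_real_)
    target <- sum(gc_chrom * w) / sum(w)
    matched <- abs(all_gc - target) <= gc_tolerance
    if (!any(matched)) {
      if (!is.null(warn_label)) {
        warning("compute_dhbfc: no GC-matched bins for ", warn_label)
      }
      return(NA_real_)
    }
    background <- stats::median(all_depths[matched])
  }
  if (is.na(background) || background == 0) return(NA_real_)
  inside / background
}

#' Depth fold change versus flanking regions (DHFFC)
#'
#' Median per-basepair depth inside the interval divided by the median
#' over the two flanking windows pooled. Flanks are truncated at
#' chromosome ends. Returns NA when the flank median is 0 (fold change
#' undefined).
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param depth a [depth_track()].
#' @param flank_bp flank window width per side (default 1000 bp, the
#'   duphold convention).
#' @export
compute_dhffc <- function(chrom, start, end, depth, flank_bp = 1000) {
  stopifnot(flank_bp > 0)
  interval_in_genome(chrom, start, end, depth)
  lens <- attr(depth, "chrom_lengths")
  d <- depth[depth$chrom == chrom, , drop = FALSE]
  chrom_len <- if (!is.null(lens) && chrom %in% names(lens))
    lens[[chrom]] else max(d$end)
  dhffc_core(d$start, d$end, d$depth, chrom_len, start, end, flank_bp)
}

#' GC fraction per depth-track bin
#'
#' @param depth a [depth_track()].
#' @param genome_seq [Biostrings::DNAStringSet] named by chromosome.
#' @return numeric vector, one GC fraction per track row.
#' @export
gc_per_bin <- function(depth, genome_seq) {
  out <- numeric(nrow(depth))
  for (chrom in unique(depth$chrom)) {
    idx <- which(depth$chrom == chrom)
    v <- Biostrings::Views(genome_seq[[chrom]],
                           start = depth$start[idx] + 1L,
                           end = depth$end[idx])
    f <- Biostrings::letterFrequency(v, letters = c("G", "C"))
    out[idx] <- rowSums(f) / (depth$end[idx] - depth$start[idx])
  }
  out
}

#' GC-matched depth fold change (DHBFC)
#'
#' Median per-basepair depth inside the interval divided by the median
#' depth over all genome bins whose GC fraction lies within
#' `gc_tolerance` of the interval's mean GC. With `gc = NULL` all genome
#' bins are used (uniform-GC behaviour). Returns NA with a warning when no
#' bin matches.
#'
#' @inheritParams compute_dhffc
#' @param gc numeric GC fraction per track bin (see [gc_per_bin()]), or
#'   NULL.
#' @param gc_tolerance half-width of the GC matching window.
#' @export
compute_dhbfc <- function(chrom, start, end, depth, gc = NULL,
                          gc_tolerance = 0.05) {
  if (gc_tolerance < 0) stop("compute_dhbfc: gc_tolerance must be >= 0")
  interval_in_genome(chrom, start, end, depth)
  sel <- depth$chrom == chrom
  d <- depth[sel, , drop = FALSE]
  if (!is.null(gc)) stopifnot(length(gc) == nrow(depth))
  dhbfc_core(d$start, d$end, d$depth, gc[sel], depth$depth, gc,
             start, end, gc_tolerance,
             warn_label = paste0(chrom, ":", start, "-", end))
}

#' HQ/LQ quality labeling from depth fold change
#'
#' A deletion is HQ iff its DHFFC is strictly below the deletion
#' threshold; a duplication is HQ iff its DHBFC is strictly above the
#' duplication threshold; anything else — including a missing score — is
#' LQ.
#'
#' @param type character vector of "DEL"/"DUP".
#' @param dhffc,dhbfc numeric vectors (NA allowed).
#' @param thresholds a [dfc_thresholds()].
#' @return character vector of "HQ"/"LQ".
#' @export
label_quality <- function(type, dhffc, dhbfc,
                          thresholds = dfc_thresholds()) {
  stopifnot(all(type %in% CNV_TYPES))
  hq <- ifelse(type == "DEL",
               !is.na(dhffc) & dhffc < thresholds$del_hq_max,
               !is.na(dhbfc) & dhbfc > thresholds$dup_hq_min)
  ifelse(hq, "HQ", "LQ")
}

#' Bin an intrinsic score
#'
#' Scores below 1 -> "below1"; in \[1, 5) -> "one_to_five"; at or above
#' 5 -> "five_plus".
#'
#' @param score numeric vector of non-negative scores; NA passes through.
#' @export
assign_score_bin <- function(score) {
  if (any(score < 0, na.rm = TRUE)) {
    stop("assign_score_bin: negative score")
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score < 1, "below1",
                ifelse(score < 5, "one_to_five", "five_plus")))
}

#' Normalize a consensus support count onto the 0-100 score scale
#'
#' A consensus callset reports, per variant, the number of approaches
#' supporting it (out of `max_n`); this maps that count linearly onto the
#' 0-100 intrinsic-score scale: n / max_n x 100.
#'
#' @param n integer count(s) of supporting approaches, in 1..max_n.
#' @param max_n maximum number of approaches (default 7).
#' @export
normalize_consensus_score <- function(n, max_n = 7) {
  if (any(n < 1 | n > max_n)) {
    stop("normalize_consensus_score: n must be in [1, ", max_n, "]")
  }
  n / max_n * 100
}

#' Normalize a GRIDSS-style score by dividing by 100
#'
#' @param score non-negative numeric vector.
#' @export
normalize_gridss_score <- function(score) {
  stopifnot(all(score >= 0, na.rm = TRUE))
  score / 100
}

#' Annotate untyped regions with a copy-number type by reciprocal overlap
#'
#' A region receives the DEL/DUP type of a typed reference segment with at
#' least `reciprocal_frac` mutual overlap (each interval covered to that
#' fraction by the other). If qualifying references disagree on the type,
#' or none qualifies, the type stays NA — so no region is ever annotated
#' with two types.
#'
#' @param regions BED-style data.frame (its `type` column, if any, is
#'   overwritten).
#' @param reference data.frame with chrom, start, end, type.
#' @param reciprocal_frac mutual-overlap fraction in (0, 1\] (default
#'   0.7).
#' @return `regions` with a `type` column (NA where unresolved).
#' @export
annotate_copy_number <- function(regions, reference, reciprocal_frac = 0.7) {
  if (!(reciprocal_frac > 0 && reciprocal_frac <= 1)) {
    stop("annotate_copy_number: reciprocal_frac must be in (0, 1]")
  }
  stopifnot(all(reference$type %in% CNV_TYPES))
  out_type <- rep(NA_character_, nrow(regions))
  if (nrow(regions) > 0 && nrow(reference) > 0) {
    hits <- GenomicRanges::findOverlaps(intervals_to_gr(regions),
                                        intervals_to_gr(reference))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(regions$end[qh], reference$end[sh]) -
          pmax(regions$start[qh], reference$start[sh])
    ok <- ov >= reciprocal_frac * (regions$end[qh] - regions$start[qh]) &
          ov >= reciprocal_frac * (reference$end[sh] - reference$start[sh])
    for (i in unique(qh[ok])) {
      types <- unique(reference$type[sh[ok & qh == i]])
      if (length(types) == 1) out_type[i] <- types
    }
  }
  regions$type <- out_type
  regions
}

#' Prepare callsets: filter, score, label
#'
#' The per-call stage applied before any aggregation: size/exclusion
#' filtering, depth-fold-change computation from the shared depth track,
#' and HQ/LQ labeling.
#'
#' @param calls canonical callset data.frame.
#' @param depth a [depth_track()].
#' @param exclusions BED-style exclusion regions or NULL.
#' @param genome_seq optional [Biostrings::DNAStringSet] for GC-matched
#'   DHBFC; with NULL, DHBFC uses the genome-wide depth median.
#' @param thresholds a [dfc_thresholds()].
#' @param min_len_bp strict minimum call length (default 500).
#' @param flank_bp DHFFC flank width per side.
#' @param gc_tolerance DHBFC GC matching half-width.
#' @return filtered callset with dhffc, dhbfc and quality columns filled.
#' @export
prepare_callsets <- function(calls, depth, exclusions = NULL,
                             genome_seq = NULL,
                             thresholds = dfc_thresholds(),
                             min_len_bp = 500, flank_bp = 1000,
                             gc_tolerance = 0.05) {
  calls <- filter_calls(calls, min_len_bp, exclusions)
  gc <- if (!is.null(genome_seq)) gc_per_bin(depth, genome_seq) else NULL
  lens <- attr(depth, "chrom_lengths")
  # pre-split the track per chromosome once; the cores work on numeric
  # vectors so the per-call cost does not rescan the whole genome
  by_chrom <- lapply(stats::setNames(nm = unique(depth$chrom)),
                     function(ch) {
                       sel <- depth$chrom == ch
                       list(start = depth$start[sel], end = depth$end[sel],
                            depth = depth$depth[sel],
                            gc = if (!is.null(gc)) gc[sel],
                            len = if (!is.null(lens) && ch %in% names(lens))
                              lens[[ch]] else max(depth$end[sel]))
                     })
  # exact fast background medians for integer depth tracks: per unique GC
  # value, a depth histogram; a target's matched-bin median is then read
  # off the summed histogram (identical membership and value to the
  # direct median in compute_dhbfc)
  gc_hist <- NULL
  if (!is.null(gc) && nrow(depth) > 0 &&
      all(depth$depth == round(depth$depth))) {
    uniq_gc <- sort(unique(gc))
    gc_hist <- list(
      uniq = uniq_gc,
      counts = unclass(table(factor(match(gc, uniq_gc),
                                    levels = seq_along(uniq_gc)),
                             factor(depth$depth,
                                    levels = 0:max(depth$depth)))))
  }
  median_from_hist <- function(h) {
    n <- sum(h)
    if (n == 0) return(NA_real_)
    cs <- cumsum(h)
    vals <- as.numeric(names(h))
    lo <- vals[which(cs >= ceiling(n / 2))[1]]
    hi <- vals[which(cs >= floor(n / 2) + 1)[1]]
    (lo + hi) / 2
  }
  n <- nrow(calls)
  dhffc <- numeric(n); dhbfc <- numeric(n)
  for (i in seq_len(n)) {
    ch <- by_chrom[[calls$chrom[i]]]
    if (is.null(ch)) stop("call on unknown chromosome ", calls$chrom[i])
    s <- calls$start[i]; e <- calls$end[i]
    # slice to the bins that can carry weight
    i0 <- max(1L, findInterval(max(0, s - flank_bp), ch$start))
    i1 <- min(length(ch$start), findInterval(e + flank_bp, ch$start) + 1L)
    sl <- i0:i1
    dhffc[i] <- dhffc_core(ch$start[sl], ch$end[sl], ch$depth[sl],
                           ch$len, s, e, flank_bp)
    if (is.null(gc_hist)) {
      dhbfc[i] <- dhbfc_core(ch$start, ch$end, ch$depth, ch$gc,
                             depth$depth, gc, s, e, gc_tolerance)
    } else {
      w <- pmax(pmin(ch$end[sl], e) - pmax(ch$start[sl], s), 0)
      inside <- weighted_median(ch$depth[sl], w)
      target <- sum(ch$gc[sl] * w) / sum(w)
      sel <- abs(gc_hist$uniq - target) <= gc_tolerance
      background <- if (!any(sel)) NA_real_ else
        median_from_hist(colSums(gc_hist$counts[sel, , drop = FALSE]))
      dhbfc[i] <- if (is.na(background) || background == 0) NA_real_
                  else inside / background
    }
  }
  calls$dhffc <- dhffc
  calls$dhbfc <- dhbfc
  calls$quality <- label_quality(calls$type, dhffc, dhbfc, thresholds)
  calls
}
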