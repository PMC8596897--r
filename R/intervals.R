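#' Genomic interval conventions
#'
#' All tables in this package use BED-style coordinates: `start` is 0-based
#' inclusive, `end` is exclusive, so the length of an interval is
#' `end - start` basepairs. Any 1-based input dialect (e.g. VCF POS) is
#' converted at the reader boundary and never downstream.
#'
#' @name interval-conventions
#' @keywords internal
NULL

#' Validate a table of genomic intervals
#'
#' Checks the `chrom`, `start`, `end` columns of a BED-style table:
#' numeric coordinates, `start >= 0`, `end > start` (zero-length intervals
#' are invalid).
#'
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly, with `start`/`end` coerced to integer-valued
#'   numeric.
#' @export
validate_intervals <- function(df, what = "interval table") {
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop(what, ": non-numeric coordinates")
  }
  if (nrow(df) > 0) {
    if (any(is.na(df$start)) || any(is.na(df$end))) {
      stop(what, ": NA coordinates")
    }
    if (any(df$start < 0)) stop(what, ": negative start coordinate")
    bad <- which(df$end <= df$start)
    if (length(bad) > 0) {
      stop(what, ": end <= start at row ", bad[1],
           " (", df$chrom[bad[1]], ":", df$start[bad[1]], "-",
           df$end[bad[1]], ")")
    }
  }
  invisible(df)
}

#' Convert a BED-style table to GRanges
#'
#' @param df data.frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @return a [GenomicRanges::GRanges] (1-based closed, as GRanges requires).
#' @keywords internal
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Convert GRanges back to a BED-style table
#' @keywords internal
gr_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Sort a BED-style table by (chrom, start, end)
#' @keywords internal
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Basepair overlap of one interval with a set of intervals
#'
#' @param chrom,start,end the query interval (0-based half-open).
#' @param df a BED-style table.
#' @return integer vector of overlap widths, one per row of `df` (0 for
#'   non-overlapping rows, including rows on other chromosomes).
#' @keywords internal
overlap_bp <- function(chrom, start, end, df) {
  w <- pmin(df$end, end) - pmax(df$start, start)
  w[df$chrom != chrom] <- 0L
  pmax(w, 0L)
}

#' Weighted median
#'
#' Median of a distribution placing mass `w[i]` on `x[i]`; used for the
#' per-basepair depth median over partially overlapped bins.
#'
#' @keywords internal
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w))
  keep <- w > 0 & !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  lo <- x[which(cw >= 0.5)[1]]
  hi <- x[which(cw > 0.5)[1]]
  if (is.na(hi)) hi <- lo  # exact 0.5 boundary: average the straddling pair
  (lo + hi) / 2
}
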