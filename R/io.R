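#' @importFrom utils read.delim write.table head tail
NULL

TECHNOLOGIES <- c("array", "sr", "lr")
CNV_TYPES <- c("DEL", "DUP")
GENOTYPES <- c("0/0", "0/1", "1/1", "NA")

norm_chrom <- function(chrom, chr_prefix = TRUE) {
  chrom <- as.character(chrom)
  bare <- sub("^chr", "", chrom)
  if (chr_prefix) paste0("chr", bare) else bare
}

#' Read a CNV callset table
#'
#' Reads a BED-like TSV with a header into the package's canonical callset
#' table. Required columns: `chrom`, `start`, `end`, `type` (DEL/DUP),
#' `dataset`, `technology` (array/sr/lr). Optional columns carried through:
#' `score` (caller-native intrinsic score, 0-100 scale), `dhffc`, `dhbfc`,
#' `copy_number`. Missing optional values are `NA`, never sentinel numbers.
#'
#' @param path path to a TSV with header.
#' @param one_based if TRUE, input coordinates are 1-based closed and are
#'   converted to 0-based half-open on read.
#' @param chr_prefix normalize chromosome names to carry (TRUE, default) or
#'   drop (FALSE) the "chr" prefix.
#' @return data.frame with columns chrom, start, end, type, dataset,
#'   technology, score, dhffc, dhbfc, copy_number and a unique `call_id`.
#' @export
read_callset <- function(path, one_based = FALSE, chr_prefix = TRUE) {
  if (!file.exists(path)) stop("callset file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_callset(df, one_based = one_based, chr_prefix = chr_prefix,
             what = paste0("callset ", basename(path)))
}

#' Normalize a raw data.frame into the canonical callset table
#'
#' @param df data.frame with at least chrom, start, end, type, dataset,
#'   technology.
#' @inheritParams read_callset
#' @param what label for error messages.
#' @export
as_callset <- function(df, one_based = FALSE, chr_prefix = TRUE,
                       what = "callset") {
  req <- c("chrom", "start", "end", "type", "dataset", "technology")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0 || any(is.na(v))) {
      stop(what, ": malformed coordinate in column '", col, "' at data row ",
           if (length(bad) > 0) bad[1] else which(is.na(v))[1])
    }
    df[[col]] <- v
  }
  if (one_based) df$start <- df$start - 1
  df$chrom <- norm_chrom(df$chrom, chr_prefix)
  validate_intervals(df, what)
  bad_type <- which(!df$type %in% CNV_TYPES)
  if (length(bad_type) > 0) {
    stop(what, ": unknown CNV type '", df$type[bad_type[1]],
         "' at data row ", bad_type[1])
  }
  bad_tech <- which(!df$technology %in% TECHNOLOGIES)
  if (length(bad_tech) > 0) {
    stop(what, ": unknown technology '", df$technology[bad_tech[1]],
         "' at data row ", bad_tech[1])
  }
  for (col in c("score", "dhffc", "dhbfc", "copy_number")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (any(!is.na(df$score) & (df$score < 0 | df$score > 100))) {
    stop(what, ": intrinsic score outside [0, 100]")
  }
  if (any(!is.na(df$dhffc) & df$dhffc < 0) ||
      any(!is.na(df$dhbfc) & df$dhbfc < 0)) {
    stop(what, ": negative depth fold change score")
  }
  keep <- c(req, "score", "dhffc", "dhbfc", "copy_number")
  # annotation columns survive a disk round-trip of prepared callsets
  extra <- intersect(c("call_id", "quality", "truth_id"), names(df))
  df <- df[, c(keep, extra), drop = FALSE]
  df$dataset <- as.character(df$dataset)
  if ("truth_id" %in% extra) df$truth_id <- as.character(df$truth_id)
  if (!"call_id" %in% names(df)) {
    df$call_id <- sprintf("%s:%s:%d-%d:%s:%d", df$dataset, df$chrom,
                          as.integer(df$start), as.integer(df$end),
                          df$type, seq_len(nrow(df)))
  }
  rownames(df) <- NULL
  df
}

#' Write a callset table
#'
#' Deterministic column order and (chrom, start, end) row sort.
#' @param calls canonical callset data.frame.
#' @param path output TSV path.
#' @export
write_callset <- function(calls, path) {
  cols <- c("chrom", "start", "end", "type", "dataset", "technology",
            "score", "dhffc", "dhbfc", "copy_number")
  extra <- setdiff(names(calls), c(cols, "call_id"))
  out <- sort_intervals(calls)[, c(cols, extra), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest DEL/DUP records from a VCF into the canonical callset table
#'
#' Thin adapter over [VariantAnnotation::readVcf()]: keeps records whose
#' `SVTYPE` is DEL or DUP, takes the end coordinate from the `END` info key,
#' and normalizes to the 0-based half-open callset model.
#'
#' @param path VCF path.
#' @param dataset,technology identifiers attached to every record.
#' @inheritParams read_callset
#' @export
read_callset_vcf <- function(path, dataset, technology, chr_prefix = TRUE) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_callset_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  svtype <- as.character(info$SVTYPE)
  keep <- !is.na(svtype) & svtype %in% CNV_TYPES
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  endv <- as.integer(unlist(info$END))[keep]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr) - 1L,  # VCF POS is 1-based
    end = endv,
    type = svtype[keep],
    dataset = dataset,
    technology = technology,
    stringsAsFactors = FALSE
  )
  as_callset(df, chr_prefix = chr_prefix, what = paste0("VCF ", basename(path)))
}

#' Construct a depth track
#'
#' A depth track is a per-chromosome tiling of fixed-width bins with a mean
#' read depth per bin. Gaps between input bins are filled with depth 0 so
#' the bins tile each chromosome from 0 to its last covered base.
#'
#' @param df data.frame with chrom, start, end, depth (0-based half-open).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, trailing gaps up to the chromosome end are zero-filled too.
#' @return a `depth_track`: sorted, gap-free data.frame with attribute
#'   `chrom_lengths`.
#' @export
depth_track <- function(df, chrom_lengths = NULL) {
  names(df)[names(df) == "score"] <- "depth"
  validate_intervals(df, "depth track")
  if (any(!is.finite(df$depth)) || any(df$depth < 0)) {
    stop("depth track: depths must be finite and >= 0")
  }
  df <- sort_intervals(df)
  pieces <- lapply(split(df, df$chrom), function(d) {
    if (any(d$start[-1] < d$end[-nrow(d)])) {
      stop("depth track: overlapping bins on ", d$chrom[1])
    }
    len <- if (!is.null(chrom_lengths) && d$chrom[1] %in% names(chrom_lengths))
      chrom_lengths[[d$chrom[1]]] else max(d$end)
    # fill gaps (including a leading gap from 0) with zero-depth bins
    bounds <- unique(sort(c(0, d$start, d$end, len)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    idx <- findInterval(starts, d$start)
    depth <- ifelse(idx >= 1 & starts < d$end[pmax(idx, 1)] &
                      starts >= d$start[pmax(idx, 1)],
                    d$depth[pmax(idx, 1)], 0)
    data.frame(chrom = d$chrom[1], start = starts, end = ends,
               depth = depth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(out$end, out$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  structure(out, chrom_lengths = chrom_lengths,
            class = c("depth_track", "data.frame"))
}

#' Read a bedGraph file into a depth track
#'
#' @param path 4-column bedGraph (no header, or a `track` line).
#' @inheritParams depth_track
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- gr_to_intervals(gr)
  df$depth <- gr$score
  depth_track(df, chrom_lengths = chrom_lengths)
}

#' Write a depth track as bedGraph
#' @export
write_bedgraph <- function(track, path) {
  gr <- intervals_to_gr(track)
  gr$score <- track$depth
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED3+ interval annotation
#'
#' Records are sorted per chromosome; overlapping or nested records are
#' preserved as-is (merging, where needed, is an explicit separate step).
#'
#' @param path BED path.
#' @param chr_prefix see [read_callset()].
#' @return BED-style data.frame (chrom, start, end, and `name` if present).
#' @export
read_interval_annotation <- function(path, chr_prefix = TRUE) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED ", path, ": ",
                                          conditionMessage(e)))
  df <- gr_to_intervals(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  df$chrom <- norm_chrom(df$chrom, chr_prefix)
  validate_intervals(df, paste0("BED ", basename(path)))
  sort_intervals(df)
}

#' Write a BED-style table
#' @export
write_bed <- function(df, path) {
  out <- sort_intervals(df)
  gr <- intervals_to_gr(out)
  if (!is.null(out$name)) gr$name <- out$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a probe map
#'
#' TSV with header columns `probe_id`, `chrom`, `position` (0-based). A
#' probe at position p lies inside an interval \[start, end) iff
#' start <= p < end.
#'
#' @param path TSV path.
#' @param chip_id chip identifier attached as an attribute.
#' @export
read_probe_map <- function(path, chip_id = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  probe_map(df, chip_id)
}

#' @rdname read_probe_map
#' @param df data.frame with probe_id, chrom, position.
#' @export
probe_map <- function(df, chip_id) {
  req <- c("probe_id", "chrom", "position")
  if (!all(req %in% names(df))) {
    stop("probe map: need columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) stop("probe map: duplicate probe_id")
  df <- df[order(df$chrom, df$position), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, chip_id = chip_id, class = c("probe_map", "data.frame"))
}

#' Read an LRR signal table
#'
#' TSV with header columns `probe_id`, `lrr` (Log R Ratio). Missing values
#' are allowed on input and dropped by the evidence assays.
#' @param path TSV path.
#' @export
read_lrr <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "lrr") %in% names(df))) {
    stop("LRR table: need columns probe_id, lrr")
  }
  df$lrr <- suppressWarnings(as.numeric(df$lrr))
  df
}

#' Read a long-read genotype table
#'
#' TSV with header columns `chrom`, `start`, `end`, `genotype`; genotypes
#' are 0/0, 0/1, 1/1 or NA (the literal string "NA" meaning no assigned
#' genotype, as VaPoR-style validators emit).
#' @param path TSV path.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = character(0))
  validate_intervals(df, "genotype table")
  if (!"genotype" %in% names(df)) stop("genotype table: missing 'genotype'")
  df$genotype[is.na(df$genotype)] <- "NA"
  bad <- which(!df$genotype %in% GENOTYPES)
  if (length(bad) > 0) {
    stop("genotype table: unknown genotype '", df$genotype[bad[1]],
         "' at data row ", bad[1])
  }
  df
}

#' Read a public-database CNV table
#'
#' TSV with header columns `db_id`, `chrom`, `start`, `end`, `type`,
#' `frequency` (population frequency in \[0,1\]).
#' @param path TSV path.
#' @export
read_database <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("db_id", "chrom", "start", "end", "type", "frequency")
  if (!all(req %in% names(df))) {
    stop("database table: need columns ", paste(req, collapse = ", "))
  }
  validate_intervals(df, "database table")
  if (any(!df$type %in% CNV_TYPES)) stop("database table: unknown CNV type")
  if (any(df$frequency < 0 | df$frequency > 1, na.rm = TRUE)) {
    stop("database table: frequency outside [0, 1]")
  }
  df
}

#' Read a fixed-step mappability track
#'
#' Accepts a wiggle (fixedStep) file as a stand-in for the bigWig
#' mappability tracks used in genome annotation.
#'
#' @param path wig path.
#' @return data.frame chrom, start, end, value (values in \[0,1\]).
#' @export
read_step_track <- function(path) {
  gr <- rtracklayer::import(path, format = "wig")
  df <- gr_to_intervals(gr)
  df$value <- gr$score
  if (any(df$value < 0 | df$value > 1)) {
    stop("mappability track: values outside [0, 1]")
  }
  sort_intervals(df)
}

#' Generic TSV writer with deterministic row sort
#' @keywords internal
write_tsv_sorted <- function(df, path) {
  if (all(c("chrom", "start", "end") %in% names(df))) df <- sort_intervals(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
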