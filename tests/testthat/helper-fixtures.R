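# Small in-code fixtures and independent brute-force oracles used across
# the suite. Oracles are deliberately naive O(n^2)/per-base
# implementations, kept independent of the package's interval machinery.

flat_track <- function(depth = 30, len = 10000, bw = 100,
                       chroms = "chr1") {
  df <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(0, len - 1, by = bw)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bw, len),
               depth = depth, stringsAsFactors = FALSE)
  }))
  depth_track(df, chrom_lengths = stats::setNames(rep(len, length(chroms)),
                                                  chroms))
}

mk_calls <- function(chrom, start, end, type = "DEL", dataset = "ds1",
                     technology = "sr", quality = NULL, score = NA_real_,
                     dhffc = NA_real_, dhbfc = NA_real_) {
  df <- data.frame(chrom = chrom, start = start, end = end, type = type,
                   dataset = dataset, technology = technology,
                   score = score, dhffc = dhffc, dhbfc = dhbfc,
                   stringsAsFactors = FALSE)
  out <- as_callset(df)
  if (!is.null(quality)) out$quality <- quality
  out
}

random_calls <- function(n, seed, technology = "sr", len = 1e6,
                         chroms = c("chr1", "chr2"), quality = NULL,
                         n_datasets = 3) {
  set.seed(seed)
  start <- floor(runif(n, 0, len - 5000))
  mk_calls(chrom = sample(chroms, n, replace = TRUE),
           start = start,
           end = start + floor(runif(n, 501, 5000)),
           type = sample(c("DEL", "DUP"), n, replace = TRUE),
           dataset = sample(paste0("ds", seq_len(n_datasets)), n,
                            replace = TRUE),
           technology = technology,
           quality = quality,
           score = round(runif(n, 0, 20), 2))
}

# O(n^2) transitive-closure merge oracle: connected components under
# same-chromosome >=1-bp overlap, outermost breakpoints
bf_merge <- function(df) {
  n <- nrow(df)
  if (n == 0) return(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), n_members = integer(0)))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (df$chrom[i] == df$chrom[j] &&
          df$start[i] < df$end[j] && df$start[j] < df$end[i] &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cid) {
    m <- df[comp == cid, ]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_members = nrow(m), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# per-base bitmap coverage oracle for overlap fractions
bf_covered_bp <- function(chrom, start, end, track) {
  if (end <= start) return(0L)
  covered <- logical(end - start)
  for (k in seq_len(nrow(track))) {
    if (track$chrom[k] != chrom) next
    a <- max(track$start[k], start); b <- min(track$end[k], end)
    if (b > a) covered[(a - start + 1):(b - start)] <- TRUE
  }
  sum(covered)
}

# independent histogram Bhattacharyya/Hellinger implementation via hist()
bf_hellinger <- function(a, b, n_bins = 20) {
  lo <- min(a, b); hi <- max(a, b)
  if (lo == hi) return(0)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  ha <- hist(a, breaks = breaks, plot = FALSE)$counts
  hb <- hist(b, breaks = breaks, plot = FALSE)$counts
  bc <- sum(sqrt((ha / sum(ha)) * (hb / sum(hb))))
  sqrt(max(0, 1 - bc))
}

# hand-built CNVR rows with the full CNVR table schema
mk_cnvrs <- function(chrom, start, end, technology = "sr", type = "DEL",
                     quality = "HQ", score = NA_real_,
                     support = "single") {
  n <- length(start)
  data.frame(
    cnvr_id = sprintf("c%02d_%s_%s", seq_len(n), rep(technology,
                                                     length.out = n),
                      rep(quality, length.out = n)),
    chrom = chrom, start = start, end = end,
    type = rep(type, length.out = n),
    technology = rep(technology, length.out = n),
    quality = rep(quality, length.out = n),
    n_calls = ifelse(rep(support, length.out = n) == "single", 1L, 3L),
    n_datasets = 1L,
    support_class = rep(support, length.out = n),
    median_score = rep(score, length.out = n),
    median_dhffc = NA_real_, median_dhbfc = NA_real_,
    stringsAsFactors = FALSE)
}

# n CNVRs of one fixed length and support class, laid out disjointly
mk_cnvrs_len <- function(len, support, n) {
  start <- seq(0, by = len + 1000, length.out = n)
  out <- mk_cnvrs(rep("chr1", n), start, start + len, support = support)
  out$cnvr_id <- paste0(out$cnvr_id, "_", support, seq_len(n))
  out
}

tiny_sim_config <- function(seed, ...) {
  sim_config(seed = seed, genome = c(chr1 = 2e6), n_variants = 20,
             size_range = c(600, 5000), ...)
}
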