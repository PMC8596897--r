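#' Connected components of the >=1-bp-overlap graph
#'
#' @param df BED-style data.frame.
#' @return list(regions = data.frame(chrom, start, end),
#'   member_idx = list of integer row-index vectors into `df`).
#' @keywords internal
merge_connected <- function(df) {
  # single sorted sweep per chromosome: a new component opens when the
  # next start sits at or beyond the running max end, so book-ended
  # (0-bp-shared) intervals stay apart and only strict >=1-bp overlaps
  # merge; for intervals this equals the transitive closure of the
  # overlap graph
  n <- nrow(df)
  o <- order(df$chrom, df$start, df$end)
  ch <- df$chrom[o]; st <- df$start[o]; en <- df$end[o]
  comp <- integer(n)
  cid <- 0L; cur_end <- -Inf; cur_ch <- ""
  for (i in seq_len(n)) {
    if (ch[i] != cur_ch || st[i] >= cur_end) {
      cid <- cid + 1L
      cur_ch <- ch[i]
      cur_end <- en[i]
    } else {
      cur_end <- max(cur_end, en[i])
    }
    comp[i] <- cid
  }
  first <- !duplicated(comp)
  regions <- data.frame(
    chrom = ch[first],
    start = st[first],  # min start: rows are start-sorted within comp
    end = as.numeric(tapply(en, comp, max)),
    stringsAsFactors = FALSE)
  list(regions = regions, member_idx = unname(split(o, comp)))
}

#' Median score propagated over region members
#'
#' Members without a score are excluded; an even member count takes the
#' mean of the central pair; no scored member gives NA.
#'
#' @param scores numeric vector of member scores (NA allowed).
#' @export
propagate_median_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(NA_real_)
  stats::median(scores)
}

#' Within-technology support of a region
#'
#' A region is "single" iff it derives from exactly one CNV call;
#' otherwise "multi". The distinct-dataset count is reported separately
#' (a region built from two calls of one dataset is multi with
#' n_datasets = 1).
#'
#' @param member_datasets character vector: dataset id of each member
#'   call.
#' @return list(n_datasets, support_class).
#' @export
count_support <- function(member_datasets) {
  stopifnot(length(member_datasets) >= 1)
  list(n_datasets = length(unique(member_datasets)),
       support_class = if (length(member_datasets) == 1) "single"
                       else "multi")
}

cnvr_row <- function(calls, idx, region, technology, type, quality) {
  m <- calls[idx, , drop = FALSE]
  sup <- count_support(m$dataset)
  data.frame(
    cnvr_id = sprintf("%s_%s_%s_%s_%d_%d", technology, type, quality,
                      region$chrom, as.integer(region$start),
                      as.integer(region$end)),
    chrom = region$chrom, start = region$start, end = region$end,
    type = type, technology = technology, quality = quality,
    n_calls = nrow(m), n_datasets = sup$n_datasets,
    support_class = sup$support_class,
    median_score = propagate_median_score(m$score),
    median_dhffc = propagate_median_score(m$dhffc),
    median_dhbfc = propagate_median_score(m$dhbfc),
    truth_derived = if ("truth_id" %in% names(m)) any(!is.na(m$truth_id))
                    else NA,
    member_call_ids = paste(m$call_id, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Merge homogeneous calls into CNV regions
#'
#' Collapses calls of one technology, one CNV type and one quality bin
#' into CNV regions (CNVRs): the connected components of the graph of
#' at-least-1-bp overlaps, each spanning the outermost member breakpoints,
#' with support metadata and median-propagated scores.
#'
#' @param calls canonical callset rows, homogeneous in technology, type
#'   and quality.
#' @return CNVR data.frame (one row per region).
#' @export
merge_calls <- function(calls) {
  if (nrow(calls) == 0) return(empty_cnvr())
  if (length(unique(calls$technology)) > 1) {
    stop("merge_calls: mixed technologies")
  }
  if (length(unique(calls$type)) > 1) stop("merge_calls: mixed CNV types")
  if (!"quality" %in% names(calls) ||
      length(unique(calls$quality)) > 1) {
    stop("merge_calls: calls must carry one quality bin")
  }
  mc <- merge_connected(calls)
  out <- do.call(rbind, lapply(seq_len(nrow(mc$regions)), function(i) {
    cnvr_row(calls, mc$member_idx[[i]], mc$regions[i, ],
             calls$technology[1], calls$type[1], calls$quality[1])
  }))
  rownames(out) <- NULL
  out
}

empty_cnvr <- function() {
  data.frame(cnvr_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), type = character(0),
             technology = character(0), quality = character(0),
             n_calls = integer(0), n_datasets = integer(0),
             support_class = character(0), median_score = numeric(0),
             median_dhffc = numeric(0), median_dhbfc = numeric(0),
             truth_derived = logical(0), member_call_ids = character(0),
             stringsAsFactors = FALSE)
}

#' Aggregate one technology's callsets into its CNVR master set
#'
#' Sequencing technologies (`split_then_merge`): calls are split into HQ
#' and LQ sets first and merged within each set, so low-quality segments
#' never drive artefact regions. Arrays (`merge_then_split`): calls are
#' first merged within each dataset (collapsing replicate and
#' multi-caller redundancy), each merged segment is re-labeled from the
#' median fold change of its members, and only then are segments split by
#' quality and merged across datasets.
#'
#' Deletions and duplications are merged entirely independently at every
#' stage.
#'
#' @param calls prepared calls of one technology (with `quality`).
#' @param technology "array", "sr" or "lr".
#' @param mode "split_then_merge" or "merge_then_split"; defaults to the
#'   technology's convention.
#' @param thresholds [dfc_thresholds()] used to re-label array segments.
#' @return CNVR data.frame.
#' @export
aggregate_technology <- function(calls, technology,
                                 mode = if (technology == "array")
                                   "merge_then_split" else
                                   "split_then_merge",
                                 thresholds = dfc_thresholds()) {
  if (!technology %in% TECHNOLOGIES) {
    stop("aggregate_technology: unknown technology ", technology)
  }
  if (!mode %in% c("split_then_merge", "merge_then_split")) {
    stop("aggregate_technology: unknown mode ", mode)
  }
  calls <- calls[calls$technology == technology, , drop = FALSE]
  if (nrow(calls) == 0) return(empty_cnvr())
  out <- list()
  for (type in CNV_TYPES) {
    tc <- calls[calls$type == type, , drop = FALSE]
    if (nrow(tc) == 0) next
    if (mode == "split_then_merge") {
      for (q in c("HQ", "LQ")) {
        qc <- tc[tc$quality == q, , drop = FALSE]
        if (nrow(qc) > 0) out[[length(out) + 1L]] <- merge_calls(qc)
      }
    } else {
      # stage 1: collapse within each dataset, ignoring quality
      segs <- list()
      for (ds in unique(tc$dataset)) {
        dc <- tc[tc$dataset == ds, , drop = FALSE]
        mc <- merge_connected(dc)
        for (i in seq_len(nrow(mc$regions))) {
          m <- dc[mc$member_idx[[i]], , drop = FALSE]
          seg <- mc$regions[i, ]
          seg$type <- type; seg$dataset <- ds; seg$technology <- technology
          seg$dhffc <- propagate_median_score(m$dhffc)
          seg$dhbfc <- propagate_median_score(m$dhbfc)
          seg$score <- propagate_median_score(m$score)
          seg$quality <- label_quality(type, seg$dhffc, seg$dhbfc,
                                       thresholds)
          seg$member_ids <- list(m$call_id)
          seg$member_datasets <- list(m$dataset)
          seg$member_scores <- list(m$score)
          seg$member_dhffc <- list(m$dhffc)
          seg$member_dhbfc <- list(m$dhbfc)
          seg$member_truth <- list(if ("truth_id" %in% names(m))
            m$truth_id else rep(NA_character_, nrow(m)))
          segs[[length(segs) + 1L]] <- seg
        }
      }
      segs <- do.call(rbind, segs)
      # stage 2: split segments by quality, merge across datasets
      for (q in c("HQ", "LQ")) {
        qs <- segs[segs$quality == q, , drop = FALSE]
        if (nrow(qs) == 0) next
        mc <- merge_connected(qs)
        for (i in seq_len(nrow(mc$regions))) {
          s <- qs[mc$member_idx[[i]], , drop = FALSE]
          flat <- data.frame(
            call_id = unlist(s$member_ids),
            dataset = unlist(s$member_datasets),
            score = unlist(s$member_scores),
            dhffc = unlist(s$member_dhffc),
            dhbfc = unlist(s$member_dhbfc),
            truth_id = unlist(s$member_truth),
            stringsAsFactors = FALSE)
          out[[length(out) + 1L]] <-
            cnvr_row(flat, seq_len(nrow(flat)), mc$regions[i, ],
                     technology, type, q)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- sort_intervals(res)
  rownames(res) <- NULL
  res
}

#' Aggregate all technologies into one CNVR table
#'
#' @param calls prepared calls (all technologies).
#' @param thresholds [dfc_thresholds()].
#' @return combined CNVR data.frame.
#' @export
aggregate_all <- function(calls, thresholds = dfc_thresholds()) {
  res <- do.call(rbind, lapply(intersect(TECHNOLOGIES,
                                         unique(calls$technology)),
                               function(tech)
                                 aggregate_technology(calls, tech,
                                                      thresholds = thresholds)))
  if (is.null(res)) empty_cnvr() else res
}
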