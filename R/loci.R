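LOCUS_SETS <- c("all", "above1", "above5", "above1_HQ")

#' Locus-set specification
#'
#' The four quality regimes under which cross-technology CNV loci are
#' built: `all` (no filter), `above1` / `above5` (long-read CNVRs kept
#' only with median intrinsic score strictly above 1 / 5), and
#' `above1_HQ` (score > 1 and HQ-only CNVRs for every technology).
#'
#' @param locus_set_id one of "all", "above1", "above5", "above1_HQ".
#' @export
locus_set_spec <- function(locus_set_id) {
  if (!locus_set_id %in% LOCUS_SETS) {
    stop("locus_set_spec: unknown locus set '", locus_set_id, "'")
  }
  list(locus_set_id = locus_set_id,
       lr_score_min = switch(locus_set_id, all = NA_real_, above1 = 1,
                             above5 = 5, above1_HQ = 1),
       hq_only = identical(locus_set_id, "above1_HQ"))
}

#' Select the CNVRs entering a locus set
#'
#' Long-read CNVRs pass a score filter iff their median intrinsic score
#' strictly exceeds the threshold (a score of exactly 1 fails `above1`);
#' the HQ-only filter drops LQ CNVRs of every technology.
#'
#' @param cnvrs CNVR data.frame.
#' @param spec a [locus_set_spec()].
#' @export
select_cnvrs <- function(cnvrs, spec) {
  keep <- rep(TRUE, nrow(cnvrs))
  if (!is.na(spec$lr_score_min)) {
    is_lr <- cnvrs$technology == "lr"
    keep[is_lr] <- !is.na(cnvrs$median_score[is_lr]) &
      cnvrs$median_score[is_lr] > spec$lr_score_min
  }
  if (spec$hq_only) keep <- keep & cnvrs$quality == "HQ"
  cnvrs[keep, , drop = FALSE]
}

#' Build cross-technology CNV loci
#'
#' Loci of one CNV type are the connected components of the graph of
#' at-least-1-bp overlaps over the selected CNVRs of all technologies (HQ
#' and LQ strata both contribute unless the locus set filtered them),
#' each spanning the outermost member breakpoints.
#'
#' @param cnvrs selected CNVRs, all of `cnv_type`.
#' @param cnv_type "DEL" or "DUP".
#' @param locus_set_id id recorded on each locus.
#' @return list(loci = data.frame(locus_id, chrom, start, end, type,
#'   locus_set, tech_set, tech_support, n_cnvrs, member_cnvr_ids),
#'   members = data.frame(locus_id, cnvr_id)).
#' @export
build_loci <- function(cnvrs, cnv_type, locus_set_id = "all") {
  if (any(cnvrs$type != cnv_type)) stop("build_loci: mixed CNV types")
  if (nrow(cnvrs) == 0) {
    loci <- data.frame(locus_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       type = character(0), locus_set = character(0),
                       tech_set = character(0), tech_support = integer(0),
                       n_cnvrs = integer(0),
                       member_cnvr_ids = character(0),
                       stringsAsFactors = FALSE)
    return(list(loci = loci,
                members = data.frame(locus_id = character(0),
                                     cnvr_id = character(0),
                                     stringsAsFactors = FALSE)))
  }
  mc <- merge_connected(cnvrs)
  idx <- mc$member_idx
  lid <- sprintf("%s_%s_%s_%d_%d", locus_set_id, cnv_type,
                 mc$regions$chrom, as.integer(mc$regions$start),
                 as.integer(mc$regions$end))
  tech_sets <- vapply(idx, function(ii)
    paste(sort(unique(cnvrs$technology[ii])), collapse = ","),
    character(1))
  loci <- data.frame(
    locus_id = lid, chrom = mc$regions$chrom, start = mc$regions$start,
    end = mc$regions$end, type = cnv_type, locus_set = locus_set_id,
    tech_set = tech_sets,
    tech_support = lengths(lapply(strsplit(tech_sets, ","), unique)),
    n_cnvrs = lengths(idx),
    member_cnvr_ids = vapply(idx, function(ii)
      paste(cnvrs$cnvr_id[ii], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  members <- data.frame(locus_id = rep(lid, lengths(idx)),
                        cnvr_id = cnvrs$cnvr_id[unlist(idx)],
                        stringsAsFactors = FALSE)
  list(loci = loci, members = members)
}

#' Percentage of a locus spanned by one technology's CNVRs in one quality
#' bin
#'
#' Total member-CNVR length in that technology and bin divided by the
#' locus length, x 100. Same-bin CNVRs of one technology are pairwise
#' disjoint, so the value never exceeds 100. NA when the technology has
#' no member in that bin.
#'
#' @param locus one locus row from [build_loci()].
#' @param member_cnvrs CNVR rows belonging to the locus.
#' @param technology,quality_bin the stratum.
#' @export
percentage_span <- function(locus, member_cnvrs, technology, quality_bin) {
  m <- member_cnvrs[member_cnvrs$technology == technology &
                      member_cnvrs$quality == quality_bin, , drop = FALSE]
  if (nrow(m) == 0) return(NA_real_)
  sum(m$end - m$start) / (locus$end - locus$start) * 100
}

#' Span percentages for every locus x technology x quality bin
#'
#' @param locus_build result of [build_loci()].
#' @param cnvrs the CNVR table the loci were built from.
#' @return long data.frame(locus_id, technology, quality, span_pct).
#' @export
span_table <- function(locus_build, cnvrs) {
  out <- list()
  for (i in seq_len(nrow(locus_build$loci))) {
    locus <- locus_build$loci[i, ]
    ids <- strsplit(locus$member_cnvr_ids, ",")[[1]]
    m <- cnvrs[match(ids, cnvrs$cnvr_id), , drop = FALSE]
    for (tech in unique(m$technology)) {
      for (q in unique(m$quality[m$technology == tech])) {
        out[[length(out) + 1L]] <- data.frame(
          locus_id = locus$locus_id, technology = tech, quality = q,
          span_pct = percentage_span(locus, m, tech, q),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus_id = character(0), technology = character(0),
                      quality = character(0), span_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Technology-sharing label of a locus
#'
#' The sorted subset of technologies with a member CNVR; a singleton
#' subset is "private" to that technology.
#'
#' @param tech_set comma-joined technology set string(s) as emitted by
#'   [build_loci()].
#' @return data.frame(label, private).
#' @export
classify_sharing <- function(tech_set) {
  label <- vapply(strsplit(tech_set, ","),
                  function(x) paste(sort(x), collapse = "+"),
                  character(1))
  data.frame(label = label, private = !grepl("\\+", label),
             stringsAsFactors = FALSE)
}

#' Build all four locus sets over a CNVR table
#'
#' For each locus set, both CNV types are integrated and an opposite-type
#' overlap flag is added (whether a DEL locus overlaps a DUP locus of the
#' same set, and vice versa).
#'
#' @param cnvrs CNVR data.frame.
#' @param sets locus set ids (default all four).
#' @return named list per set: list(loci, members, spans, cnvrs_selected).
#' @export
integrate_loci <- function(cnvrs, sets = LOCUS_SETS) {
  out <- list()
  for (set_id in sets) {
    spec <- locus_set_spec(set_id)
    sel <- select_cnvrs(cnvrs, spec)
    builds <- lapply(CNV_TYPES, function(ty)
      build_loci(sel[sel$type == ty, , drop = FALSE], ty, set_id))
    loci <- do.call(rbind, lapply(builds, `[[`, "loci"))
    members <- do.call(rbind, lapply(builds, `[[`, "members"))
    if (nrow(loci) > 0) {
      other <- function(ty) if (ty == "DEL") "DUP" else "DEL"
      loci$opposite_type_overlap <- vapply(seq_len(nrow(loci)),
        function(i) {
          opp <- loci[loci$type == other(loci$type[i]), , drop = FALSE]
          any(overlap_bp(loci$chrom[i], loci$start[i], loci$end[i],
                         opp) > 0)
        }, logical(1))
      loci <- cbind(loci, classify_sharing(loci$tech_set))
    }
    out[[set_id]] <- list(loci = loci, members = members,
                          spans = span_table(list(loci = loci), sel),
                          cnvrs_selected = sel)
  }
  out
}
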