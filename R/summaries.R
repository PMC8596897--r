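#' Dataset and merged-CNVR summary counts
#'
#' Per input dataset and per merged technology CNVR set: deletion count,
#' duplication count and the del/dup ratio (NA when the duplication count
#' is 0).
#'
#' @param cnvrs CNVR data.frame.
#' @param calls prepared callset data.frame.
#' @return data.frame(scope, name, technology, del_n, dup_n,
#'   del_dup_ratio).
#' @export
table1_summary <- function(cnvrs, calls) {
  ratio <- function(del, dup) if (dup == 0) NA_real_ else del / dup
  rows <- list()
  for (tech in intersect(TECHNOLOGIES, unique(calls$technology))) {
    tc <- cnvrs[cnvrs$technology == tech, , drop = FALSE]
    del <- sum(tc$type == "DEL"); dup <- sum(tc$type == "DUP")
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "merge-CNVR", name = paste0("merge-CNVR-", tech),
      technology = tech, del_n = del, dup_n = dup,
      del_dup_ratio = ratio(del, dup), stringsAsFactors = FALSE)
    for (ds in sort(unique(calls$dataset[calls$technology == tech]))) {
      dc <- calls[calls$dataset == ds, , drop = FALSE]
      del <- sum(dc$type == "DEL"); dup <- sum(dc$type == "DUP")
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "dataset", name = ds, technology = tech, del_n = del,
        dup_n = dup, del_dup_ratio = ratio(del, dup),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-technology vs within-technology support cross-tabulation
#'
#' For each between-technology support level (1, 2, 3) and each
#' technology: the fraction of member CNVRs that are multi- vs
#' single-supported within their technology. Fractions in a cell sum
#' to 1.
#'
#' @param locus_build result of [build_loci()] / one entry of
#'   [integrate_loci()] (needs `loci` and `members`).
#' @param cnvrs the CNVR table.
#' @return data.frame(tech_support, technology, n_multi, n_single,
#'   frac_multi, frac_single).
#' @export
support_crosstab <- function(locus_build, cnvrs) {
  mem <- locus_build$members
  mem$tech_support <- locus_build$loci$tech_support[
    match(mem$locus_id, locus_build$loci$locus_id)]
  idx <- match(mem$cnvr_id, cnvrs$cnvr_id)
  mem$technology <- cnvrs$technology[idx]
  mem$support_class <- cnvrs$support_class[idx]
  rows <- list()
  for (ts in sort(unique(mem$tech_support))) {
    for (tech in sort(unique(mem$technology[mem$tech_support == ts]))) {
      sub <- mem[mem$tech_support == ts & mem$technology == tech, ]
      n_multi <- sum(sub$support_class == "multi")
      n_single <- sum(sub$support_class == "single")
      rows[[length(rows) + 1L]] <- data.frame(
        tech_support = ts, technology = tech, n_multi = n_multi,
        n_single = n_single,
        frac_multi = n_multi / (n_multi + n_single),
        frac_single = n_single / (n_multi + n_single),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length contrast between multi- and single-supported CNVRs
#'
#' Group medians of basepair length plus a two-sided Wilcoxon rank-sum
#' p-value (normal approximation with tie correction, via
#' [stats::wilcox.test()]).
#'
#' @param cnvrs CNVR data.frame.
#' @param technology the technology to contrast.
#' @return list(median_multi, median_single, rank_sum_p, n_multi,
#'   n_single); NULL medians/p when a group is empty.
#' @export
length_by_support <- function(cnvrs, technology) {
  tc <- cnvrs[cnvrs$technology == technology, , drop = FALSE]
  len <- tc$end - tc$start
  multi <- len[tc$support_class == "multi"]
  single <- len[tc$support_class == "single"]
  if (length(multi) == 0 || length(single) == 0) {
    return(list(median_multi = NA_real_, median_single = NA_real_,
                rank_sum_p = NA_real_, n_multi = length(multi),
                n_single = length(single)))
  }
  p <- suppressWarnings(stats::wilcox.test(multi, single)$p.value)
  if (is.nan(p)) p <- 1  # all-tied degenerate case: no rank shift
  list(median_multi = stats::median(multi),
       median_single = stats::median(single),
       rank_sum_p = p, n_multi = length(multi),
       n_single = length(single))
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> prepare -> aggregate -> integrate ->
#' evidence -> summarize and writes every table, a run log and a manifest
#' of output checksums into `out_dir`.
#'
#' `config` is a list (or a YAML file path) with either a `simulate`
#' block (arguments to [sim_config()], seed mandatory) or an `inputs`
#' block of file paths (`callsets` vector, `depth` bedGraph,
#' `exclusions` BED; optional `genome_fasta`, `probes`/`lrr` named
#' lists, `genotypes`, `databases` named list, `segdups` BED,
#' `mappability` wig), plus optional `thresholds` (del_hq_max,
#' dup_hq_min), `min_len_bp`, `flank_bp`, `locus_sets`.
#'
#' @param config list or YAML path.
#' @param out_dir output directory (created).
#' @return invisibly, a list with every in-memory result.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- do.call(dfc_thresholds, config$thresholds %||% list())
  min_len <- config$min_len_bp %||% 500
  flank_bp <- config$flank_bp %||% 1000
  sets <- config$locus_sets %||% LOCUS_SETS

  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(sim_config, config$simulate)
    sim <- stage("simulate", simulate_inputs(sim_cfg))
    calls <- sim$calls; depth <- sim$depth
    exclusions <- sim$annotations$exclusions
    genome_seq <- sim$genome_seq; arrays <- sim$arrays
    databases <- sim$databases; segdups <- sim$annotations$segdups
    mappability <- sim$annotations$mappability
    truth <- sim$truth
    write_tsv_sorted(truth, file.path(out_dir, "truth.tsv"))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in c(unlist(inp$callsets), inp$depth, inp$exclusions)) {
      if (!file.exists(f)) {
        stop("pipeline stage 'load' failed: missing input ", f,
             call. = FALSE)
      }
    }
    calls <- stage("load", do.call(rbind, lapply(inp$callsets,
                                                 read_callset)))
    depth <- stage("load", read_bedgraph(inp$depth))
    exclusions <- stage("load", read_interval_annotation(inp$exclusions))
    genome_seq <- if (!is.null(inp$genome_fasta))
      Biostrings::readDNAStringSet(inp$genome_fasta) else NULL
    if (!is.null(genome_seq)) {
      names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
    }
    arrays <- if (!is.null(inp$probes)) {
      stats::setNames(lapply(names(inp$probes), function(chip)
        list(probes = read_probe_map(inp$probes[[chip]], chip),
             lrr = read_lrr(inp$lrr[[chip]]))), names(inp$probes))
    } else NULL
    databases <- if (!is.null(inp$databases))
      lapply(inp$databases, read_database) else NULL
    segdups <- if (!is.null(inp$segdups))
      merge_intervals(read_interval_annotation(inp$segdups)) else NULL
    mappability <- if (!is.null(inp$mappability))
      read_step_track(inp$mappability) else NULL
    truth <- NULL
  } else {
    stop("pipeline config needs a 'simulate' or 'inputs' block")
  }

  prepared <- stage("prepare",
                    prepare_callsets(calls, depth, exclusions, genome_seq,
                                     thr, min_len, flank_bp))
  write_tsv_sorted(prepared, file.path(out_dir, "prepared_calls.tsv"))

  cnvrs <- stage("aggregate", aggregate_all(prepared, thr))
  write_tsv_sorted(cnvrs, file.path(out_dir, "cnvrs.tsv"))

  loci <- stage("integrate", integrate_loci(cnvrs, sets))
  for (set_id in names(loci)) {
    write_tsv_sorted(loci[[set_id]]$loci,
                     file.path(out_dir, paste0("loci_", set_id, ".tsv")))
    write.table(loci[[set_id]]$spans,
                file.path(out_dir, paste0("spans_", set_id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  genotypes <- if (!is.null(truth)) {
    # the long-read validator is run on the CNVR list itself
    simulate_lr_genotypes(cnvrs, truth,
                          error_rate = sim_cfg$genotype_error,
                          seed = sim_cfg$seed + 8L)
  } else if (!is.null(config$inputs$genotypes)) {
    read_genotypes(config$inputs$genotypes)
  } else NULL
  ev <- stage("evidence",
              evidence_table(cnvrs, arrays = arrays,
                             genotypes = genotypes,
                             databases = databases, segdups = segdups,
                             mappability = mappability,
                             genome_seq = genome_seq))
  write.table(ev, file.path(out_dir, "evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  t1 <- stage("summarize", table1_summary(cnvrs, prepared))
  write.table(t1, file.path(out_dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  crosstab_set <- if ("above1" %in% names(loci)) "above1" else
    names(loci)[1]
  ct <- stage("summarize", support_crosstab(loci[[crosstab_set]], cnvrs))
  write.table(ct, file.path(out_dir, "support_crosstab.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lbs <- do.call(rbind, lapply(intersect(TECHNOLOGIES,
                                         unique(cnvrs$technology)),
    function(tech) {
      r <- length_by_support(cnvrs, tech)
      data.frame(technology = tech, median_multi = r$median_multi,
                 median_single = r$median_single,
                 rank_sum_p = r$rank_sum_p, n_multi = r$n_multi,
                 n_single = r$n_single, stringsAsFactors = FALSE)
    }))
  write.table(lbs, file.path(out_dir, "length_by_support.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    paste0("package: cnvtriad ",
           as.character(utils::packageVersion("cnvtriad"))),
    paste0("R: ", R.version.string),
    paste0("seed: ", if (!is.null(config$simulate))
      config$simulate$seed else "external inputs"),
    paste0("thresholds: del_hq_max=", thr$del_hq_max, " dup_hq_min=",
           thr$dup_hq_min),
    paste0("min_len_bp: ", min_len, "  flank_bp: ", flank_bp),
    paste0("locus_sets: ", paste(sets, collapse = ","))
  ), log_path)

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   c(log_path, file.path(out_dir, "manifest.tsv")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(prepared = prepared, cnvrs = cnvrs, loci = loci,
                 evidence = ev, table1 = t1, crosstab = ct,
                 length_by_support = lbs, manifest = manifest,
                 truth = truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
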