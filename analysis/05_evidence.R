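#!/usr/bin/env Rscript
# Step 5: assay every CNVR against the raw data of all technologies.
#
# Array: Hellinger distance between in-region probe LRR and the 50
# nearest flanking probes per side, plus the median in-region LRR.
# Short reads: the inherited median depth fold changes. Long reads: a
# genotype per CNVR (validator emulation over the truth model), with
# 0/1 and 1/1 counted as concordant. Plus database presence/frequency
# at the 50% overlap rule and genomic context (segdup fraction, flank
# GC, mean mappability).

suppressMessages(library(cnvtriad))

inp <- "results/inputs"
cnvrs <- read.delim("results/cnvrs.tsv")
truth <- read.delim(file.path(inp, "truth.tsv"))
seed <- 2024

arrays <- lapply(
  stats::setNames(nm = sub("^probes_(.*)\\.tsv$", "\\1",
                           list.files(inp, pattern = "^probes_"))),
  function(chip) list(
    probes = read_probe_map(file.path(inp, paste0("probes_", chip,
                                                  ".tsv")), chip),
    lrr = read_lrr(file.path(inp, paste0("lrr_", chip, ".tsv")))))
databases <- lapply(
  stats::setNames(nm = sub("^db_(.*)\\.tsv$", "\\1",
                           list.files(inp, pattern = "^db_"))),
  function(db) read_database(file.path(inp, paste0("db_", db, ".tsv"))))
segdups <- read_interval_annotation(file.path(inp, "segdups.bed"))
mappability <- read_step_track(file.path(inp, "mappability.wig"))
genome_seq <- Biostrings::readDNAStringSet(file.path(inp, "genome.fasta"))
names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))

genotypes <- simulate_lr_genotypes(cnvrs, truth, error_rate = 0.05,
                                   seed = seed + 8)
ev <- evidence_table(cnvrs, arrays = arrays, genotypes = genotypes,
                     databases = databases, segdups = segdups,
                     mappability = mappability, genome_seq = genome_seq)
write.table(ev, "results/evidence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hq <- cnvrs$quality == "HQ"
message("array Hellinger mean, HQ vs LQ CNVRs: ",
        round(mean(ev$array_hellinger[hq], na.rm = TRUE), 3), " vs ",
        round(mean(ev$array_hellinger[!hq], na.rm = TRUE), 3))
conc <- ev$lr_concordance == "concordant"
message("long-read concordant CNVRs: ", sum(conc), "/", nrow(ev),
        "; their mean |DHFFC-1|: ",
        round(mean(abs(ev$dhffc[conc] - 1), na.rm = TRUE), 3),
        " vs discordant ",
        round(mean(abs(ev$dhffc[!conc] - 1), na.rm = TRUE), 3))
message("database presence, multi vs single support: ",
        round(100 * mean(ev$db_dbA_present[cnvrs$support_class ==
                                             "multi"]), 1), "% vs ",
        round(100 * mean(ev$db_dbA_present[cnvrs$support_class ==
                                             "single"]), 1), "%")
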