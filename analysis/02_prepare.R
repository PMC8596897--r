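#!/usr/bin/env Rscript
# Step 2: per-call preparation.
#
# Reads the raw callsets back from disk, drops calls of 500 bp or less
# and calls touching excluded regions (telomere/centromere/blacklist),
# computes duphold-style depth fold changes for every surviving call
# (DHFFC vs 1-kb flanks, DHBFC vs GC-matched genome bins) and labels
# each call HQ/LQ (DEL: DHFFC < 0.7; DUP: DHBFC > 1.3).

suppressMessages(library(cnvtriad))

inp <- "results/inputs"
calls <- do.call(rbind, lapply(
  list.files(inp, pattern = "^callset_", full.names = TRUE),
  read_callset))
depth <- read_bedgraph(file.path(inp, "depth.bedGraph"))
exclusions <- read_interval_annotation(file.path(inp, "exclusions.bed"))
genome_seq <- Biostrings::readDNAStringSet(file.path(inp, "genome.fasta"))
names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))

prepared <- prepare_callsets(calls, depth, exclusions, genome_seq)
write_tsv <- function(df, f) write.table(df, f, sep = "\t",
                                         quote = FALSE, row.names = FALSE)
write_tsv(prepared, "results/prepared_calls.tsv")

message(nrow(calls) - nrow(prepared), " of ", nrow(calls),
        " calls removed by the size/exclusion filters")
message("quality labels: ", sum(prepared$quality == "HQ"), " HQ / ",
        sum(prepared$quality == "LQ"), " LQ")
message("median DHFFC of DEL calls: ",
        round(median(prepared$dhffc[prepared$type == "DEL"],
                     na.rm = TRUE), 3),
        "; median DHBFC of DUP calls: ",
        round(median(prepared$dhbfc[prepared$type == "DUP"],
                     na.rm = TRUE), 3))
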