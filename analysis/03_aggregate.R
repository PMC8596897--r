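#!/usr/bin/env Rscript
# Step 3: collapse calls into CNV regions (CNVRs) per technology.
#
# Sequencing callsets are split into HQ/LQ first and merged within each
# bin (so low-quality segments never bridge regions); arrays are merged
# within each dataset first (collapsing replicate/caller redundancy),
# relabeled from median fold changes, then split and merged across
# datasets. Deletions and duplications never mix.

suppressMessages(library(cnvtriad))

prepared <- read_callset("results/prepared_calls.tsv")

cnvrs <- aggregate_all(prepared)
write.table(cnvrs, "results/cnvrs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(nrow(prepared), " calls -> ", nrow(cnvrs), " CNVRs")
for (tech in unique(cnvrs$technology)) {
  tc <- cnvrs[cnvrs$technology == tech, ]
  message(sprintf("  %-5s %3d regions (%d DEL / %d DUP), %d multi-support",
                  tech, nrow(tc), sum(tc$type == "DEL"),
                  sum(tc$type == "DUP"),
                  sum(tc$support_class == "multi")))
}
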