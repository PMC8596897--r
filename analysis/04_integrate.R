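#!/usr/bin/env Rscript
# Step 4: build cross-technology CNV loci under four quality regimes.
#
# Loci are unions of same-type CNVRs from all technologies at >= 1 bp
# overlap. The four sets differ in which CNVRs enter: all; long-read
# median score > 1 (above1); > 5 (above5); and above1 plus HQ-only for
# every technology (above1_HQ). Per locus we record the technology set,
# between-technology support (1-3) and the percentage span of each
# technology's CNVRs per quality bin.

suppressMessages(library(cnvtriad))

cnvrs <- read.delim("results/cnvrs.tsv")
loci <- integrate_loci(cnvrs)

for (set_id in names(loci)) {
  l <- loci[[set_id]]$loci
  write.table(l, sprintf("results/loci_%s.tsv", set_id), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(loci[[set_id]]$spans,
              sprintf("results/spans_%s.tsv", set_id), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sup <- table(factor(l$tech_support, levels = 1:3))
  message(sprintf(
    "%-9s %3d loci | support 1/2/3: %d/%d/%d | private: %d | median span %.1f%%",
    set_id, nrow(l), sup[1], sup[2], sup[3], sum(l$private),
    median(loci[[set_id]]$spans$span_pct)))
}
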