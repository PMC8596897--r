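#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# One seeded truth model (two 5-Mb chromosomes, 200 CNVs) drives every
# raw input the later steps consume: nine callsets (three datasets per
# technology), a 30x binned depth track, two array chip designs with LRR
# signal, two public-style CNV databases, annotation tracks and the
# genome sequence. Everything is written as plain text under
# results/inputs/.

suppressMessages(library(cnvtriad))

seed <- 2024
cfg <- sim_config(seed = seed)
bundle <- simulate_inputs(cfg, dir = "results/inputs")

message("seed: ", seed)
message("truth variants: ", nrow(bundle$truth), " (",
        sum(bundle$truth$type == "DEL"), " DEL / ",
        sum(bundle$truth$type == "DUP"), " DUP)")
message("raw calls: ", nrow(bundle$calls), " across ",
        length(unique(bundle$calls$dataset)), " datasets; ",
        sum(is.na(bundle$calls$truth_id)), " are planted false calls")
message("depth bins: ", nrow(bundle$depth), "; probes: ",
        paste(vapply(bundle$arrays, function(a) nrow(a$probes), 1L),
              collapse = " + "))
message("inputs written to results/inputs/")
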