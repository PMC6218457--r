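#!/usr/bin/env Rscript
# Stage 2: per-neuron morphometrics.
# Reads every reconstruction under results/demo/swc/ and computes the six
# headline metrics (axonal / dendritic cable length in mm, branch and
# terminal-tip counts); writes results/demo/morphometrics.csv.

library(projectome)

outdir <- "results/demo"
swcs <- sort(list.files(file.path(outdir, "swc"), full.names = TRUE))
neurons <- lapply(swcs, read_swc)
morpho <- summarize_neurons(neurons)
write.csv(morpho, file.path(outdir, "morphometrics.csv"), row.names = FALSE)

cat(sprintf("Measured %d neurons\n", nrow(morpho)))
cat(sprintf("Axonal length: %.1f-%.1f mm (mean %.1f); dendritic mean %.2f mm\n",
            min(morpho$axon_length_mm), max(morpho$axon_length_mm),
            mean(morpho$axon_length_mm), mean(morpho$dend_length_mm)))
cat(sprintf("Branch/tip ratio across axons: %.3f (condensed-tree expectation ~2)\n",
            sum(morpho$axon_branches) / sum(morpho$axon_tips)))
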