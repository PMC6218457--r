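#!/usr/bin/env Rscript
# Stage 6: render the markdown report (group summary table, class counts,
# per-neuron ipsi/contra decomposition, comparison table) from the tables
# written by stages 2-5.

library(projectome)

cfg <- run_config(outdir = "results/demo", seed = 1)
path <- run_report(cfg)
cat(sprintf("Report written to %s (%d lines)\n", path,
            length(readLines(path))))
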