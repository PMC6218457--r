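#!/usr/bin/env Rscript
# Stage 4: neuron classification.
# Assigns soma region/layer, the CPN/APN subclass (contralateral cable >=
# 1 mm), the corpus-callosum routing flag, and a reproducible projection
# category (threshold + Jaccard single linkage over target sets). Writes
# class_records.csv; checks recovered classes against the generator's
# ground truth.

library(projectome)

outdir <- "results/demo"
vol <- read_nrrd(file.path(outdir, "atlas.nrrd"))
ont <- read_ontology_csv(file.path(outdir, "ontology.csv"))
mid <- midline_plane("x", 4000)
swcs <- sort(list.files(file.path(outdir, "swc"), full.names = TRUE))
neurons <- lapply(swcs, read_swc)

records <- do.call(rbind, lapply(neurons, classify_it, vol = vol, ont = ont,
                                 mid = mid, cc_region = "cc"))
pm_df <- read.csv(file.path(outdir, "projection_matrix.csv"),
                  check.names = FALSE)
pm <- as.matrix(pm_df[, -1])
rownames(pm) <- pm_df$name
records$category_id <- unname(categorize_profiles(pm))
write.csv(records, file.path(outdir, "class_records.csv"), row.names = FALSE)

truth_cls <- vapply(sort(list.files(file.path(outdir, "truth"),
                                    full.names = TRUE)),
                    function(f) jsonlite::read_json(f)$class, "")
acc <- mean(records$it_subclass == truth_cls)
cat(sprintf("Classified %d neurons: %d CPN, %d APN; %d cross via cc\n",
            nrow(records), sum(records$it_subclass == "CPN"),
            sum(records$it_subclass == "APN"), sum(records$crossed_via_cc)))
cat(sprintf("Agreement with generator ground truth: %.0f%%\n", 100 * acc))
cat(sprintf("Projection categories found: %d\n",
            length(unique(records$category_id))))
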