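#!/usr/bin/env Rscript
# Stage 5: group statistics.
# Builds the mean ± s.e.m. summary per soma group (MOs L5, MOs L2/3, PL,
# ORBm) and the two-sample Student's t comparisons: CPN vs APN within MOs
# layer 2/3, layer 2/3 vs layer 5 CPNs, and the three frontal areas
# against each other. Writes group_summary.csv and comparisons.csv.

library(projectome)

outdir <- "results/demo"
morpho <- read.csv(file.path(outdir, "morphometrics.csv"))
records <- read.csv(file.path(outdir, "class_records.csv"))
ont <- read_ontology_csv(file.path(outdir, "ontology.csv"))

area_of <- function(id) {
  chain <- c(id, region_ancestors(ont, id))
  acr <- ont$acronym[match(chain, ont$region_id)]
  root_children <- ont$acronym[!is.na(ont$parent_id) &
                                 ont$parent_id ==
                                 ont$region_id[ont$acronym == "brain"]]
  hit <- acr[acr %in% root_children]
  if (length(hit)) hit[1] else acr[1]
}
morpho$group <- paste0(vapply(records$soma_region, area_of, ""), "_",
                       gsub("[^0-9/]", "", records$soma_layer))
metrics <- c("axon_length_mm", "axon_branches", "axon_tips",
             "dend_length_mm", "dend_branches", "dend_tips")
summary <- summarize_groups(morpho, "group", metrics)
write.csv(summary, file.path(outdir, "group_summary.csv"), row.names = FALSE)

cpn <- morpho[records$it_subclass == "CPN" & morpho$group == "MOs_2/3", ]
apn <- morpho[records$it_subclass == "APN" & morpho$group == "MOs_2/3", ]
l5 <- morpho[morpho$group == "MOs_5", ]
cmp <- do.call(rbind, c(
  lapply(c("axon_length_mm", "dend_length_mm", "axon_branches",
           "dend_branches"), function(mt) rbind(
    compare_groups(cpn[[mt]], apn[[mt]], mt,
                   c("MOs_L2/3_CPN", "MOs_L2/3_APN")),
    compare_groups(cpn[[mt]], l5[[mt]], mt,
                   c("MOs_L2/3_CPN", "MOs_L5_CPN"))))))
write.csv(cmp, file.path(outdir, "comparisons.csv"), row.names = FALSE)

ax <- summary[summary$metric == "axon_length_mm", ]
cat("Group axonal length (mean ± sem, mm):\n")
for (i in seq_len(nrow(ax))) {
  cat(sprintf("  %-10s %6.2f ± %5.2f (n=%d)\n", ax$group[i], ax$mean[i],
              ax$sem[i], ax$n[i]))
}
key <- cmp[cmp$metric == "axon_length_mm", ]
cat(sprintf("CPN vs APN (L2/3) axon length: t=%.2f, p=%.3f (%s)\n",
            key$t[1], key$p[1], key$stars[1]))
cat(sprintf("L2/3 vs L5 CPN axon length:    t=%.2f, p=%.2g (%s)\n",
            key$t[2], key$p[2], key$stars[2]))
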