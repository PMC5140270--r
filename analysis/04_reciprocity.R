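#!/usr/bin/env Rscript
# Step 4: pairwise reciprocity of the chemical network among neurons.

suppressPackageStartupMessages(library(cionaconn))

conn <- connectome(read_roster("results/data/roster.csv"),
                   read_contacts("results/data/contacts.csv"),
                   read_thickness_schedule("results/data/thickness_schedule.yaml"))

et <- build_edge_table(conn, "chemical")
pairs <- pair_reciprocity_table(et, conn$cells)
readr::write_csv(pairs, "results/pair_reciprocity.csv")

p <- reciprocity_proportion(et, conn$cells)
summary <- list(
  reciprocity_proportion = p,
  n_connected_pairs = nrow(pairs),
  n_reciprocal_pairs = sum(pairs$reciprocal),
  max_geometric_mean_um = max(pairs$geometric_mean, na.rm = TRUE)
)
jsonlite::write_json(summary, "results/reciprocity.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "reciprocity: %.3f of %d connected neuron pairs have edges both ways\n",
  p, nrow(pairs)))
cat(sprintf("largest geometric-mean pair depth: %.3f um\n",
            summary$max_geometric_mean_um))
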