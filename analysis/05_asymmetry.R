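#!/usr/bin/env Rscript
# Step 5: left/right asymmetry -- sided census, neuromuscular left:right
# ratios per motor pair, relay-class laterality onto the motor ganglion,
# the side-sorted connectivity matrix, and homologous-pair edge diffs.

suppressPackageStartupMessages(library(cionaconn))

conn <- connectome(read_roster("results/data/roster.csv"),
                   read_contacts("results/data/contacts.csv"),
                   read_thickness_schedule("results/data/thickness_schedule.yaml"))
roster <- conn$cells

sc <- sided_counts(roster[roster$region %in% c("BV", "neck", "MG", "CNC"), ])
readr::write_csv(sc$by_group, "results/sided_counts.csv")
cat("CNS census (left/centre/right):",
    paste(unlist(sc$total[, c("left", "centre", "right")]), collapse = "/"),
    "\n")

ratios <- dplyr::bind_rows(lapply(paste0("MN", 1:5), function(p) {
  nmj_lr_ratio(conn, paste0(p, c("L", "R")), p)
}))
readr::write_csv(ratios, "results/nmj_lr_ratios.csv")
print(ratios[, c("label", "left_pct_by_count", "right_pct_by_count",
                 "left_pct_by_sections", "right_pct_by_sections")])

et <- build_edge_table(conn, "chemical")
rl <- relay_laterality(et, roster, c("prRN", "pr-AMG RN", "antRN"))
readr::write_csv(rl, "results/relay_laterality.csv")
print(rl[, c("source_class", "pct_left_by_depth", "pct_left_by_edges")])

# side-sorted whole-matrix view (neurons with assigned sides)
sided <- roster[roster$is_neuron & roster$side != "unassigned", ]
mat_path <- "results/matrix.csv"
write_matrix(et, sided, mat_path)
m <- as.matrix(readr::read_csv(mat_path, show_col_types = FALSE)[, -1])
rownames(m) <- sided$cell_id
sorted <- sort_matrix_by_side(m, sided)
readr::write_csv(tibble::as_tibble(sorted$matrix, rownames = "cell_id"),
                 "results/matrix_side_sorted.csv")
jsonlite::write_json(sorted$quadrants, "results/matrix_quadrants.json",
                     auto_unbox = TRUE, digits = NA)

# homologous motor-ganglion pairs: which edges exist on one side only?
hp <- tibble::tibble(
  left = c(paste0("MN", 1:5, "L"), paste0("MGIN", 1:3, "L")),
  right = c(paste0("MN", 1:5, "R"), paste0("MGIN", 1:3, "R")))
sd_rep <- side_diff(et, hp)
print(sd_rep)
jsonlite::write_json(
  lapply(unclass(sd_rep), as.data.frame),
  "results/mg_side_diff.json", auto_unbox = TRUE, digits = NA)
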