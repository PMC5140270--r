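#!/usr/bin/env Rscript
# Step 2: synapse-level descriptive statistics -- the summary-table
# fields, polyad arity distribution, compartment targeting, per-neuron
# loads and their scaling with partner number.

suppressPackageStartupMessages(library(cionaconn))

conn <- connectome(read_roster("results/data/roster.csv"),
                   read_contacts("results/data/contacts.csv"),
                   read_thickness_schedule("results/data/thickness_schedule.yaml"))

s <- summarize_contacts(conn)
readr::write_csv(s$by_kind, "results/contact_summary.csv")
print(s$by_kind[, c("kind", "total_contacts", "total_sections",
                    "mean_sections_per_contact", "pct_polyadic")])

pd <- polyad_distribution(conn)
readr::write_csv(pd$counts, "results/polyad_arity.csv")
cat(sprintf("polyad fraction %.3f, dyad share %.3f\n",
            pd$polyad_fraction, pd$dyad_share))

cd <- compartment_distribution(conn, "post")
readr::write_csv(cd, "results/postsynaptic_compartments.csv")
at <- sum(cd$fraction[cd$compartment %in% c("axon", "terminal")])
cat(sprintf("%.0f%% of synapses terminate on axons or terminals\n", 100 * at))

per <- per_neuron_stats(conn)
readr::write_csv(per$per_cell, "results/per_neuron_stats.csv")
readr::write_csv(per$population, "results/per_neuron_population.csv")
print(per$population)

fit <- fit_scaling(per$per_cell[per$per_cell$n_presyn > 0 &
                                  per$per_cell$out_partners > 0, ])
cat(sprintf("depth ~ synapse count: slope %.3f, r^2 %.3f\n",
            fit$linear$slope, fit$linear$r_squared))
cat(sprintf("synapses ~ partners: S = %.2f * P^%.2f, r^2 %.3f\n",
            fit$power$a, fit$power$b, fit$power$r_squared))
jsonlite::write_json(fit, "results/scaling_fits.json",
                     auto_unbox = TRUE, digits = NA)
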