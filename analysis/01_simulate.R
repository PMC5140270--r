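#!/usr/bin/env Rscript
# Step 1: generate the synthetic connectome used by the downstream
# analyses, plus the canonical small fixtures, and write them under
# results/ in the package's CSV schemas.

suppressPackageStartupMessages(library(cionaconn))

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
conn <- generate_connectome(cfg)
stopifnot(nrow(validate_connectome(conn)) == 0)

write_contacts(conn, "results/data/contacts.csv")
write_roster(conn$cells, "results/data/roster.csv")
write_thickness_schedule(conn$thickness_schedule,
                         "results/data/thickness_schedule.yaml")
generate_fixture_suite("results/data/fixtures", seed = seed)

cat(sprintf(
  "simulated connectome (seed %d): %d cells, %d chemical contacts, %d gap contacts\n",
  seed, nrow(conn$cells), sum(conn$contacts$kind == "chemical"),
  sum(conn$contacts$kind == "gap")))
cat("wrote results/data/{contacts,roster}.csv and fixtures/\n")
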