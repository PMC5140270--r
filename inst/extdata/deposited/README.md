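# Deposited connectivity matrices (not shipped)

The whole-brain chemical-synapse and gap-junction matrices are
distributed with the original study as supplementary Excel workbooks and
are not redistributed here. To enable the real-data benchmarks in
`tests/testthat/test-acceptance.R`, convert them once to CSV and place
the results in this directory:

- `chemical_matrix.csv` — the chemical-synapse matrix sheet, exported
  as CSV with the first column named `cell_id` holding the presynaptic
  row labels and the remaining column headers holding the matching
  postsynaptic labels (same order), entries in µm of cumulative depth.
- `gap_matrix.csv` — the gap-junction matrix, same layout.
- `roster.csv` — a cell roster in the package schema
  (`cell_id,cell_type,region,side,nucleus_section,nucleus_x,nucleus_y,is_neuron,has_cilium`)
  whose `cell_id` values match the matrix labels.

Conversion conventions to record when exporting (user-editable; adjust
to the workbook at hand): sheet name used, header row number, whether
merged header cells were flattened, and how pooled muscle columns were
labelled (`muscle-L` / `muscle-R`).
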