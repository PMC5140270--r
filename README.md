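# cionaconn

Quantitative analysis of a whole-larva synaptic connectome, modelled on
the central nervous system of the *Ciona intestinalis* larva — the first
chordate nervous system to be reconstructed in full from serial-section
electron microscopy. The package is aimed at connectomics researchers
who have (or want to emulate) an exhaustive synapse-by-synapse
annotation table and need the downstream numbers: weighted connectivity
matrices, synapse statistics, network statistics, reciprocity,
left/right asymmetry measures, and minimal sensory-to-motor pathways.

## The model

Anatomical synaptic strength is proxied by **cumulative depth of
contact**: each annotated contact spans some number of serial sections,
and its depth is the sum of per-section thicknesses (60/70/100 nm zones
along the body axis), in µm. The weight of an ordered cell pair is

    D(i→j) = Σ_contacts(i→j) Σ_sections t(s)/1000   [µm]

Polyadic synapses (dyads, triads) contribute full depth to every
postsynaptic target; gap junctions are undirected canonical pairs;
muscle and basal lamina are exclusively postsynaptic pseudo-cells that
can be excluded with the standard keywords (`bm`, `Ep`, `Mu`, `space`),
alongside a minimum-section reliability filter, before aggregation.
Sidedness comes from the nucleus-versus-midline rule; left:right ratios
use largest-remainder rounding; network statistics use unweighted hop
counts with documented conventions for clustering, path length,
heterogeneity and centralization. A seeded synthetic-connectome
generator reproduces the study's marginal statistics (negative-binomial
synapse loads with mean 49 and SD 61, geometric section spans, 10.7%
polyads with 93% dyads, reciprocity 0.39, per-pair neuromuscular
left:right skews) so that every analysis is testable without the
deposited annotation files. See the methods vignette
(`vignettes/connectome-analysis.Rmd`) for the full account.

## Worked example

```r
library(cionaconn)

# a synthetic connectome at the study's marginal statistics
conn <- generate_connectome(generator_config(seed = 1L))
conn
#> <connectome> 216 cells (206 neurons), 11239 chemical contacts, 1013 gap contacts

# summary-table arithmetic on the deterministic published-marginal fixture
summarize_contacts(make_table1_connectome())$by_kind
#>       kind total_contacts total_sections mean_sections_per_contact pct_polyadic
#> 1 chemical           8617          30163                  3.500406         10.7
#> 2      gap           3205           5765                  1.798752          0.0

et <- build_edge_table(conn, "chemical")
reciprocity_proportion(et, conn$cells)
#> [1] 0.3913150

nmj_lr_ratio(conn, c("MN1L", "MN1R"), "MN1")[, c("left_pct_by_count",
                                                 "right_pct_by_count")]
#>   left_pct_by_count right_pct_by_count
#> 1                41                 59

network_stats(et, "directed", conn$cells, "cns_only")[
  , c("n_nodes", "clustering_coefficient", "characteristic_path_length")]
#>   n_nodes clustering_coefficient characteristic_path_length
#> 1     178              0.4156918                   1.867295
```

The first table reproduces the published totals exactly (mean 3.5
sections per synapse, 1.8 per gap junction, 10.7% polyadic); the
generator-level numbers recover their configured targets (reciprocity
0.39, MN1 skew 40:60) up to sampling noise. Synthetic wiring is
deliberately unlayered, so its clustering and path length describe the
generator, not the real larva; the real-data network benchmarks run
whenever a converted copy of the deposited connectivity matrix is placed
under `inst/extdata/deposited/`.

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline over a
simulated dataset and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # connectome + fixture suite
Rscript analysis/02_contact_summary.R # synapse statistics, scaling fits
Rscript analysis/03_network_stats.R   # network statistic tables, GraphML
Rscript analysis/04_reciprocity.R     # pairwise reciprocity
Rscript analysis/05_asymmetry.R       # census, NMJ ratios, side diffs
Rscript analysis/06_pathways.R        # shortest arcs, motifs
```

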