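---
title: "Quantitative analysis of a whole-larva connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of a whole-larva connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cionaconn)
```

## The data model

The package analyses a connectome of the kind produced by exhaustive
annotation of a serial-section transmission-EM series through an entire
ascidian (*Ciona intestinalis*) larva: a cell roster (identity, type code,
CNS region, left/right side, nucleus position) and a contact table in
which every chemical synapse, neuromuscular junction and putative gap
junction is one record carrying its presynaptic cell, one or more ordered
postsynaptic targets, and the span of serial sections over which the
contact was observed.

Because no physiological measure of synaptic strength is available in
fixed tissue, the analyses use **cumulative depth of contact** as the
strength proxy: the number of sections a contact spans multiplied by the
section thickness, in micrometres. The series was cut in three thickness
runs along the anterior–posterior axis (3375 sections at 60 nm, 1360 at
70 nm, 2193 at 100 nm), so depth is computed per section against a
thickness schedule rather than with a single scalar: a contact straddling
the 60/70 nm boundary sums its true per-section values. Section indices
are 0-based and spans are closed intervals. For an ordered cell pair
$(i \to j)$ the edge weight is

$$D(i \to j) \;=\; \sum_{c \,\in\, \text{contacts}(i \to j)} \;
  \sum_{s \in \text{span}(c)} t(s) / 1000 \quad [\mu m],$$

with $t(s)$ the thickness in nm of section $s$. Polyadic synapses (dyads,
triads) contribute their full span and depth to *every* postsynaptic
target, matching how all connections of a dyad are plotted in the
published connectivity matrix. Unpolarized synapses (vesicles on both
sides of the cleft) are stored once in their annotated direction with a
flag; `expand_unpolarized = TRUE` adds the reversed half-contact for
sensitivity analyses. Muscle cells and the basal lamina are represented
as exclusively postsynaptic pseudo-cells so that "synapses onto the basal
lamina" are representable — and excludable with the standard exclusion
keywords (`bm`, `Ep`, `Mu`, `space`), which are applied, together with
the minimum-section reliability filter, *before* aggregation into edges.

Sidedness follows the nucleus rule: a midline drawn through the neural
canal classifies nuclei strictly left or right; nuclei intersected by the
line are midline cells; cells without a recorded nucleus stay
`unassigned` with a warning (`assign_side()` is exhaustive and mutually
exclusive over those four outcomes).

## Statistic conventions

`summarize_contacts()` reproduces the summary-table quantities (totals,
sections, mean span, polyad / unpolarized / dense-core-vesicle
percentages). Percentages are rounded half-up to one decimal for
reporting because the published table prints one decimal; raw values are
kept alongside. Per-neuron means use the population SD (divisor $n$) —
a descriptive-statistics reading of a single complete specimen — with the
sample SD available behind a flag. The default per-neuron denominator is
CNS neurons with at least one presynaptic site; the bipolar tail neurons
can be added because the published per-neuron averages are ambiguous
about them.

`network_stats()` mirrors the conventions of the graph-analysis tool used
for the published network table, stated here explicitly since that tool
does not document them per statistic: shortest paths are unweighted hop
counts (the published path lengths of ~2.7 are consistent with hops, not
depth-weighted distances); the characteristic path length averages over
ordered reachable pairs of distinct nodes, with the reachable-pair count
and percentage reported separately; components are weak components;
diameter and radius are the extreme node eccentricities over reachable
pairs; clustering, average neighbours, heterogeneity
($\mathrm{SD}(k)/\bar k$) and centralization
($\tfrac{n}{n-2}(k_{\max}/(n-1) - \text{density})$) are computed on the
undirected simple graph with self-loops removed, nodes with fewer than
two neighbours contributing zero clustering. A directed clustering
variant is available behind a flag. Multi-edge pair counts come from the
raw contact list, since a depth-aggregated edge table no longer knows
contact multiplicities.

One property worth noting: adding an edge never *lengthens any pair's*
shortest path, but it can *raise the mean* path length by making distant
pairs newly reachable — the invariant the tests assert is therefore the
pairwise one.

Reciprocity is measured over unordered neuron pairs joined by at least
one directed edge: the proportion with edges both ways, and per pair the
extent $D_{\text{fwd}}/(D_{\text{fwd}}+D_{\text{bwd}})$ (reported from
the larger direction, so one-way pairs have extent 1) and the geometric
mean $\sqrt{D_{\text{fwd}} D_{\text{bwd}}}$ for reciprocal pairs. Pairs
involving muscle or basal lamina are excluded by default — they are
exclusively postsynaptic and can never be reciprocal — with inclusion
behind a flag.

Left:right ratio tables use largest-remainder rounding so each printed
pair sums to exactly 100, and neuromuscular ratios pool the dorsal and
medial muscle bands per side (the bands are coupled by gap junctions).
Homologous-pair edge differences (`side_diff()`) take the left–right
pairing as explicit configuration, because homologues are identified by
name, not inferred; an edge belongs to the side of its presynaptic cell
and decussating edges are tracked separately from ipsilateral ones.
Minimal sensory-to-motor arcs are measured in synapse (edge) count — a
pathway through one interneuron is *disynaptic* — all ties are
enumerated rather than broken, and gap junctions are excluded from the
search by default since the published arcs are synaptic; the
edge-depth threshold for the search defaults to 0 (no filtering) because
no minimum synapse size is stated for the published arc figures.

## The synthetic connectome generator

No annotation tables ship with the package, so a seeded generator
(`generate_connectome()`) emulates the *marginal statistics* the analyses
assume, at the study's own values:

| parameter | default | basis |
|---|---|---|
| per-neuron presynaptic sites | NB, mean 49, SD 61 | reported mean/SD; SD > mean rules out Poisson |
| CNS synapse span | geometric, mean 3.5, max 29 | reported mean span and maximum |
| NMJ span | geometric, mean 5, max 65 | NMJ span bound; larger junctions |
| gap-junction span | geometric, mean 1.8, max 55 | reported mean and maximum |
| polyad probability | 0.107 | polyad share of synapses |
| dyad share of polyads | 0.93 | reported dyad share |
| unpolarized probability | 0.052 | reported percentage |
| dense-core-vesicle probability | 0.08 | reported percentage |
| axon/terminal targeting | 0.68 | reported compartment share |
| reciprocity target | 0.39 | reported proportion |
| per-neuron gap junctions | NB, mean 13, SD 23 | reported mean/SD |
| NMJ left shares per pair | 40/46/60/60/58 % | printed by-count ratios |
| coupling $S = aP^b$ | $a = 4.5$, $b = 0.8$ | $a$ set so a 49-synapse neuron has ~20 partners (the observed average neighbourhood); $b$ a configurable default |

The roster defaults to a synthetic sided census with the published
region-by-side margins (brain vesicle 72/14/57, neck 1/0/1, motor
ganglion 12/1/12, caudal nerve cord 3/0/5; CNS total 88/15/75; PNS
8/6/14). Within-region per-type counts are the package's own choice
consistent with those margins — the extracted census rows are
typographically unreliable below the margin level — and no claim is made
about real cell identities beyond type, region and side.

Generation proceeds in a fixed order under one Mersenne–Twister seed:
nucleus placement; per-neuron synapse counts $S_i$ (truncated at ≥1 to
match the reported range starting at one synapse); partner counts
$P_i = \max(1, \mathrm{round}((S_i/a)^{1/b} e^{\varepsilon}))$ with
log-normal noise, clamped to $P_i \le S_i$; allocation of the $S_i$
contacts so every selected partner receives at least one; per-contact
spans, polyad arity, compartments and vesicle flags; a small fraction of
monadic synapses redirected to the basal lamina, ependymal cells or an
unresolved target so the exclusion machinery is exercised; neuromuscular
junctions per motor pair as Bernoulli left/right draws at the configured
skew; gap junctions (each neuron initiates half its expected junction
count, since each junction touches two cells); and finally reciprocity
adjustment. Reciprocity is induced transparently by post-hoc mirroring:
with natural reciprocity $r_0$ among connected pairs, each one-way pair
receives a reverse contact with probability $q = (\rho - r_0)/(1 - r_0)$,
making the expected proportion exactly the target $\rho$. Polyad extras
are drawn from the presynaptic cell's existing partner pool so polyads do
not perturb the pair structure. This is a deliberate modelling
simplification — mirroring is not a degree-corrected null model.

Two generator properties deserve honesty. First, mirrored contacts
inflate per-neuron synapse counts a few percent above the configured
mean; kind-level span statistics are unaffected. Second, because partner
counts are integers floored at one while the negative binomial places
roughly a third of neurons below the knee $S = a$ of the concave coupling
curve, the exponent *observable* in whole-connectome synthetic data by a
log–log refit exceeds the configured $b$. Exponent-recovery validation
therefore simulates per-neuron $(P, S)$ tables directly from
$S = aP^b e^{\varepsilon}$ (150 neurons), where the refit is unbiased;
the whole-connectome coupling is a qualitative, not calibrated, feature.

What the generator does **not** emulate: the real wiring diagram's
layered sensory→interneuron→motor topology (partner choice is uniform,
so synthetic shortest arcs are shorter than the real disynaptic minimum),
spatial axon trajectories, class-specific laterality of relay
projections, and any correlation between contact size and partner
identity (independence is assumed and recorded in the fixture manifest).
Passing tests on synthetic data therefore validate the *computations*,
not claims about real anatomy; the deposited-matrix benchmarks, which run
whenever a converted copy of the published matrix is placed under
`inst/extdata/deposited/`, are the end-to-end anchor.

A deterministic companion, `make_table1_connectome()`, constructs without
randomness a connectome whose kind-level totals equal the published
summary table exactly (8617 synapses over 30163 sections, 922 polyadic
with a 93% dyad share, 448 unpolarized, 689 with dense-core vesicles;
3205 gap junctions over 5765 sections), which pins the summary arithmetic
(30163/8617 = 3.5, 5765/3205 = 1.8, 922/8617 = 10.7%) and the
over-one-section filter count (6618) to exact assertions.

## Numerical and testing choices

Degenerate inputs: empty contact lists summarize to zeros with a warning;
empty graphs are an error; clustering is absent below three nodes;
classes with no outgoing edges are dropped from laterality tables with a
warning; unreachable pathway queries return an explicit non-result rather
than throwing. Matrix writers emit six significant digits in fixed column
order so identical inputs give byte-identical files; round-trips are
tested to 1e-9 µm. Ties in shortest-arc search are enumerated via
exhaustive shortest-path expansion, never broken by ordering.

Graph statistics are validated against brute-force oracles (hand-written
all-pairs BFS and definition-level formulas) on 200 random graphs of up
to 20 nodes, and arc enumeration against exhaustive depth-limited search
on 100 random layered graphs — sizes at which exhaustive computation is
exact and fast. Stochastic generator checks run at the default roster
(~180 CNS neurons, ~11000 contacts) across several fixed seeds, asserting
exact binomial 95% confidence bands around the configured polyad and
reciprocity values and a ±3-point band on the neuromuscular skew of the
largest motor pair; the smallest pairs (a handful of junctions) are
intrinsically noisier than any such band, which is a property of the
study conditions, not of the estimator.

## Limitations

Single-specimen data admit no significance testing of asymmetries, and
none is provided. The package does not reconcile the internally
inconsistent published totals (e.g. 8768 synapses in the text vs 8617 in
the summary table; 2105 vs 3205 gap junctions): it stores whatever the
input contains and makes both exclusion readings computable. Volumes and
surface areas are consumed as optional per-cell attributes, never
computed. Excitatory/inhibitory sign is out of scope, as is any dynamical
model of the swimming circuit.
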