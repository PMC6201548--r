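---
title: "Reference-assisted chromosome assembly and breakpoint-region analysis with karyoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-assisted chromosome assembly and breakpoint-region analysis with karyoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoforge)
library(dplyr)
```

## The problem

Most bird genomes sequenced with short reads exist only as thousands of
scaffolds. Turning them into chromosome-level assemblies classically takes
three kinds of evidence: a related chromosome-level reference (comparative
evidence), read pairs whose inserts span scaffold joins (sequence
evidence), and molecular cytogenetics — BAC probes hybridised to
chromosomes (FISH) — to place and orient the resulting fragments.
`karyoforge` implements a tested, simulation-backed version of this
workflow:

1. merge pairwise alignment blocks into **syntenic fragments** (SFs);
2. flag scaffold joins whose flanking SFs conflict on the reference, and
   split putative **chimeric scaffolds** wherever spanning-pair physical
   coverage falls below a threshold calibrated against PCR verdicts;
3. chain scaffold fragments into **predicted chromosome fragments**
   (PCFs) using read-pair adjacency evidence;
4. **anchor** PCFs to chromosomes with BAC/FISH observations and export
   AGP;
5. build **homology maps** (per target chromosome, the ordered signed
   list of reference homolog segments), count fusions and fissions,
   classify **evolutionary breakpoint regions** (EBRs), and
6. quantify **conserved non-coding element** (CNE) density in EBR
   classes, msHSBs (multi-species homologous synteny blocks) and the
   genome-wide background.

Because real inputs of this kind are large and partly wet-lab derived,
the package ships a first-class synthetic-data module that emulates every
input, with a planted ground truth against which each stage is tested.

## Event-counting conventions

Interchromosomal events are counted under explicit conventions chosen so
that the chromosome-count identity holds on complete maps:

* **fusions, junction-based** — a target chromosome concatenating $k$
  distinct reference units contributes $k-1$ fusions;
* **fissions, piece-based** — a reference unit appearing on $m$ target
  chromosomes contributes $m-1$ fissions;
* identity: `#targets = #units + fissions − fusions`.

The *reference unit set* is an explicit parameter, because avian
comparisons are stated under two conventions. Chicken chromosome 4 arose
from an ancestral fusion: its p-arm is an ancestral microchromosome.
`unit_set("chicken")` counts 4p + 4q as one unit; `unit_set("ancestral")`
keeps 4p as its own microchromosome unit. Intact-unit counts are reported
at both unit granularity and homolog granularity (arm labels collapsed),
since published "homologs showing no rearrangement" counts are stated at
the homolog level. The packaged `load_fixture()` maps for ostrich,
budgerigar and saker falcon declare their unit set; the budgerigar map
carries a `note` column on the rows whose within-chromosome partner
assignment (which GGA5/GGA7 arm pairs with which partner) is uncertain —
no count used anywhere depends on that ambiguity.

## The synthetic-data generator

`sim_config()` centralises every knob. Defaults define a scaled-down
avian-like genome — the demo scale is roughly 1/40 of a real bird genome
so a full pipeline run takes seconds on one CPU:

| parameter | default | meaning |
|---|---|---|
| `n_macro`, `n_micro` | 4, 6 | macro- and microchromosome counts |
| `macro_len_range` | 4–8 Mb | macrochromosome lengths |
| `micro_len_range` | 0.6–2 Mb | microchromosome lengths |
| `cne_target_density` | 0.087 | genome-wide CNE base fraction |
| `cne_len_mean` | 300 bp | mean CNE element length (gamma, shape 2) |
| `mshsb_len_range` | 1.5–2.5 Mb | msHSB block lengths (all > 1.5 Mb) |
| `mshsb_enrichment` | 0.107/0.087 | CNE density ratio inside msHSBs |
| `breakpoint_gamma` | 8 | CNE-avoidance exponent for breakpoints |
| `telomere_depletion_len/factor` | 50 kb, 0.45 | subtelomeric CNE thinning |
| `lambda_true`, `lambda_chim` | 400, 5 | spanning-pair coverage regimes |
| `chimera_rate` | 0.08 | fraction of pieces joined chimerically |

CNE placement is exact by construction: element lengths are drawn, then
separated by Dirichlet-distributed gaps, so each region's realised
density matches its target up to integer rounding (the genome-wide
density lands within ±0.005 of the target). msHSBs are placed on
macrochromosomes away from subtelomeres and receive the enrichment
ratio; the background density is solved so that the genome-wide target
is met.

### Breakpoint bias and the class gradient

Breakpoint positions are drawn from 1-kb candidate windows with
probability proportional to $(1-f)^{\gamma w}$, where $f$ is the
window's CNE fraction, $\gamma$ is `breakpoint_gamma` and $w$ a
per-class weight (`gamma_class_weights`). The design makes the three
breakpoint classes differ in how strongly they avoid conserved
sequence, emulating the empirically observed density gradient
*fission < fusion < intrachromosomal < genome-wide < msHSB*:

* **fissions** use the full exponent ($w=1$): cuts land in the most
  CNE-poor windows;
* **fusions** join *original telomeric ends* of two chromosomes (the
  dominant avian mechanism — intact microchromosomes fusing end-to-end),
  so fusion breakpoints inherit the subtelomeric CNE depletion
  (`telomere_depletion_factor`), intermediate between fissions and
  inversions; subtelomeric elements are proportionally shorter, which
  keeps the per-window density there comparatively even;
* **inversions** use a weak exponent ($w=0.12$): their breakpoints are
  only mildly CNE-avoidant.

Fissions are applied first, then fusions (only ends that are still
ancestral-chromosome termini are joinable, so a fission-cut end is never
re-used as a fusion junction), then inversions (an inverted interval
never spans a pre-existing breakpoint). These constraints keep every
planted event's signature attributable, which is what makes the
planted-truth ↔ detected-EBR bijection testable; they also match the
biology the package emulates, where fission-then-refusion at the same
locus within one lineage is not part of the observed repertoire.

Every rearrangement operates on a piecewise coordinate map (ordered
signed ancestor segments per derived chromosome), so total sequence
length and total CNE bases are conserved exactly, and tracks, BAC
markers and alignment blocks are projected through the same map.

### Observables

`fragment_and_observe()` cuts the derived karyotype into scaffolds at
random positions and, at `chimera_rate`, concatenates two pieces from
non-adjacent loci (different chromosomes or ≥ 1 Mb apart, so comparative
conflict is detectable in principle) into a chimeric scaffold. It emits:

* alignment blocks tiling each scaffold exactly (the TSV dialect
  `ref_chrom ref_start ref_end tgt_scaffold tgt_start tgt_end strand`,
  0-based half-open);
* **physical coverage** at every intra-scaffold junction — the number of
  read pairs spanning the junction point, Poisson(`lambda_true`) at true
  joins and Poisson(`lambda_chim`) at chimeric joins (400:5 by default,
  matching the order of magnitude of reported spanning-pair ranges);
* an **adjacency-support table**: spanning pairs across consecutive
  scaffold ends in the derived karyotype. This is the read-pair evidence
  a reference-assisted assembler uses to chain scaffolds; without it, a
  fission (reference-contiguous sequence on two derived chromosomes)
  would be invisible to a purely comparative assembler.

`pcr_oracle()` issues in-silico PCR verdicts: split regions of 6 kbp or
more cannot be amplified reliably and are `untestable` (the boundary is
closed: exactly 6,000 bp is untestable); below that, true joins are
`confirmed` and chimeric joins `refuted`, with an optional error rate.
`emit_bac_panel()` places markers every ~`bac_spacing` on the ancestor
and reports their order per derived chromosome — what a FISH experiment
observes.

## Assembly

`build_syntenic_fragments()` merges consecutive blocks on the same
(scaffold, reference chromosome, strand) when both-genome gaps stay
under `resolution` and the geometry is colinear; merged fragments
shorter than `resolution` are discarded. The interface default
(150 kb) matches full-size genomes; pipeline defaults scale it to 10 kb
for the demo-scale simulations.

`find_conflicting_joins()` flags a join when its flanking SFs disagree
on reference chromosome, strand geometry, or adjacency (reference gap
beyond resolution). `calibrate_threshold()` scans candidate thresholds
$T \in \{0\} \cup \{c+1\}$ over observed coverages and maximises
agreement with PCR — `#(confirmed with coverage ≥ T) + #(refuted with
coverage < T)` — returning the smallest maximiser (the most conservative
split rule among the best). Untestable joins contribute nothing.

`assemble_pcfs()` splits conflicting joins below the threshold
(PCR-confirmed structures are never split), then chains scaffold
fragments into PCFs. Chain edges come from the adjacency-support table:
an edge joins two fragments whose facing scaffold ends are supported by
at least the threshold number of spanning pairs; a supported adjacency
to a scaffold too short to align is bridged, so chains continue across
short unplaceable scaffolds. Without an adjacency table the chainer
falls back to reference-midpoint order within each chromosome. Member
orientation follows directly from which scaffold end each edge enters.
Two consequences mirror the real workflow:

* an intact scaffold spanning a species-specific fusion links two
  reference-chromosome chains into one PCF;
* a chimeric scaffold whose junction coverage happens to exceed the
  threshold survives splitting and glues unrelated chains — the FISH
  stage then reports it as a *disagreement* and leaves it unplaced,
  the in-silico counterpart of a disagreement between
  sequence-based chaining and cytogenetic evidence.

`anchor()` places each PCF on the chromosome where its BACs are
observed; orientation requires at least two distinct-offset BACs with
fully concordant (Kendall $\tau = \pm 1$) offset/order relation; mixed
order or multi-chromosome hits are recorded as disagreements and left
unplaced (the resolution policy is report-only, since published totals
report disagreements as counts). `export_agp()` writes AGP v2.1 with
100-bp `contig`/`map` gap rows — the only place coordinates become
1-based inclusive — and `parse_agp()` is its inverse.

## Breakpoint regions and CNE statistics

`detect_ebrs()` walks each unit's segments in reference order: a
discontinuity between ref-consecutive segments on different target
chromosomes is a **fission** EBR spanning the reference gap;
target-adjacent but order- or strand-broken neighbours give an
**intrachromosomal** EBR; each distinct-unit junction contributes a
**fusion** EBR at the broken reference end of both flanking segments.
Intervals are clipped to ≥ 1 bp; EBRs longer than 100 kb are detected
but flagged excluded from CNE analysis.

`make_flank_set()` extends sub-kb EBRs by ±1 kb and lays two abutting
windows of the (extended) EBR's length on each side; windows clipped at
chromosome ends are flagged truncated and such EBRs are dropped from the
contrast. `ebr_flank_contrast()` runs Kruskal–Wallis across the five
window roles and a Mann–Whitney U of EBR densities against pooled
flanks (one-sided "less" by default — the depletion hypothesis). No
multiple-testing correction is applied, and reports say so.

`scan_1kb_windows()` tiles each chromosome from position 0 (final
partial windows are dropped — the tiling restarts per chromosome),
drops windows with ≤ 50% sequenced bases (defined via the `gap` track;
with no gap track all bases count as available, which a synthetic genome
controls explicitly), and classifies windows with precedence
fission > fusion > intrachromosomal > msHSB > rest; any overlap with an
EBR makes the window an EBR window. `distance_to_mshsb_density()`
reports, for each zero-CNE usable window, the distance in windows to the
nearest window at or above the msHSB average density (NA if no such
window exists on the chromosome).

### Rank tests

`mann_whitney_u()` enumerates all $\binom{N}{n_x}$ assignments exactly
for pooled sizes up to 12 (mid-ranks make ties exact too) and otherwise
uses the normal approximation with tie and continuity corrections —
numerically identical to `wilcox.test`'s approximation, which serves as
an independent cross-check in the tests. The exact-vs-normal gap at
$n_x=n_y=6$ can reach ~0.016, which is why the exact path extends to
pooled size 12. `kruskal_wallis()` delegates to `stats::kruskal.test`
(tie-corrected H, $\chi^2_{k-1}$ p) with an explicit degenerate path:
all observations equal gives H = 0, p = 1.

### Inversion counts

`estimate_inversions()` returns the exact signed
sorting-by-reversals distance by breadth-first search — a cached
full-space distance table per size up to 7 elements (distance is
symmetric because reversals are involutions; the 7-element table has
645,120 states), per-input BFS with a state cap up to 10 — and the
signed breakpoint lower bound $\lceil b/2 \rceil$, labelled
`lower_bound`, beyond that. Published inversion totals for real
genomes rest on marker-order data without a standardised counting
procedure, so equality with them is deliberately not asserted anywhere; `inversions_from_map()`
reports per-unit distances (minimised over reading direction) labelled
exact or estimate.

## What the simulations do and do not show

The generator reproduces the *structure* of the real workflow's data: a
CNE/msHSB landscape with the published density contrast, biased
breakpoints, two-regime junction coverage, a PCR testability rule and
FISH marker order. Passing tests therefore show that the pipeline's
logic — calibration, splitting, chaining, anchoring, counting,
density contrasts — recovers planted truth under those conditions. They
do not show robustness to everything real data adds: alignment noise
and repeat-driven mis-mappings, unequal scaffold quality, assembly gaps
inside the reference, CNE-annotation error, or partial BAC panels.
Sequence-level effects (read errors, repeats) are out of the model
entirely; coverage is physical spanning-pair count, not read depth.

Problem sizes were chosen for desk-scale reproducibility: module tests
use ~8-chromosome, ~16 Mb genomes; the class-ordering experiment uses
90 chromosomes (~70 Mb) with 80 events of each type over 20 seeded
replicates; the type-I-error experiment redraws 60 unbiased breakpoints
200 times on one fixed genome. Absolute full-genome statistics
(real-genome N50s, % of assembly placed) are not reproducible at this
scale and are
exercised as recoverable *properties* (orderings, recoveries,
calibration separation) instead.

## A short walk-through

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 7), seed = 7)
res <- run_pipeline(cfg, "demo_run")

glance(res$calibration)     # selected spanning-pair threshold
res$anchoring_stats         # % placed / oriented
glance(res$event_counts)    # fusions, fissions, intact units
res$scan$report             # CNE density by window class
report_tables("demo_run")   # split-region / assembly / density tables
```

The packaged species maps reproduce the published event counts:

```{r fixtures}
sak <- count_interchromosomal_events(load_fixture("saker"))
glance(sak)
microchromosome_summary(load_fixture("budgerigar"))[c("n_fused", "n_intact")]
```

## Known limitations

* The assembler is a deliberate simplification of a full
  reference-assisted assembly algorithm: no adjacency likelihood
  scoring, no outgroup three-way reconciliation, no gap-size estimation
  between PCF members.
* PCF chaining trusts the adjacency-support table; with dense spurious
  adjacencies it would over-chain (real pipelines score adjacencies
  probabilistically).
* `estimate_inversions()` is exponential-state beyond 10 segments by
  design; per-unit inputs larger than that return a labelled lower
  bound.
* Coordinates are coordinate-only throughout; no sequence is simulated
  or emitted.
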