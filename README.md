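# metabarprime

Design and in silico evaluation of metabarcoding primers against
taxonomy-annotated reference databases.

Metabarcoding surveys (insect inventories above all) amplify one short
mitochondrial marker from a mixed sample and assign the resulting reads to
species. Whether that works hinges on the primer pair: a marker is only as
good as the fraction of the target fauna its primers amplify (*taxonomic
coverage*, B\_C) times the fraction of amplified species whose amplicons
form a single, clean sequence cluster (*exclusive taxonomic resolution*,
B\_E). `metabarprime` computes this whole chain in silico:

* **reference databases** — load/write taxonomy-annotated FASTA
  (`>seq_id|species|genus|family|order|circular={0,1}`) or tab-separated
  ecoPCR-style dumps; subset by insect order; validate lineages.
* **in silico PCR** — IUPAC-degenerate primer matching with per-primer
  mismatch budgets, a mismatch-free 3' anchor, two inosine pairing modes,
  ±10% amplicon-length windows, and circular (mitogenome) templates
  scanned across the origin.
* **clustering** — deterministic UCLUST-style greedy centroid clustering
  of the predicted inserts across a 95–100% similarity sweep, backed by a
  C++ global-alignment identity with fixed, documented scoring.
* **indices** — B\_C, B\_S, B\_E, the cluster-relative B\_E′ whose peak
  locates the **barcoding gap**, and the effective taxonomic resolution
  ETR = B\_C·B\_E; plus two-marker combinations (ETR\_T = ETR\_U(i) +
  ETR\_U(j) + ETR\_R) and residual primer design over the species a first
  marker misses.
* **primer design** — gap-column trimming, windowed Shannon-entropy
  profiling, degeneracy-capped degenerate-consensus construction (caps 12
  and 216), and pairing by insert length (100–500 bp by default).
* **synthetic data** — a seeded mitogenome-like simulator with a rank
  tree, planted primer sites, controlled intra-/interspecific divergence
  and within-genus label noise, so every pipeline stage is testable
  against known ground truth.

## Worked example

Simulate a 300-species reference set with a planted 130 bp marker, then
evaluate that marker end to end:

```r
library(metabarprime)

sim <- simulate_reference_db(sim_config(seed = 7))
sim$db
#> <reference_db> 416 records | 300 species | 60 genera | 15 families | 5 orders

ev <- evaluate_marker(sim$db, sim$truth$primer_pair)
round(ev$coverage, 3)
#> [1] 0.987
ev$gap
#> [1] 0.97
ev$gap_report
#> <index_report> threshold 0.97
#>   B_C 0.99 | B_S 0.87 | B_E 0.86 | B_E' 0.91 | ETR 0.85
#>   |S| 300  |S_A| 296  |S_U| 255  |C_U| 255  |C_M| 17  |C_N| 9
```

Reading the report: the planted pair amplifies 296 of 300 species
(B\_C = 0.99 — the simulator degrades 1% of planted site copies). At the
97% similarity threshold — the B\_E′ argmax, i.e. the marker's barcoding
gap — 255 species sit in exactly one pure cluster each (B\_E = 255/296 =
0.86), 17 clusters mix congeneric species whose divergence falls below
the threshold, and 9 pure clusters share a label (split species). The
bottom line is ETR = 255/300 = 0.85: the fraction of the whole fauna this
marker both detects and cleanly resolves. Published primer pairs for
eight mitochondrial markers are shipped in
`inst/extdata/insect_mito_primers.tsv` and load with
`read_primer_list()`; a thin CLI over the same functions lives at
`inst/scripts/metabarprime.R` (`db-stats`, `simulate`, `amplify`,
`evaluate`, `design`).

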