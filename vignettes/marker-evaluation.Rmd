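---
title: "In silico design and evaluation of metabarcoding markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico design and evaluation of metabarcoding markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabarprime)
```

## The problem

Metabarcoding profiles a mixed sample (a Malaise-trap catch, soil, water)
by PCR-amplifying one short marker region from every organism present and
sequencing the pool. A good marker needs two things at once: conserved
flanks, so that a single degenerate primer pair amplifies as many of the
target taxa as possible, and a variable insert, so that the resulting
amplicons separate species. These goals trade off against each other, and
for insect mitochondria they trade off differently in ribosomal RNA genes
(12S/16S: conserved primer sites, moderate insert variability) and in
protein-coding genes (COI and relatives: hypervariable third codon
positions everywhere, including under the primers). `metabarprime`
implements an in silico pipeline for quantifying that trade-off against a
taxonomy-annotated reference database of (mito)genomes: degenerate primer
design, PCR emulation, amplicon clustering, and an index family that
summarizes how much of the fauna a marker actually resolves.

## Quality indices

Let $S$ be the species in the reference database, $S_A$ those with at
least one amplified sequence, and cluster the amplified inserts at a
similarity threshold. A species is *resolved* when none of its clusters
contains sequences of another species; it is *uniquely resolved* when, in
addition, all of its sequences fall in a single cluster. With $S_R$ and
$S_U$ those two species sets:

* taxonomic coverage $B_C = |S_A|/|S|$;
* taxonomic resolution $B_S = |S_R|/|S_A|$;
* exclusive taxonomic resolution $B_E = |S_U|/|S_A|$, which, unlike
  $B_S$, penalizes a species split over several clusters — the relevant
  notion when clusters are used as MOTUs without a reference;
* effective taxonomic resolution $\mathrm{ETR} = B_C \cdot B_E =
  |S_U|/|S|$, the headline number: the fraction of all database species a
  marker both amplifies and unambiguously resolves.

$B_S$ rises monotonically with the clustering threshold (at 100% only
identical sequences co-cluster), so it cannot locate the threshold that
separates intra- from interspecific variation. The cluster-relative index
$B_E' = |C_U| / (|C_U| + |C_M| + |C_N|)$ — pure clusters with a unique
label over all clusters, where $C_M$ are mixed-label clusters and $C_N$
pure clusters sharing their label with others — is penalized both by
lumping (low thresholds) and by oversplitting (high thresholds). Its
argmax over a threshold sweep is the package's operational definition of
the *barcoding gap* (`find_barcoding_gap()`), with ties broken toward the
lower threshold. Note that $|C_U| = |S_U|$ always, but $B_E' \le B_E$ is
only guaranteed while clustering refines species; below the gap, where
clusters merge species, $B_E'$ can exceed $B_E$.

A note on $S_R$: "occurring in a homogeneously labelled cluster" admits
an *at least one pure cluster* reading. The package uses the *all pure*
reading — a species with any mixed cluster is unresolved — because that
is what unambiguous identification requires downstream. All indices are
computed over amplified sequences only; unamplified conspecific
sequences never penalize a species' purity.

Two markers are combined set-algebraically (`combine_independent()`):
$\mathrm{ETR}_T = |S_U(i) \cup S_U(j)|/|S|$ decomposes exactly into the
unique contributions $|S_U(i) \setminus S_U(j)|/|S|$ (and vice versa)
plus the redundant part $|S_U(i) \cap S_U(j)|/|S|$. Each marker keeps its
own optimal threshold; reads of two markers cannot be merged at the
sequence level, so the combination is on species sets only. The residual
strategy (`residual_design()`) instead designs a second pair over only
the species the first pair failed to amplify ($S \setminus S_A$) and
scores $\mathrm{ETR}_{CR} = |S_U(\mathrm{first}) \cup
|S_U(\mathrm{new})|/|S|$ after evaluating the new pair on the full
database.

## PCR emulation

`amplify()` reports every site where the forward primer matches one
strand and the reverse complement of the reverse primer matches the same
strand downstream, on both orientations, with:

* **set-theoretic matching**: an IUPAC code matches a template base when
  its base set contains it; template `N` (or any template ambiguity code)
  never matches — the conservative choice, so coverage is never inflated
  by undetermined reference positions;
* **inosine** either pairing with all four bases (`as_N`) or with A/C/T
  only (`as_H`), the difference between an optimistic and a
  chemically realistic reading of inosine-containing primers;
* a per-primer **mismatch budget** with a mismatch-free **3' anchor**
  (default 2 bases, conventionally 3 at design time) — mismatches at the
  3' end abort extension in a real PCR;
* an **insert length window**, ±10% of the pair's expected insert by
  default, mirroring stringent-PCR emulation;
* **circular templates** scanned across the origin by doubling, with
  wrap-around products reported with `end > length` and products longer
  than the template rejected.

Coordinates are 0-based half-open on the forward strand. The insert
excludes the primer annealing sites; a template may yield several
products, each of which enters clustering, while its species counts once
in $S_A$.

## Clustering and the identity definition

Amplicons are clustered greedily in UCLUST style: sequences are processed
in descending insert length (ties by id), each joins the first existing
centroid with identity at or above the threshold, otherwise it founds a
cluster. There is no RNG and no abundance weighting, so clusterings are
reproducible byte for byte.

Pairwise identity is matches over alignment columns of the optimal
*global* alignment (match +1, mismatch −1, gap −2 per column, end gaps
penalized), with terminal gap columns excluded from the denominator.
Penalizing end gaps in the score matters: a free-end-gap optimum on
dissimilar sequences is a short, spurious, high-identity overlap, which
would glue unrelated amplicons together at high thresholds. Co-optimal
alignments are disambiguated deterministically (maximal matches, then
minimal denominator), so identity is a well-defined function of the
sequence pair. The constants are fixed, not tunable per run, so
thresholds are comparable across markers. The implementation is a small
C++ dynamic program; the test suite checks it against an exhaustive
enumeration of all alignments on short sequences, an independent
matrix DP on 60-mers, and `Biostrings::pairwiseAlignment()` scores.

A threshold sweep (95–100% in 1% steps by default) computes the identity
matrix once and reuses it at every threshold.

## Primer design

`design_primer_pairs()` proposes degenerate primers from a multiple
sequence alignment (supplied pre-aligned; the package does not wrap an
aligner):

1. columns with more than 10% gaps are trimmed (`trim_alignment()`,
   `min_occupancy = 0.9`; a column at exactly 10% is kept);
2. every window start is profiled with the Shannon entropy
   $-\sum_i p_i \log_2 p_i$ of its unique full-length window strings,
   rows with in-window gaps excluded (`entropy_profile()`);
3. the lowest-entropy windows (rank-based, default the lowest 10%) get a
   degeneracy-capped consensus primer (`design_degenerate_primer()`);
4. forward/reverse-complement pairings whose median ungapped insert falls
   in the target range (default 100–500 bp, metabarcoding-sized) are
   ranked by joint exact-match coverage, ties by summed entropy.

The consensus construction starts from the most frequent base per column
and adds one base at a time while the degeneracy cap (presets 12 and 216)
permits, carrying a small deterministic beam (default width 4) of partial
primers scored by rows matched exactly, then residual mismatch mass, then
degeneracy. Width 1 is plain greedy; the beam exists because single-step
greedy cannot see base pairs in different columns that only pay off
jointly. On random six-column windows the beam search matches an
exhaustive search over all degeneracy-feasible IUPAC primers in over 90%
of cases and is never better (the oracle bound is asserted in the tests).
Primer length defaults to 18; reverse primers are emitted 5'→3' as
reverse complements of their window consensus.

## The synthetic data generator

`simulate_reference_db()` emulates the statistical structure of a curated
mitogenome reference set with known ground truth, so every claim in the
test suite is checkable against a planted answer. A root genome is
mutated down a rank tree (order → family → genus → species → haplotype)
at per-rank substitution rates; two conserved 18-mers flanking a fixed
insert are stamped into every sequence and then degraded per copy (with
probability `mut_prob` a copy receives one random substitution), so
amplifiability is controlled by a single parameter and the expected
amplifiable species set is known exactly. Species labels can be swapped
within genera (`inject_mislabels()`) to emulate the roughly 10%
annotation disagreement seen between public repositories — swaps are
within-genus because plausible misidentifications are congeneric, not
uniform noise.

Defaults define the package's standard validation fixture and were chosen
once, as a realistic scaled-down analogue of a public insect mitogenome
set: 300 species (5×3×4×5 down the ranks), 2 kb circular genomes, a
130 bp marker insert, haplotype counts of 1/2/3 with probabilities
0.7/0.2/0.1 (databases are dominated by singletons), ~1% intraspecific
and ~5% congeneric pairwise divergence (each tier mutates at half the
target pairwise rate), and a 1% per-copy site degradation probability.
Substitutions only — no indels — so equal-length sequences double as an
alignment and identity arithmetic is closed-form in tests; an indel
process is deliberately out of the default model. What the simulator does
*not* emulate: real rank-dependent rate heterogeneity, codon structure
and selection, gene order, length variation, or the heavily skewed
taxon sampling of public databases. Passing tests therefore demonstrate
correctness of the machinery and qualitative behaviour (coverage loss
under site degradation, the $B_S$ vs $B_E'$ contrast, barcoding-gap
location between the planted divergence levels), not quantitative
performance on any real taxon set.

## Validation scale and numerical choices

The standard fixture (300 species, ~400 sequences, 130 bp inserts, six
thresholds, 20 seeds) keeps a full barcoding-gap recovery run in the
minutes range; oracle-equivalence checks run on ≤2 kb templates, ≤15
sequences per exhaustive clustering check, and 60-mers for alignment
oracles. Thresholds are compared with `>=` on exact rational identities;
index identities are set-theoretic (ETR is computed as $|S_U|/|S|$, so
$\mathrm{ETR} = B_C B_E$ holds to machine precision rather than as a
float product). Degenerate inputs fail loudly: an empty database, an
amplification with no amplified species (an error distinct from
reporting $B_C = 0$), ragged alignments, windows longer than the
alignment, thresholds outside $(0,1]$.

## Known limitations

* In silico coverage ignores thermodynamics: no melting temperatures,
  dimers, or amplification efficiency — a primer that matches may still
  fail at the bench.
* Identity is not bit-compatible with any particular USEARCH build;
  published tool chains may cluster borderline pairs differently, so
  reproduction of published index values is expected to 2 decimal
  places, not exactly.
* The residual strategy inherits the reference database's blind spots: a
  taxon absent from the design set cannot be rescued by a residual
  primer.
* Evaluating a real reference set (e.g. the deposited insect mitogenome
  databases) requires downloading it separately; the package ships only
  synthetic fixtures and the published primer list
  (`inst/extdata/insect_mito_primers.tsv`).
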