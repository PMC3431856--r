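---
title: "Methods: mitogenome architecture, composition, structure and phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome architecture, composition, structure and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomoth)
```

mitomoth describes annotated circular mitochondrial genomes the way insect
mitogenome papers do: gene-by-gene architecture around the circle,
strand-asymmetric nucleotide composition, codon usage under the invertebrate
mitochondrial code, structural elements of the A+T-rich control region, tRNA
cloverleaf validation, and concatenated-protein phylogenetics. This vignette
records the models and the design decisions behind each stage, including the
choices that were genuinely open.

## The annotated genome and its architecture

A genome is a circle of known length with 1-based closed feature intervals
(GenBank convention). A feature spanning the origin is one row with
`end < start`; extraction walks the two arcs. `F` is the majority strand as
annotation tables print it; `R` features are reverse-complemented on
extraction, so all downstream analyses see coding orientation.

The junction ledger assigns every consecutive feature pair the signed gap
`start(next) - end(this) - 1`, closing the circle from the last feature back
to the first. Positive gaps are intergenic spacers, negative gaps overlaps.
This gives the identity (sum of feature lengths) + (sum of signed gaps) =
genome length, which holds whenever no feature is nested inside another;
nesting is therefore an error, not a deep overlap. Summaries exclude
junctions flanking the control region by default, matching the convention of
counting spacers apart from the A+T-rich region; `exclude = character(0)`
includes them.

The packaged *Sesamia inferens* annotation (`sesamia_annotation()`)
transcribes the published table verbatim, including its printed size and
spacer columns. Coordinates are authoritative; `feature_table_qc()` reports
where the printed columns disagree with coordinate-derived values. Three
such inconsistencies exist: the atp6 span (678 bp derived vs 696 printed),
the rrnL–trnV junction (derived gap +1 vs printed 0), and consequently the
spacer totals (derived 19 locations / 248 bp; printed column 18 / 247 bp;
running text 257 bp). The package reports derived values and flags the
conflicts rather than silently harmonising them.

Gene-order comparison aligns two orders under the rotation minimising
position/strand mismatches and reports the genes at mismatching positions.
We deliberately do not anchor the rotation at a fixed gene: if the anchor
itself moved, anchoring would shift every downstream position and report
nearly the whole genome as displaced; minimum-mismatch rotation isolates the
actual perturbation (e.g. swapping two tRNAs reports exactly those two).
Reflections are never normalised — strand is biological signal.

## Composition and skews

AT skew is (A − T)/(A + T) and GC skew is (G − C)/(G + C). `N` bases are
excluded from numerators and denominators; a zero denominator yields `NA`
rather than a value. The regional report computes the whole-genome row on
the majority strand and the PCG/tRNA/rRNA/control rows on concatenated
coding-orientation sequences. Whether published whole-genome skews include
the control region is generally unstated; ours do. The coding-strand
convention for gene categories is likewise a choice we state rather than
inherit: it makes strand-asymmetry comparable across genes regardless of
which strand encodes them.

Codon-position composition is computed strictly in frame, after removing
each gene's initiation codon and its complete or truncated termination
codon — the same codon set the usage table counts, so the two reports can
never drift apart.

## Codon usage and RSCU

The invertebrate mitochondrial code (NCBI table 5: AGA/AGG = Ser, ATA =
Met, TGA = Trp) leaves 62 sense codons. Families follow the convention of
mitogenome codon plots: Leu splits into Leu1 (CTN) and Leu2 (TTA/TTG), Ser
into Ser1 (AGN) and Ser2 (TCN); the split lives in one table
(`codon_families()`). Truncated stops T and TA are recognised from CDS
length modulo 3 plus terminal bases and are excluded from counting, as are
initiation codons (nonstandard starts such as cox1's CGA are excluded the
same way, not counted as sense codons). In-frame internal stops are
reported per gene in the QC attribute and left out of the sense table —
never silently dropped. RSCU is count × degeneracy / family total, `NA`
for an absent family, so nonzero family sums always equal the degeneracy
exactly and per-thousand values sum to 1000.

## Control-region scanners

All detectors work on the region string with 1-based region-local
coordinates and are position-covariant.

**Origin signature.** Each `ATAGA` occurrence followed, within `max_gap`
(default 5) bases, by a poly-T run of at least `min_t_run` is reported with
the run length. The default threshold is 10 although the motivating
instance is a 19-bp run — orthologous regions carry shorter runs, and a
threshold at the observed value would overfit one genome. Both knobs are
exposed.

**Microsatellites.** Maximal perfect runs with unit length 1–6 and at least
5 (fractional) copies. Units are canonicalised to their lexicographically
minimal rotation, and a run whose unit is itself a repetition of a shorter
unit is suppressed, so an (AT)n run is never also reported as (ATAT)n/2.

**Tandem repeats.** A from-scratch detector in the spirit of classic
tandem-repeat finders, with its own (documented) scoring: for each period p
in 2–50 the region is scored against its own p-shift, +2 per agreement and
−3 per disagreement, and all disjoint maximal-scoring segments reaching
`min_score = 20` are reported with period, fractional copy number,
column-majority consensus, and identity. Segment extraction uses a
prefix-minimum scan with deterministic tie-breaks (higher score, then
smaller start, then smaller end) and recursive splitting, which yields the
same set as greedy global extraction. Indel-containing repeats are found at
a shifted period rather than through gapped alignment; gapped scoring is a
non-goal. Reports at different periods covering substantially the same span
(harmonics) are deduplicated by score; `dedup = FALSE` disables this for
oracle comparison.

**Stem-loops.** All maximal bulge-free hairpins with stem ≥ 5 bp
(Watson–Crick plus G–U wobble by default) and loop 3–20 nt. Maximal means
the stem extends neither outward nor inward (inward extension respecting
the minimum loop). Each hit carries two flank flags for the insect
replication-initiation element: TATA within 10 nt upstream and G(A)1–8T
within 10 nt downstream. Thermodynamic folding is out of scope; the score
is structural, not energetic.

**Fixed motifs.** Presence/absence, in genome coordinates, of ATACTAA in
the trnS2–nad1 spacer, AAGCCTTA within ±20 nt of the trnW–trnC junction,
and a ≥9-nt poly-A run in the 30 nt upstream of trnM (on the circle). A
named junction missing from the annotation is an error, not an absence.

`scan_control_region()` runs all detectors and drops microsatellite reports
whose span is covered by a higher-scoring tandem report at the same period
— the same repeat seen by two detectors.

## tRNA cloverleaf folding

The cloverleaf is a constrained fold, not a free secondary-structure
prediction: a 7-bp acceptor stem pairing positions 1..7 against the 3' end
behind an optional 1-nt discriminator; the anticodon arm fully anchored by
the annotated anticodon (5-bp stem, 7-nt loop with the anticodon at loop
positions 3–5); a DHU arm of 0–4 bp and a TΨC arm of 0–6 bp placed freely
in the intervals between the fixed arms (loops 3–12 nt, variable loop up to
23 nt — wide enough for metazoan tRNAs). Pairs score +2 (Watson–Crick),
+1 (G–U), −1 (mismatch); the fold maximises the total. Because the free
arms occupy disjoint intervals the optimum decomposes per arm; the test
suite verifies this against a joint exhaustive search. Ties prefer a longer
DHU stem, then a longer TΨC stem, then a present discriminator, then the
leftmost placement — deterministic by construction. A DHU stem of length 0
encodes the trnS1(AGN)-type missing arm. CCA tails are not expected in
mitochondrial tRNA genes and are trimmed if present. "Unmatched" pairs in
the descriptive sense are G–U plus mismatches.

## Phylogenetics

Distances: proportion of differing sites after complete deletion of
columns containing a gap or ambiguity, optionally Poisson-corrected
(−ln(1−p)). Poisson correction is the default for amino-acid matrices —
the classic distance-era default — and `p = 1` yields a missing distance
rather than infinity. Neighbor joining follows the Saitou–Nei Q criterion
with ties broken by lowest index pair; negative branch lengths are clamped
to zero with the total deficit recorded as an attribute. Parsimony is
Fitch's union/intersection count with gaps as wildcards, implemented on
bitmasks; the score is rerooting-invariant. The tree search is
nearest-neighbor-interchange hill climbing hardened in two ways: plateaus
of equal-scoring trees are explored breadth-first (bounded), and when no
single interchange helps, chains of two and then three interchanges are
examined — depth three spans the whole five-taxon tree space, so on
five-taxon instances the search provably reaches the parsimony optimum.
The move order is fixed, so the result is deterministic given the start
tree. Bootstrap resamples columns
with replacement; supports are the percentage of replicate trees containing
each split, and the reported tree is the 50% majority-rule consensus (at
exactly 50%, splits are admitted greedily while compatible). Trees are ape
`phylo` objects; outgroup rooting is presentation, not inference — core
trees are unrooted.

## The synthetic-data generator

`simulate_mitogenome()` exists so that every stage can be tested against
ground truth with no downloads. Its defaults are the study conditions of
the motivating genome and are not tuning knobs:

* the gene-order template is the packaged annotation, so the junction
  ledger (18+1 spacer locations, 6 overlaps totalling 25 bp) is reproduced
  by construction;
* protein genes carry the annotated start/stop codons, including cox1's
  CGA start and the three truncated-T stops; interior codons are sampled
  with per-position base frequencies chosen to give codon-position AT
  content near the observed 87.7/72.9/75.2%, resampling in-frame stops;
* the control region (~96% AT background; ~92% AT over the whole
  region once the GC-bearing plants are in place) carries the origin
  signature
  (ATAGA + 19-bp poly-T), a TATA/GAAAAT-flanked 8-bp-stem hairpin, a
  duplicated 17-bp repeat with one substitution, a decuplicated divergent
  8-bp repeat whose per-copy substitutions are deliberately aperiodic (so
  no harmonic outscores the true period), and an (AT)7 microsatellite,
  each separated by a run-breaking base so maximal runs end where the
  plant ends;
* tRNAs are designed cloverleaves: acceptor and anticodon stems are
  AT-rich and may carry planted G–U (rate 0.04) and mismatch (rate 0.025)
  pairs — rates chosen to mirror the observed regime of a few dozen
  non-canonical pairs across 22 tRNAs; the placement-free DHU and TΨC
  stems are GC-armed inside single-letter loops, which makes the planted
  placement the unique score optimum, so folding recovers the plant
  exactly; trnS1 is planted with no DHU stem;
* overlapping features (trnW/trnC, atp8/atp6, trnF/nad5, trnI/trnQ,
  trnL1/rrnL) are resolved by constraint propagation: whatever was written
  first fixes the shared bases and the later feature's design complements
  around them. The AAGCCTTA motif is planted first at the trnW–trnC
  overlap and both tRNAs build their acceptor stems around it.

Everything planted is recorded in a ledger (base counts per region,
interior codons per gene, stem pairs per tRNA, control-region plant
coordinates), and the tests assert module outputs against the ledger —
exactly for composition and codon counts, up to detector thresholds for
the scanners. What the generator does **not** emulate: real mutational
processes, indels, rate heterogeneity, rRNA secondary structure, or
biologically realistic spacer sequences. Passing these tests shows the
analytics are correct on genomes with known truth, not that the detectors'
thresholds are optimal for real control regions.

`simulate_alignment()` evolves amino-acid columns independently under the
20-state equal-rates model: on a branch of length b a site changes with
probability (19/20)(1 − e^(−20b/19)), to a uniformly chosen other state.
This closed form is also what the tests check the observed p-distance
against.

## Problem sizes and numerical choices

The test suite validates the tandem and stem-loop detectors against
exhaustive brute-force oracles on 100 random sequences of 200–300 nt and
the cloverleaf folder against exhaustive arm-placement search on 50 random
tRNAs; neighbor joining is checked for exactness on additive matrices up
to 12 taxa, the parsimony search against all 15 five-taxon topologies,
and bootstrap behaviour on an 8-taxon, 2000-column simulated alignment at
200 replicates, where all true splits are expected at ≥90% support. These
sizes keep the whole suite within a few minutes on a single core while
leaving each check at full strength at its scale. Percentages are reported
to full precision and only rounded for display; all randomised procedures
take a single integer seed and consume one random stream in a fixed order,
so repeated runs are byte-identical.

## Known limitations

* The GenBank dialect is minimal (LOCUS / FEATURES / ORIGIN with CDS,
  tRNA, rRNA, D-loop, misc_feature); other keys are skipped with a
  warning, and multi-record files are unsupported.
* Ambiguity codes other than N are rejected; the intended inputs are
  finished mitogenome sequences.
* The tandem detector's substitution-only scoring finds indel-bearing
  repeats at shifted periods rather than as gapped alignments.
* Rearrangement distances (breakpoint, DCJ), rRNA structure models,
  thermodynamic RNA folding, codon adaptation indices and ML/Bayesian
  phylogenetics are out of scope.
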