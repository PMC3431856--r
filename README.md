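# mitomoth

Analytics for annotated circular insect mitochondrial genomes, built around
the lepidopteran gene arrangement. Given an annotation table (or a minimal
GenBank flat file) and optionally the nucleotide sequence, mitomoth computes
the statistics a mitogenome description paper reports:

* **architecture** — the junction ledger of intergenic spacers and gene
  overlaps around the circle (`gap = start(next) − end(this) − 1`, closed at
  the origin), gene-order signatures and displaced-gene comparison;
* **composition** — per-region nucleotide composition with the strand-skew
  statistics AT skew = (A−T)/(A+T) and GC skew = (G−C)/(G+C), plus AT
  content at the three codon positions of the protein-coding genes;
* **codon usage** — start/stop classification (including truncated stops T
  and TA), codon counts per thousand and relative synonymous codon usage
  (RSCU = count × degeneracy / family total) under the invertebrate
  mitochondrial code, with Leu and Ser split into their conventional
  subfamilies;
* **control region** — from-scratch structural scanners for the A+T-rich
  region: the replication-origin signature (ATAGA + poly-T), microsatellites,
  a tandem-repeat detector with self-alignment scoring (+2/−3, min score
  20), flanked stem-loops (TATA … G(A)nT), and diagnostic junction motifs
  (ATACTAA, AAGCCTTA, poly-A upstream of trnM);
* **tRNA structure** — constrained cloverleaf folding anchored on the
  annotated anticodon (acceptor 7 bp, DHU 0–4 bp, anticodon 5 bp + 7 nt
  loop, TΨC 0–6 bp; scores WC +2, G–U +1, mismatch −1) with per-pair
  classification;
* **phylogenetics** — p/Poisson distances with complete deletion, Saitou–Nei
  neighbor joining, Fitch parsimony with NNI hill climbing, and column
  bootstrap with 50% majority-rule consensus, all on `ape::phylo` objects;
* **synthetic data** — a generator that plants all of the above structure in
  a full-length genome and records the ground truth, so each stage is
  testable without downloads.

Results are tibbles (with `tidy()`/`glance()` accessors and
`autoplot()`/`plot_*()` displays), so analyses chain with the pipe.

## Worked example

The package ships the published annotation of the *Sesamia inferens*
mitogenome (GenBank JN039362; 15,413 bp, 37 genes + A+T-rich region):

```r
library(mitomoth)

rec <- sesamia_annotation()
rec
#> <mitogenome> S_inferens_JN039362: 15,413 bp circular, 38 features, sequence absent
#>   control: 1, PCG: 13, rRNA: 2, tRNA: 22

rec |> junction_ledger() |> ledger_summary()
#> # A tibble: 1 × 6
#>   spacer_count spacer_total_bp longest_spacer overlap_count overlap_total_bp
#>          <int>           <int>          <int>         <int>            <int>
#> 1           19             248             68             6               25
#> # ℹ 1 more variable: longest_overlap <int>
```

The six overlaps total 25 bp with the deepest (11 bp) between atp8 and
atp6, and the longest spacer (68 bp) sits between trnQ and nad2 — the
values the annotation table implies. Note the spacer count: the printed
spacer column of the source table has 18 positive entries totalling
247 bp, but the coordinates imply one more 1-bp spacer at the rrnL–trnV
junction. `feature_table_qc()` reports exactly where the printed columns
and the coordinates disagree:

```r
feature_table_qc(rec)
#> # A tibble: 2 × 4
#>   check  feature   printed derived
#>   <chr>  <chr>       <dbl>   <dbl>
#> 1 size   atp6          696     678
#> 2 spacer rrnL-trnV       0       1
```

Sequence-dependent stages run on a synthetic genome with planted, known
structure:

```r
sim <- simulate_mitogenome(genome_spec(seed = 1))
region_composition_report(sim$record) |>
  dplyr::select(region, at_content, at_skew, gc_skew)
#> # A tibble: 5 × 4
#>   region         at_content at_skew gc_skew
#>   <chr>               <dbl>   <dbl>   <dbl>
#> 1 whole_genome         78.8 -0.0386 -0.0706
#> 2 PCGs                 79.0 -0.204  -0.256
#> 3 tRNAs                66.1  0.437   0.0140
#> 4 rRNAs                83.4  0.0619  0.197
#> 5 control_region       92.0 -0.0490 -0.04

sim$record |> extract_feature_sequence("AT_rich") |> scan_control_region()
# origin signature (ATAGA + 19-bp poly-T), the (AT)7 microsatellite, the
# 17-bp duplication and divergent 8-bp decuplication, and the flanked
# stem-loop, each with region-local coordinates

trna_structure_report(sim$record) |> head(3)
# per-tRNA arm lengths and WC / G-U / mismatch counts; trnS1 folds with
# a missing DHU arm
```

Phylogenetics on a simulated alignment:

```r
true <- ape::unroot(ape::rtree(8))
true$edge.length <- runif(nrow(true$edge), 0.1, 0.3)
aln <- simulate_alignment(true, 2000, seed = 5)
tree <- bootstrap_support(aln, builder = "nj", replicates = 200, seed = 7)
attr(tree, "split_support")   # per-split bootstrap percentages
```

## Scope

Wet-lab workflow steps (assembly, alignment construction, de novo tRNA
scanning) are out of scope: annotations and alignments arrive as inputs.
rRNA secondary structure, thermodynamic RNA folding, rearrangement
distances and ML/Bayesian phylogenetics are non-goals. See the methods
vignette (`vignettes/mitomoth-methods.Rmd`) for models, parameter
defaults and design decisions.
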