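# indelatlas

Insertions and deletions (indels) in protein sequences are rare genomic
changes: a segment gained or lost in one lineage leaves a characteristic
gap pattern in a multiple sequence alignment (MSA), and such patterns can
mark clades, diagnose species, and reveal systematic biases in how
proteins grow and shrink.  `indelatlas` is an R package for molecular
evolutionary biologists who want to mine aligned protein families for
these signals.  It implements, as tested and reusable components:

* **Consensus-guided indel extraction.**  A column of an MSA is
  *conserved* at similarity threshold *t*% when its most frequent residue
  is shared by at least *t*% of the sequences (gaps count in the
  denominator; `X` matches nothing).  Maximal runs of variable columns
  between conserved anchors are candidate indel regions; regions
  separated by fewer than the *inter-indel space* (default 3) conserved
  columns are merged, and only regions containing gaps are reported.
  A threshold survey over 25–100% in 5% steps locates the optimum
  (the peak of the complex-indel count curve).
* **Simple vs complex states.**  Each sequence's gap pattern over a
  region is a mask; a region with exactly two masks — segment fully
  present or fully absent — is a *simple* indel (potentially one
  event), anything else is *complex*.  Leading/trailing gap runs are
  treated as missing data, not deletions.
* **Phylogenetic typing.**  Against a rooted reference tree, each simple
  indel is a *singleton* (minority state in exactly one taxon), a
  *clade-defining indel* (CDI: one gain or one loss explains the
  pattern), *homoplastic* (≥ 2 independent events required under any
  rooting — checked against an exhaustive minimum-change oracle in the
  test suite), or *ambiguous* (a missing taxon sits inside or sister to
  the would-be clade).
* **Insertion:deletion (I:D) ratios.**  Singletons polarize by
  parsimony (lone segment present = insertion, lone gap = deletion);
  per-taxon, per-group and pooled I:D ratios quantify insertion bias.
* **Ortholog screening.**  Three-tier BLAST hit retention (E-value 0.0
  hits; median log10 E-value-distance cutoff; single sub-1e-30 hit),
  fragment removal at 50% of the mean ungapped length, in-paralog
  pruning (shortest branch in >70% supported single-species clades) and
  four-way taxon-coverage categories
  (complete / nearly complete / patchy / flawed).
* **A ground-truth simulator.**  Indel events are planted on the
  branches of a phylogeny (Poisson per site per unit branch length,
  geometric 1aa-heavy lengths, configurable I:D rate ratio, default
  2.31) between conserved flanks, with an event log from which every
  downstream call can be verified exactly.

## Worked example

Simulate a 12-protein corpus over the bundled 35-taxon tree, run the
pipeline and inspect the results:

```r
library(indelatlas)
co  <- simulate_corpus(simulation_config(n_proteins = 12, seed = 42))
run <- run_pipeline(co$alignments, co$tree, co$roster, quiet = TRUE)
print(run)
#> Indel pipeline run
#>   alignments kept: 12 of 12
#>   indels: 209 (200 simple, 9 complex) at threshold 50%
#>   simple-indel partition:
#>         type   n pct_simple pct_all
#>    singleton 117       58.5    56.0
#>          CDI  83       41.5    39.7
#>  homoplastic   0        0.0     0.0
#>    ambiguous   0        0.0     0.0
#>   pooled I:D ratio: 2.34 (82:35)
```

The run recovered all 209 planted regions: 200 are simple (two-state)
indels, of which 117 are singletons and 83 are clade-defining; on this
fully sampled, noise-free corpus nothing is homoplastic or ambiguous, as
it should be.  The pooled I:D ratio of 2.34 (82 singleton insertions,
35 deletions) estimates the 2.31 insertion:deletion rate ratio the
simulator plants by default.

```r
print(run$id_ratios)
#> Singleton insertion:deletion ratios
#>   pooled: 82 insertions / 35 deletions = 2.34
#>   mean of taxa (>=1 deletion): 1.8
#>             group insertions deletions pooled_ratio mean_of_taxa
#>         Amoebozoa          4         4     1.000000     1.000000
#>  Choanoflagellata          3         1     3.000000     3.000000
#>             Fungi         17         6     2.833333     1.055556
#>           Metazoa         37        15     2.466667     2.166667
#>        Rhodophyta          4         0          Inf           NA
#>     Viridiplantae         17         9     1.888889     1.466667
```

`run$indels` holds the per-region table (0-based half-open spans;
reports print 1-based inclusive), `run$calls` the per-indel phylogenetic
calls, and `write_indel_report()` / `run_pipeline(out_dir = ...)`
serialize everything as TSV.  A thin command-line front-end with
`simulate | screen | extract | phylo | run` subcommands is installed at
`system.file("cli", "indelatlas.R", package = "indelatlas")`.

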