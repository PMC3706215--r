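---
title: "Methods: consensus-guided indel extraction and phylogenetic typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-guided indel extraction and phylogenetic typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `indelatlas`,
the assumptions they make, the tunable parameters and their defaults,
and the design choices taken where more than one reasonable definition
exists.  The companion README shows a worked run; here we explain *why*
the machinery is built the way it is.

## The extraction model

An indel that occurred in the history of a protein family is visible in
a multiple sequence alignment as a stretch of columns where some
sequences carry residues and others carry gaps, bracketed by columns
where all sequences agree well.  Extraction therefore rests on a
per-column *conservation profile*:

* A column is **conserved at threshold _t_ (percent)** when its most
  frequent residue is shared by at least _t_% of the sequences.  Gaps
  count in the denominator, and neither the gap character nor `X` can be
  the consensus residue.  This makes a column with two residues and two
  gaps 50% conserved — gapped sequences vote against conservation, which
  is what lets gap-rich regions surface as variable.
* When two residues tie for most frequent, the tied maximum count
  defines the fraction (no residue identity is needed for the
  conserved/variable call).  Where a consensus *identity* is required —
  the per-group conservation summary — the alphabetically first tied
  residue is used, a deterministic and documented tie-break.

Candidate indel regions are maximal runs of variable columns strictly
between the first and last conserved columns; unanchored alignment ends
are excluded because a region with no conserved flank on one side cannot
be delimited reliably (and fragmentary sequence ends would flood it with
spurious gaps).  Two candidates separated by fewer than the
**inter-indel space** (default 3) conserved columns are merged, the
merged span keeping the intervening columns: weakly conserved islands
inside a long indel are part of the indel, and this merging is exactly
how large multi-state regions arise as the threshold grows.  Finally,
only spans in which at least one sequence has a gap are reported —
a variable but gap-free region is substitutional, not indel, variation.

**States.**  Each sequence's gap pattern over a span is reduced to a
mask (residue/gap per column).  A region with exactly two masks, fully
present and fully absent, is a **simple** indel: one segment, carried or
not, potentially the product of a single event.  Anything else is
**complex**.  A 1aa region can only ever have the two masks, so 1aa
indels are simple by construction — the suite asserts this invariant.

**Terminal gaps.**  A leading or trailing gap run is treated as missing
data: truncated sequences are common and their absent termini are not
deletion events.  Sequences whose terminal gap run covers a span are
excluded from that span's state set and presence vector; a region whose
non-missing masks collapse to a single state is dropped.

**Threshold survey.**  Extraction is run over thresholds 25–100% in 5%
steps; the count of complex indels traces a curve whose peak balances
stringency (too low a threshold hides indels inside "conserved" noise)
against sensitivity (too high a threshold merges everything into a few
giant regions).  `select_optimal_threshold()` returns the argmax of the
complex count, ties broken toward the lower threshold.  The default
threshold everywhere is 50%.

## Phylogenetic typing

Simple indels are interpreted against a rooted reference phylogeny with
the alignment's taxa mapped to leaves.  The classification, in order of
precedence:

1. **Singleton** — exactly one scored taxon carries the *minority*
   state.  A lone carrier of residues among gapped sequences is a
   singleton insertion; a lone gap among residue carriers is a singleton
   deletion.  The minority-state formulation is deliberate: defining
   singletons only by residue presence would misread every singleton
   deletion as a clade marker of the remaining *n* − 1 taxa.
   Singleton status takes precedence over ambiguity — a derived state in
   one sampled taxon stays a singleton no matter which other taxa are
   missing.
2. **Homoplastic** — the presence/absence bipartition cannot be
   explained by one gain or one loss anywhere on the tree.
   Operationally: neither the bearing set nor its complement can form a
   clade under any rooting of the tree pruned to the scored taxa.  This
   single-event criterion is rooting-invariant; the test suite proves it
   equivalent to an exhaustive minimum-change oracle (all internal-state
   assignments enumerated) on every non-constant pattern for all
   topologies with up to 6 leaves and samples of 7- and 8-leaf
   topologies.
3. **Ambiguous** — the pattern fits a single event, but a roster taxon
   absent from the alignment attaches, on the full tree, inside the
   defined clade or in its immediate sister lineage.  Such a taxon could
   break or extend the clade, so the call is withheld.  The rule is
   structural because "a missing sister taxon" is the one precisely
   localizable cause of uninterpretability; taxa missing elsewhere in
   the tree do not block the call.
4. **CDI** (clade-defining indel) — otherwise; the defined clade is the
   monophyletic side of the bipartition (the smaller side when the split
   is adjacent to the root and both sides are clades, ties to the
   residue side).  A shared deletion defines its clade just as a shared
   insertion does.

**Polytomies** are treated as soft: a set equal to the union of some of
a polytomy's child subtrees is compatible with monophyly (some
resolution makes it a clade), so polytomies never create homoplasy;
a set that splits a resolved clade does.  This is conservative toward
CDI calls.

**Polarization and I:D ratios.**  With at least two uniform non-bearing
sequences, parsimony forces the direction of a singleton (insertion vs
deletion).  `compute_id_ratios()` reports per-taxon counts and ratios,
and *both* the pooled ratio (summed insertions / summed deletions) and
the mean of per-taxon ratios over taxa with at least one deletion.  The
two differ whenever insertion bias varies across taxa, and published
"average" ratios do not always say which was computed — reporting both
avoids the ambiguity.  A taxon with insertions but no deletions has an
infinite ratio and is excluded from the mean.

## Ortholog screening

The screening stage mirrors how universal single-copy ortholog sets are
assembled in practice:

* **Hit retention** is three-tiered: E-value 0.0 hits are taken alone
  when present; otherwise hits below 1e-65 are ranked by their log10
  E-value distance to the top hit, d = |log10 E − log10 E₁|, and the
  median distance is the cutoff; otherwise the single best sub-1e-30 hit
  is taken.  Log space is the only scale on which a median over E-value
  gaps spanning tens of orders of magnitude is meaningful.  The default
  retains hits with d ≤ cutoff — those comparable to the best hit, which
  is what an orthology screen wants; `keep = "far"` retains the distant
  side instead for users who need that convention.  Median-based
  trimming is not idempotent in the moderate tier (re-filtering
  recomputes a median over survivors and trims again); the other tiers
  are stable under re-filtering, and the tests pin down both behaviours.
* **Fragment removal** drops sequences with fewer residues than half
  (configurable) the mean ungapped length, in a single pass — the mean
  is not recomputed on survivors, so the filter cannot cascade.
* **In-paralog pruning** keeps, within every maximal clade of >70%
  support whose leaves are all one species, the leaf with the shortest
  root-to-leaf path; nothing else is touched, and the last sequence of a
  taxon can never be removed.
* **Coverage categories**: `complete` (no taxa missing),
  `nearly_complete` (≤ 2 missing, none a deep-branch sole
  representative), `patchy` (3–7 missing, deep branches intact), and
  `flawed` (a deep taxon missing, a whole major group missing, or > 7
  missing).  The boundaries ≤ 2 / 3–7 make the table total and disjoint;
  a property test checks exactly one label applies to any subset.
  `flawed` alignments are discarded by the pipeline.

## The simulator: what it emulates, and what it does not

`simulate_corpus()` generates the data-generating process the analysis
assumes: indel events arising on branches of a known phylogeny.  Events
per protein are Poisson with mean (ins + del rate) × length × total
branch length; each event lands on a branch with probability
proportional to branch length, is an insertion or deletion in proportion
to the rates, and draws a geometric length (P(1aa) = `size_p`).  An
insertion on branch *b* yields residues in exactly the leaves below *b*;
a deletion yields gaps there.  Defaults are fixed once as the package's
study conditions: deletion rate 1.4 × 10⁻³ per site per unit branch
length with insertions 2.31× as frequent (the insertion bias reported
for universal single-copy eukaryotic proteins), `size_p` = 0.427 (so
~43% of events are 1aa), proteins of 250–1000 residues over the bundled
35-taxon tree, and a conserved flank width of 5 columns.

Design choices worth knowing:

* **Alignments are emitted directly in a master coordinate system** —
  homologous residues stay aligned by construction, isolating pipeline
  correctness from aligner error.  There is no re-alignment stress mode.
* **Event regions are flanked by identical conserved columns** at least
  as wide as the inter-indel space, so planted regions can never merge
  and recovery can be asserted exactly (spans, simple/complex state and
  phylogenetic type all match the event log on noise-free corpora — the
  acceptance suite checks 100% of ~1,900 events on a 100-protein
  corpus).
* **Residues inside event regions are varied across carriers** so the
  columns score as variable at any threshold; biologically this reads as
  substitution saturation inside loop regions, and it only affects
  conservation, never the gap masks.
* **Complex regions** are planted by nesting a deletion (on a descendant
  branch) inside an insertion with probability `complex_fraction`
  (default 0.2 of eligible insertions), guaranteeing ≥ 3 mask states.
* **Substitution noise columns** (`noise_rate`, default 0) are gap-free,
  partially conserved columns placed in their own flanked slots, so the
  recovery guarantees survive noise.
* The simulator's **bundled tree and roster are synthetic**: 35 taxa in
  the proportions 15 Metazoa / 8 Fungi / 8 Viridiplantae / 2 Amoebozoa /
  1 Rhodophyta / 1 Choanoflagellata with three sole-representative deep
  branches, uniform branch lengths 0.1.  They stand in for a real
  proteome sampling; no published tree is reproduced.

What passing tests therefore show — and do not show.  Exact recovery on
this generator demonstrates that the extraction and typing logic is
correct: every planted pattern is found and interpreted as the
generative model implies.  It does *not* demonstrate robustness to
aligner error, non-geometric size laws, rate variation across sites or
lineages, or fragmentary sequences beyond the terminal-gap rule: real
corpora violate all of these to some degree, and absolute counts (for
instance the shape of a threshold-survey curve) will shift accordingly.
In particular, because the synthetic flanks are perfectly conserved, the
survey counts barely move with the threshold on simulated corpora; the
survey machinery is exercised there, but its threshold response is
tested on random noisy alignments instead.

## Numerical conventions and degenerate inputs

* Column spans are 0-based half-open internally; reports print 1-based
  inclusive spans.  No silent trimming anywhere: column indices survive
  every round trip.
* FASTA is written wrapped at 60 columns; reading accepts any wrapping
  and case.  `.` and `*` are hard errors (their meaning differs between
  alignment tools), as are ragged records (the offending record is
  named) and empty files.
* Ragged/duplicate/unknown-taxon inputs error early with the offending
  identifier; an all-gap "indel" pattern and a span with fewer than two
  states are rejected, not guessed at.
* All randomness flows through a single integer seed; a fixed seed makes
  the corpus — and every downstream file — byte-identical, which the
  suite asserts.

## Problem sizes used by the test and acceptance suites

The suites are sized to run comfortably on one CPU: oracle equivalence
enumerates all topologies to 6 leaves and 25 random topologies each for
7 and 8 leaves (all non-constant patterns in every case, > 15,000
pattern–tree checks); planted-event recovery uses a 100-protein,
35-taxon corpus; I:D recovery uses 8-taxon corpora with ≥ 500 singleton
events per run, single runs for rate ratios 1, 2 and 4 plus 100
replicates each for the coverage check of the exact binomial interval.

## Known limitations

* Substitution-group consensus (treating biochemically similar residues
  as matching) is not implemented; consensus is exact identity, matching
  the "no substitution groups" setting of consensus-based extraction
  tools.
* Gene trees for in-paralog pruning are inputs; no tree inference is
  performed.
* The ambiguity rule is structural (missing-inside-or-sister); it does
  not model probabilistic placement of unsampled taxa.
* Out-paralog clades are not automatically split into new clusters.
* Indel-only phylogeny reconstruction is out of scope by design: the
  typing results themselves (homoplasy among apparently simple indels)
  argue for treating indels as corroborating, not primary, characters.
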