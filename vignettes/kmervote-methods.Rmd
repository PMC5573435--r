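---
title: "Two-stage taxonomic classification of metagenomic fragments: methods and design notes"
author: "kmervote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage taxonomic classification of metagenomic fragments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shotgun metagenomic sequencing produces large numbers of short DNA
fragments (typically 75–400 bp) from a mixture of microbial species.
Taxonomic read classification asks: given a collection of labelled
reference genomes, which species did each fragment come from?
Composition-based classifiers answer this from the fragment's k-mer
profile; alignment-based classifiers answer it by local alignment
against the reference. Short fragments are the hard case: different
species share similar short segments, so a single fixed k-mer size loses
information and misclassifies a substantial minority of reads.

`kmervote` implements a two-stage hybrid:

1. **Voting stage.** An ensemble of L2-loss linear SVMs — one per k-mer
   size, default $k \in \{6,7,8,9,10\}$ — votes a species for every
   query fragment. Fragments whose vote count for the plurality label
   reaches a threshold (default 5, i.e. full agreement) form the
   *confident set*; the rest form the *diffident set*. The intuition is
   that different k-mer sizes carry complementary information: easy
   fragments are classified identically under every k, hard ones are
   not.
2. **Fallback stage.** Only the diffident fragments are re-classified
   by their best local-alignment hit against the same reference set; a
   fragment with no hit passing the e-value (and optional identity)
   policy is tagged `unknown`. Confident labels are never touched.

## The models

### k-mer profiles

A fragment of length $l$ is represented, for each $k$, by the vector of
counts of its length-$k$ words over the $4^k$-dimensional word space —
at most $\min(4^k,\, l - k + 1)$ entries are non-zero, so profiles are
stored sparsely (`Matrix::dgCMatrix`). Counting slides a window of
step 1 along the given strand only; windows containing a non-ACGT base
(e.g. N) are skipped entirely, so for an ACGT-only sequence the counts
sum to $l - k + 1$. The index convention is fixed (A=0, C=1, G=2, T=3,
first position most significant) and serialized models depend on it.
Raw integer counts are the default feature values; length
normalisation and canonical (strand-symmetric) counting exist as
options but are off, since the classifier is trained and applied on
fragments of a fixed length from a known orientation convention.

### Per-k linear SVM

Each ensemble member is a one-vs-rest L2-loss linear SVM. For class
$c$ with labels $c_j \in \{-1,+1\}$ over training profiles $x_j$, the
weight vector solves

$$\min_W \; \tfrac12 W^\top W \;+\; \omega \sum_{j=1}^N
  \max\bigl(1 - W^\top x_j\, c_j,\; 0\bigr)^2 ,$$

with no bias term (the decision function passes through the origin, the
usual choice for high-dimensional count features). The loss weight
defaults to $\omega = 32$, a value selectable by stratified k-fold
cross-validation (`svm_select_omega()`); the default reflects the
scale of constraint violation penalty that CV selects on mid-sized
fragment collections, and it is deliberately exposed because the
"right" $\omega$ is data-dependent. Prediction takes the class with
the largest decision value, ties broken towards the lexicographically
first class so runs are reproducible.

The solver is dual coordinate descent (the standard algorithm for this
objective: box-constrained dual with diagonal shift $1/(2\omega)$),
implemented in C++. It runs until the projected-gradient gap falls
below $10^{-3}$ (configurable) with a 1000-pass cap, visiting points in
a random order drawn from a fixed-seed generator, so results are
deterministic for a given data ordering. The tests verify the solver
against an independent BFGS minimisation of the primal objective
(which is differentiable) to $10^{-4}$ relative on small instances, and
check the structural identity that duplicating every training point
while halving $\omega$ leaves the solution unchanged.

### Voting and the partition

Member predictions are aggregated by plurality; the agreement count of
a fragment is the number of members voting for its plurality label
(ties again to the lowest class index). With threshold $t$, a fragment
is confident iff its agreement $\ge t$. Two properties follow directly
and are asserted as tests: the confident and diffident sets partition
the query set for every $t$, and confident sets are nested decreasing
in $t$ (with $t = 1$ putting everything in the confident set). In
voting-only mode every fragment — diffident included — receives its
plurality label; this is a documented choice (the simplest
deterministic rule), since a voting classifier has no rejection option.

### Alignment fallback

The reference index stores every exact word of length 11 (the classic
nucleotide seed size) of the reference sequences; queries are seeded in
both orientations, so both reference strands are reachable even though
k-mer profiling is single-stranded (local alignment is strand-aware by
construction). The top seeded candidates per query (default 8, ranked
by seed support) are extended by Smith–Waterman local alignment over
the seed-bounded subject window with the classic nucleotide scoring
(match +2, mismatch −3, gap open 5, gap extend 2), reusing
`Biostrings::pairwiseAlignment` for the dynamic programming. Raw
scores are converted through the Karlin–Altschul statistics for this
scoring scheme ($\lambda = 0.625$, $K = 0.41$, the standard gapped
values for +2/−3):

$$\text{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m \, n \, 2^{-\text{bit}},$$

with $m$ the query length and $n$ the total reference length. The best
hit is the lowest e-value (ties: higher bit score, then lowest subject
id). Two policy presets exist: `default` (e-value $\le 10$, no
identity floor — a plain nucleotide search) and `strict` (e-value
$\le 10^{-5}$ and identity $\ge 97.5\%$ — for noisy real-world data
where a wrong label is worse than `unknown`). An adapter consumes
standard 12-column tabular alignment output instead
(`best_hits_tabular()`), applying identical tie rules, so an external
`blastn` run can stand in for the internal aligner; the test suite
cross-checks the two routes against each other on exact-substring
queries.

### Evaluation conventions

Reports follow the conventions of the staged design:

* **accuracy** = 100 · (total true positives) / (all fragments in the
  set, *including* those tagged `unknown`) — refusing to answer is not
  rewarded;
* **sensitivity** and **specificity** are macro-averages of per-class
  $TP/(TP+FN)$ and $TN/(TN+FP)$ over the evaluated (non-unknown)
  fragments, with empty-denominator classes skipped; micro-averaging is
  available (`average = "micro"`) because the choice is a genuine
  convention ambiguity, and outputs are labelled with the convention
  used;
* `n_unknown` is always reported alongside.

`staged_report()` produces the confident / diffident / combined rows;
when nothing is unknown the combined accuracy is exactly the
set-size-weighted mean of the per-set accuracies (tested). Reports at
coarser taxonomic levels use a user-supplied species-to-level mapping
(`map_taxonomy()`).

## The synthetic data generator

`synthetic_spec()` + `make_dataset()` emulate a multi-species genome
collection:

* each species gets an order-3 Markov composition model with rows drawn
  from a symmetric Dirichlet (concentration 1 by default) — distinct
  oligonucleotide composition is exactly the signal k-mer classifiers
  exploit; concentration `Inf` removes it (all species uniform);
* per species, an ancestor genome is sampled and every reference and
  validation genome is an independent 2%-substituted copy of it, so
  validation genomes are never in the reference set but originate from
  its species (a strain-like relationship);
* genomes are shredded into non-overlapping 400 bp windows (trailing
  remainder dropped; nothing under 75 bp is ever emitted), and
  substitution errors at a configurable rate (0 by default, 2% for the
  error study) are applied to validation fragments only, uniformly over
  the three alternative bases.

The defaults (5 species, 10 reference + 2 validation genomes per
species, 50 kb genomes) are the study conditions used by the
acceptance tests and `scripts/acceptance.R`; they were chosen to scale
down a real small benchmark (tens of genomes over a handful of
species) to desk size. The whole dataset is a pure function of the
spec, seed included.

### What the generator does and does not emulate

This matters for interpreting the test suite, and we state it plainly.
The generator reproduces: species-distinct composition, within-species
divergence, fixed-length shredding, substitution errors. It does
**not** reproduce several features of real genome collections:

* **strain-level accessory content** — real validation strains contain
  sizeable regions with no homolog in the reference; here every
  validation base descends from the shared species ancestor;
* **inter-species compositional overlap** — Dirichlet(1) order-3
  models are far more distinct than real bacterial genera;
* indels, platform error profiles, quality values, abundance skew.

Two consequences show up in the acceptance runs, and we report them
rather than hide them. First, because every validation fragment is a
near-copy (≈4% substitution distance) of homologous training
fragments, the member SVMs can classify by exact shared k-mers, all
five members agree on essentially every fragment, and the diffident
set comes out **empty**: the staged pattern seen on real data — a
large accurate confident set against a small inaccurate diffident set
that the alignment fallback rescues — does not materialise under these
conditions, and the acceptance test asserting it fails honestly.
Second, the same homology keeps accuracy at 100% even in the
uniform-composition control, where a composition-only argument would
predict chance (20% for 5 species): shared-ancestor sequence identity
is a signal in its own right, independent of composition, so that
control's near-chance expectation also fails. Any generator that gives
the alignment fallback something to find (cross-set homology)
necessarily hands the SVMs this memorisation signal; a generator
without homology would instead make the fallback useless. Producing
the real staged pattern would require modelling accessory genomes and
realistic compositional overlap, which is out of scope here. The
passing tests therefore establish the correctness of the machinery
(counting, solver, voting, partition invariants, alignment statistics,
report arithmetic, conservativeness of the fallback, error robustness)
— not that synthetic performance predicts real-data performance.

## Numerical choices and degenerate inputs

* Solver: tolerance $10^{-3}$ on the projected-gradient gap, 1000-pass
  cap, fixed-seed visiting order; objective values are checked against
  an independent minimiser in the tests.
* All tie-breaks deterministic: argmax and vote ties to the lowest
  class index, best-hit ties by bit score then subject id.
* `k` above 15 is rejected (the integer word-index space overflows).
* A sequence shorter than k yields an empty profile, not an error; a
  query shorter than the seed word size yields no hit, not an error.
* Single-class training labels, non-positive $\omega$, out-of-range
  thresholds, unlabelled reference sequences, and id mismatches between
  predictions and truth are rejected with informative errors.
* An empty diffident set produces a `not applicable` (NA) diffident
  report row, with set sizes still reported.

## Problem sizes in the tests

The unit tests run on small collections (3 species, a few kb genomes,
k up to 6); the acceptance tests and `scripts/acceptance.R` run the
full staged scenario (6,250 reference and 1,250 validation fragments,
five k values up to $4^{10}$ features) plus its two controls and the
2%-error study, a few minutes of CPU in total. These sizes are the
package's chosen study conditions, stated here so results are
reproducible at the same scale.

## Known limitations

* The generator limitations above: no accessory genome content, no
  indels, no abundance modelling.
* The internal aligner is a seed-and-extend heuristic with fixed word
  size 11; it will miss homology below ≈70% identity (no shared
  11-mers), which is the intended operating range for same-species
  fallback but not a general-purpose search. The tabular adapter
  exists precisely so a full BLAST run can be substituted.
* Karlin–Altschul parameters are fixed for the +2/−3 scoring; changing
  the scoring matrix without updating $\lambda, K$ would silently
  mis-scale e-values, so the scoring is not exposed as a user
  parameter.
* One-vs-rest with a plain argmax has no rejection option at the
  voting stage; `unknown` can only arise from the fallback policy.
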