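---
title: "Rate-based locus selection: model, procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-based locus selection: model, procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusrank)
```

## The problem

Target-capture (hybrid enrichment) studies recover a few hundred loci across
tens of taxa. Not all loci are equally useful for deep phylogenetics:
fast-evolving loci saturate — multiple substitutions overwrite each other —
and some carry genealogies that conflict with the species tree, so adding
them to a concatenated supermatrix can *reduce* the support of the resulting
phylogeny. `locusrank` implements a selection procedure that exploits this:

1. estimate an absolute substitution rate for every locus under a strict
   molecular clock on one shared, calibrated constraint tree, so rates are
   comparable across loci;
2. rank loci from slowest to fastest;
3. build concatenated supermatrices of the first $n$ loci for an increasing
   grid of $n$;
4. score each supermatrix by the average bootstrap support of its
   maximum-likelihood tree;
5. select the locus set whose tree attains the maximum average support.

The selected set is always a prefix of the slowest-first ranking.

## Substitution model

All likelihoods use the general time-reversible model with discrete-gamma
among-site rate variation (GTR+$\Gamma$). The instantaneous rate matrix has
off-diagonals $q_{ij} = s_{ij}\,\pi_j$ with six symmetric exchangeabilities
$s_{ij}$ (order AC, AG, AT, CG, CT, GT) and stationary frequencies $\pi$,
and is scaled so that $-\sum_i \pi_i q_{ii} = 1$: branch lengths are
expected substitutions per site. Transition probabilities are computed by
symmetric-similarity eigendecomposition, which is exact for reversible
models. Rate variation uses $k$ equal-probability gamma categories whose
rates are the band means of a mean-one gamma distribution, renormalised to
mean exactly 1; $k = 4$ by default, the de facto standard. Gaps, `N` and
`?` enter the likelihood as fully missing states (all-ones conditional
vectors); IUPAC ambiguity codes contribute their compatible state subset,
so partial information is kept rather than discarded. In the site-pattern
statistics, however, ambiguity codes are counted as undetermined alongside
gaps — the matrix-quality summary deliberately takes the conservative view.

The likelihood itself is Felsenstein pruning over pattern-compressed sites
with per-node rescaling against underflow; equal-weight averaging over the
gamma categories happens in log space. Proportion-of-invariant-sites
models, codon models and model selection are out of scope: the pipeline
fixes the GTR+$\Gamma$ family throughout.

## Per-locus clock rates

Each locus is fitted on the constraint chronogram pruned to the locus's
taxa (`prune_to_taxa()`; pruning preserves all pairwise path lengths, and
the pruned root is the MRCA of the retained taxa, so the time scale is
unchanged). Under a strict clock the expected length of an edge is
$r \cdot \Delta t$, with $\Delta t$ the age difference of its endpoints in
Myr, so the only free parameter is the scalar rate $r$ in
substitutions/site/Myr.

Two numerical points matter here:

* **Node ages are fixed** at the chronogram's values; the package does not
  co-estimate divergence times. Full clock dating would re-estimate node
  ages per locus; fixing them is a deliberate simplification, because the
  selection procedure consumes only the *rank order* of rates, and any
  monotone time scale shared across loci preserves that order.
* The rate likelihood is **flat once every branch is saturated**, so a bare
  golden-section search over the whole rate interval can stall on the
  plateau. The optimiser therefore probes log-spaced rates first and then
  searches only the bracket around the best probe (bounded to
  $[0, 10]$ subs/site/Myr, tolerance $10^{-12}$ on the bracketed search).
  A rate at the lower bound with near-identical sequences is a legitimate
  "effectively zero" estimate and is flagged as converged.

The gamma shape is re-estimated per locus by a grid-then-refine search
(grid $\alpha \in \{0.2, 0.5, 1, 2, 5\}$, then a 1-D refinement on
$\log\alpha$), since loci differ markedly in among-site heterogeneity.

If the constraint tree arrives as a phylogram (branch lengths in
substitutions/site), `calibrate_chronogram()` projects it onto a time scale
by mean-path smoothing — each node's tentative age is the mean root-to-tip
path below it, ages are forced monotone along root-to-tip paths, and the
tree is rescaled so the root sits at the calibration age (the package
default of 108 Ma is a typical family-level crown age for such datasets).
This is not a model-based dating method; it is a monotone projection that
again preserves the rank order the pipeline needs.

Before ranking, loci with *extraordinarily high* rates can be excluded.
The statistical default removes rates above
$\mathrm{median} + 5 \cdot \mathrm{MAD}$ (high side only, with the usual
MAD consistency constant), a deliberately permissive proxy for manual
curation; an explicit-list mode reproduces a curated exclusion exactly.
Ranking breaks ties lexicographically by locus id so results are total
orders, reproducible across runs.

## Tree search and bootstrap scoring

The per-increment supermatrix is scored by `ml_tree_search()` plus
`bootstrap_support()`. The numerical engine behind the search is
**phangorn**'s `pml`/`optim.pml`: a neighbour-joining tree on ML
distances starts a nearest-neighbour-interchange hill climb with
branch-length re-optimisation, GTR+$\Gamma$ parameters estimated by ML on
each increment (a single joint model across partitions — per-partition
models are supported by `log_likelihood()` for likelihood evaluation, but
re-fitting one model per gene inside every bootstrap replicate would
multiply the engine cost roughly by the number of genes while leaving the
support *ranking* unchanged, so curve scoring uses the joint fit).

The bootstrap is nonparametric column resampling at the original length.
Two speedups in the spirit of the "fast bootstrap" options of large-scale
ML programs are used, and both leave the statistic's contract — bipartition
frequencies mapped onto the best tree — untouched:

* model parameters are estimated once on the original alignment and held
  fixed across replicates;
* each replicate's NNI climb starts from the best tree rather than from a
  fresh NJ tree (set `full_search = TRUE` for the classic variant).

Replicate seeds derive from the master seed through `mix_seed()`, a
splitmix-style integer mixer, so any replicate can be regenerated in
isolation and the whole pipeline is byte-deterministic for a fixed seed.

The selection score is the arithmetic mean of the supports on **all**
internal edges of the unrooted best tree, outgroup edges included — the
simplest reproducible definition; restricting the average to ingroup edges
would require an outgroup annotation the procedure otherwise never needs.
Ties in the argmax resolve towards the *smaller* gene count, favouring
parsimony of loci.

For species-tree workflows, `contract_low_support()` collapses internal
edges with support strictly below a threshold (20 is the conventional
cut) into polytomies before the gene trees are handed to a coalescent
summary method; collapsed edges lose their branch length, which such
methods ignore anyway.

## The synthetic-data generator

`simulate_dataset()` generates the structure the analysis assumes, with a
full truth record for validation: a pure-birth (Yule) chronogram rescaled
to a 108-Ma root; slow, clock-like loci with rates log-uniform in
$[5\times10^{-4}, 3\times10^{-3}]$ subs/site/Myr; fast loci in
$[2\times10^{-2}, 10^{-1}]$, half of them on a topology perturbed by two
random NNI swaps (performed directly on the chronogram, rejecting swaps
that would violate node-age monotonicity, so gene trees stay ultrametric
on the same time scale — a cheap stand-in for genealogical conflict that
does not model hybridisation or coalescence); locus lengths uniform in
300–2000 nt; and 5% per-locus taxon dropout, mimicking uneven capture
success. Per-site gamma categories are sampled rather than marginalised,
standard sequence-simulation practice. Default shape is $\alpha = 2$:
moderate heterogeneity typical of trimmed coding alignments, chosen so
that at the fast-class rate floor even the slowest gamma category is fully
randomised over the tree's depth — the fast class must be *genuinely*
saturated for the selection curve's downturn to be attributable to it.
The generator defaults (86 taxa, 300 slow + 50 fast loci) mirror the
scale of a family-level capture study; tests and examples use smaller
instances.

What the generator does **not** emulate: alignment error and indels,
coalescent gene-tree heterogeneity, base-composition heterogeneity among
lineages, and read-level artefacts. Passing the validation suite therefore
shows the procedure behaves correctly under its own model assumptions, not
that it is robust to every pathology of real capture data.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
likelihoods against exhaustive internal-state enumeration on every
topology with up to 5 leaves (relative tolerance $10^{-10}$) and against
an independent GTR+$\Gamma$ implementation; transition probabilities and
two-taxon ML distances against Jukes–Cantor closed forms; discrete-gamma
rates against quadrature; splits and RF distances against naive graph
bisection; Yule node ages against an independent forward sampler.

End-to-end checks run at sizes chosen to exercise the full pipeline in
minutes on one core: rate recovery uses 40 loci of 1000 sites over 20
taxa (Pearson $r \ge 0.9$, median relative error $\le 15\%$); the
selection study uses 30 clock-like + 20 fast loci over 16 taxa, scored at
$n = 5, 10, \ldots, 50$ with 25 bootstrap replicates per increment. At
this taxon count the supermatrices are information-rich, so the support
curve hits 100 on a broad plateau rather than showing the pronounced
decline seen at full study scale; the smaller-$n$ tie rule then correctly
keeps the selection inside the clock-like prefix, the planted
saturated/conflicting loci are excluded, and the selected supermatrix's
ML tree matches the generating topology exactly. Byte-level determinism
is verified by running a reduced pipeline twice with one seed.

## Known limitations

* Strict clock only; a relaxed clock would change absolute rates but, for
  moderate rate autocorrelation, not the slow/fast ranking the selection
  uses.
* NNI-only tree search can be trapped by local optima on adversarial
  topologies; at the desk scales validated here it recovers the
  generating topology reliably, but very large or very unbalanced trees
  deserve an SPR-capable engine.
* The trimmer is a deliberately simplified conserved-block rule set
  (majority-residue conservation, gap allowance, short-run and
  minimum-block rules with flank trimming); it is not a re-implementation
  of any published trimmer's exact output.
* Average bootstrap is a global score: it cannot distinguish *which*
  clades lose support when fast loci enter.
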