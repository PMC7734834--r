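# locusrank

Rate-based locus selection for target-capture phylogenomics.

Target-capture (hybrid enrichment) studies recover hundreds of loci across
tens of taxa, but fast-evolving loci saturate and some carry conflicting
genealogies, so concatenating *everything* can weaken the resulting
phylogeny. `locusrank` implements the selection procedure that addresses
this: estimate an **absolute substitution rate** for every locus under a
strict molecular clock on one calibrated constraint tree, rank loci
**slowest-first**, concatenate them incrementally, score every increment's
supermatrix by the **average bootstrap support** of its maximum-likelihood
tree, and select the locus set maximising that score.

## The method in brief

For locus $g$ on the calibrated chronogram (pruned to the locus's taxa),
the strict clock sets every expected branch length to
$r_g \, \Delta t_e$, with $\Delta t_e$ the age span of edge $e$ in Myr, and

$$\hat r_g = \arg\max_{r \in [0,10]} \; \ln L\big(r \mid \text{alignment}_g,
\text{GTR}+\Gamma\big)$$

in substitutions/site/Myr. Node ages are fixed by the calibration (e.g. a
108-Ma root), so rates are directly comparable across loci. Loci are ranked
by $\hat r_g$ (outlier rates excluded), and for gene counts
$n = \text{start}, \text{start}+\text{step}, \ldots, \text{stop}$ the first
$n$ loci are concatenated and scored by

$$\bar B(n) = \frac{1}{|E_{\text{int}}|} \sum_{e \in E_{\text{int}}} B_e,$$

the mean nonparametric bootstrap support over the internal edges of the
supermatrix's unrooted ML tree (GTR+Γ, NJ start + NNI hill climb). The
selected set is the prefix attaining $\max_n \bar B(n)$, ties resolving to
the smaller $n$.

The package also provides: FASTA/Newick I/O, supermatrix concatenation with
RAxML-style partition tables, distinct-site-pattern and missing-data
statistics, a simplified conserved-block alignment trimmer, low-coverage
locus filtering, bootstrap-support contraction of gene trees for
coalescent species-tree input, Robinson–Foulds distances, gene-recovery
accounting (percent-recovered heatmap matrices), and a fully seeded
multi-locus simulator (known chronogram, per-locus rates, planted
topological conflict, taxon dropout) used to validate every stage.

## Worked example

Simulate a small study — 12 taxa, 8 clock-like loci plus 4 fast loci (two
of them with a deliberately conflicting history) — and run the pipeline:

```r
library(locusrank)

cfg <- simulation_config(n_taxa = 12, n_slow_loci = 8, n_fast_loci = 4,
                         locus_length_range = c(300, 800), seed = 42)
ds  <- simulate_dataset(cfg)
ds
#> <locus_dataset> 12 loci (8 slow, 4 fast, 2 conflicting) over 12 taxa

res <- run_locus_selection(ds$loci, ds$chronogram, start = 2, step = 2,
                           stop = 12, n_bootstrap = 20, seed = 1,
                           outlier_rule = "explicit", model = cfg$model)
res
#> <locus_selection> 12 ranked loci; 0 rate outlier(s) excluded; selected 8 loci (max average bootstrap 100.00)

tidy(res$curve)
#> # A tibble: 6 x 4
#>   n_genes average_bootstrap log_lik selected
#>     <int>             <dbl>   <dbl> <lgl>
#> 1       2              93.9  -2455. FALSE
#> 2       4              98.3  -5329. FALSE
#> 3       6              99.4 -12060. FALSE
#> 4       8             100   -19513. TRUE
#> 5      10             100   -35934. FALSE
#> 6      12             100   -50370. FALSE

head(res$rates[, c("locus_id", "n_taxa", "rate", "log_lik")], 4)
#> # A tibble: 4 x 4
#>   locus_id n_taxa     rate log_lik
#>   <chr>     <int>    <dbl>   <dbl>
#> 1 locus008     12 0.000515  -1518.
#> 2 locus003     11 0.000678   -949.
#> 3 locus002     10 0.000679  -1321.
#> 4 locus006     12 0.000705  -1548.

rf_distance(res$tree, ds$chronogram)
#> [1] 0
```

Reading the output: average support climbs while slow, clock-like loci are
added (93.9 → 100 across 2–8 genes), plateaus once the tree is fully
resolved, and the tie rule selects the smallest maximising set — exactly
the 8 clock-like loci; the fast/conflicting loci are excluded, and the
selected supermatrix's ML tree matches the generating species tree
(RF = 0). `autoplot(res$curve)` draws the gene-count vs average-bootstrap
curve; `res$supermatrix` holds the selected concatenation with its
partition table.

Estimated rates are in substitutions/site/Myr on the chronogram's time
scale (here a 108-Ma root): `locus008` is the slowest gene at
~5.2 × 10⁻⁴, and ranking is invariant to taxon order and alignment column
order.

A thin command-line wrapper over the same functions is provided at
`inst/cli/locusrank.R` (subcommands `simulate`, `filter`, `trim`, `rates`,
`curve`, `select`, `report`).

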