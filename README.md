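# toxmodules

Conserved pathway modules from dose–response toxicogenomics.

Toxicogenomic screens expose a biological system — rat liver in vivo
(RLV), primary rat hepatocytes (PRH), primary human hepatocytes (PHH) — to
a panel of chemicals at several doses and times and profile genome-wide
expression. `toxmodules` asks whether the pathway-level response to
chemical stress is conserved across these settings and across species,
working at the level of a shared pathway namespace so rat and human can be
compared without restricting to orthologous genes.

## The method

For each gene *i* and chemical *j*, a linear dose–time model is fit by
ordinary least squares:

```
G_i = β0 + β1·D_j + β2·T_j + β3·D_j·T_j + ε
```

with `D` the ordinal dose (0 = control … 3 = high) and `T` the treatment
time in hours. Genes are ranked per chemical by the signed significance of
the dose effect, `sign(β1) × −log10(p)` (two-sided Student *t*, df = n − 4).
Each ranked list is scored against the common pathway collection with
preranked GSEA — the weighted running-sum enrichment score, a size-matched
random-set null, and the normalized enrichment score (NES) — giving a
pathway × chemical enrichment matrix per setting. The iterative signature
algorithm (ISA) biclusters each matrix into transcriptional modules
(pathway sets jointly perturbed by chemical sets), with permutation-based
robustness filtering and a 0.5 correlation limit for redundancy. Modules
are matched across settings by pathway overlap with a one-sided
hypergeometric test (α = 0.001) under a reciprocal best-hit rule;
three-way conservation is anchored on the in vivo reference. Hypergeometric
over-representation tests are also provided for chemical classes (e.g.
hepatocarcinogens) within module chemical supports and for leading-edge
gene-list overlaps.

A synthetic-data generator emulates the factorial designs of the three
settings (including per-chemical vehicle controls and missing low-dose
arms), a shared pathway namespace over disjoint species gene universes,
and planted pathway × chemical modules, so the whole pipeline can be
validated end to end against known truth.

## A worked example

```r
library(toxmodules)

cfg <- pipeline_config(sim = demo_config(1L),
                       outdir = "demo_run", rng_seed = 1L)
manifest <- run_pipeline(cfg)
print(manifest)
#> toxmodules run (seed 1): 100 pathways, settings RLV/PRH/PHH
#>   modules: RLV=3, PRH=3, PHH=3
#>   conserved triples: 3

manifest$recovery$triple_recovery_rate
#> [1] 1
print(manifest$recovery$per_module, n = 9)
#> # A tibble: 9 × 5
#>   planted setting best_match jaccard_pathways jaccard_chemicals
#>   <chr>   <chr>   <chr>                 <dbl>             <dbl>
#> 1 truth1  RLV     mod3                  1                 1
#> 2 truth1  PRH     mod1                  0.889             1
#> 3 truth1  PHH     mod1                  0.8               1
#> 4 truth2  RLV     mod2                  0.889             1
#> 5 truth2  PRH     mod3                  1                 1
#> 6 truth2  PHH     mod2                  0.889             1
#> 7 truth3  RLV     mod1                  0.583             0.909
#> 8 truth3  PRH     mod2                  0.889             1
#> 9 truth3  PHH     mod3                  1                 1
```

The demo simulates three experimental settings over 6,000 genes per
species, 100 shared pathways and 60 chemicals, with three planted modules
(8 pathways × 10 chemicals, dose effect two noise-SDs). The run recovers
each planted module in every setting (Jaccard of the best-matching output
module against the planted pathway and chemical supports, shown above) and
links them across settings as conserved triples; `modules_*.json`,
`enrichment_*.tsv`, `matches_*.tsv`, `conserved_triples.json` and a
`manifest.json` with stage timings and output checksums are written under
`outdir`. Fitted objects have `tidy()`/`glance()` methods and
`autoplot()` views (NES heatmap, module size map).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/toxmod.R` (`run-all`, `simulate`, `score-truth` verbs).

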