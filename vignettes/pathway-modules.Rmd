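---
title: "Methods: dose-response pathway modules and their cross-setting conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response pathway modules and their cross-setting conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmodules)
```

## The problem

Toxicogenomic screens such as TG-GATEs expose a biological system — rat
liver in vivo (RLV), primary rat hepatocytes (PRH), primary human
hepatocytes (PHH) — to a panel of chemicals at several doses and times and
profile genome-wide expression. The scientific question is whether the
in vitro systems recapitulate the pathway-level response seen in vivo, and
whether that response is conserved between rat and human. Comparing at the
gene level is hampered by incomplete orthology; `toxmodules` instead works
at the pathway level, where a shared pathway namespace lets species be
compared directly while each species keeps its own gene memberships.

The pipeline has four modelling stages, each exposed as ordinary functions
over data frames and matrices:

1. **Gene–chemical association.** For each gene *i* and chemical *j*, an
   ordinary least squares fit of
   $G_i = \beta_0 + \beta_1 D_j + \beta_2 T_j + \beta_3 D_j T_j + \varepsilon$
   where $D$ is the dose and $T$ the treatment time. The dose coefficient
   $\beta_1$ carries the association; its two-sided Student *t* p-value
   (df = *n* − 4) and sign define the ranking score
   $\mathrm{sign}(\beta_1)\times(-\log_{10} p)$.
2. **Preranked GSEA.** Each chemical's ranked gene list is scored against
   the common pathway collection with the weighted running-sum enrichment
   statistic; a size-matched random-set null yields the normalized
   enrichment score (NES) and nominal p, and the leading-edge genes are
   recorded. Stacking chemicals gives a pathway × chemical NES matrix per
   setting.
3. **ISA biclustering.** The iterative signature algorithm extracts
   modules — pathway sets jointly perturbed by chemical sets — from each
   enrichment matrix, over a grid of row/column thresholds, with
   permutation-based robustness filtering and correlation-based
   deduplication (limit 0.5).
4. **Conservation.** Modules from two settings are matched by pathway
   overlap with a one-sided hypergeometric test on the common pathway
   universe and a reciprocal best-hit rule (α = 0.001); three-way
   conservation is anchored on the in vivo reference (RLV), which the
   field treats as the gold standard.

## Modelling choices and their rationale

**Dose coding.** Dose enters the linear model as the ordinal coding
0 (control), 1 (low), 2 (middle), 3 (high). Absolute dose magnitudes differ
by orders of magnitude across chemicals while each model is fit within one
chemical, so an ordinal coding preserves the monotone-dose contract without
per-chemical rescaling. The synthetic generator uses the identical coding —
generator and fitting model must agree for planted effects to be
recoverable at face value. Controls enter as dose 0; without them the dose
effect would be unidentified from treated samples alone. Time is in hours
as measured (2/8/24 in vitro; 3/6/9/24 in vivo).

**Significance and ranking.** The *t* test on $\beta_1$ is two-sided; the
direction is carried separately by the sign in the ranking score. P-values
are floored at 1e−300 before the log so scores stay finite. A fit with zero
residual and zero $\beta_1$ (a flat profile) is scored 0 by convention.
Ties in the ranking are broken by gene id so ranked lists are
deterministic. No gene-level multiple-testing correction is applied — the
scores feed a rank-based method, where only the ordering matters.

**Enrichment statistic.** The weighted statistic (weight = 1) with 1,000
permutations mirrors the defaults of the classical GSEA implementation.
Walking the ranked list, hits add $|s|^w / \sum_{hits} |s|^w$ and misses
subtract $1/(N - N_{hit})$; the ES is the extremum of the running sum
(earliest position on ties), which always returns to zero at the end of
the list. The only coherent null for an externally ranked list is the
gene-set permutation: random sets of identical size. NES divides the ES by
the mean absolute same-sign null ES; the nominal p uses add-one smoothing
so it is never zero. Pathways with fewer than 15 genes in the ranked
universe (aligned with the collection size filter of [15, 500], bounds
inclusive) are masked rather than dropped, and masked cells are imputed as
0 — "no enrichment" — so the biclustering input is complete; the mask is
retained alongside. Null distributions are shared across pathways of equal
overlap size and seeded by size, so results are independent of pathway and
chemical processing order.

**ISA variant.** The enrichment matrix is standardized twice (rows and
columns; zero-variance slices are zeroed and flagged). Row scores are the
column-standardized matrix times the column scores, thresholded at
mean + thr × SD of the absolute scores with sign retained — modules may
mix up- and down-regulated pathways, as mixed-sign response blocks do occur
in this kind of data. Convergence requires Pearson correlation ≥ 0.99
between successive score vectors in both dimensions *and* exactly stable
supports, so every returned module is a fixed point of one further
iteration. Seeds are sparse binary column vectors (2 nonzero entries),
100 per threshold pair, over the grid {1.5, 2, 2.5, 3} × {1.5, 2, 2.5, 3}
by default; all of this is configuration. Robustness is
$\sqrt{|r^\top E_c c|}$ on unit-norm score vectors.

Two pieces deserve emphasis because the algorithm family leaves them open:

- *Robustness filtering.* The same sweep (same seeds, same thresholds) is
  repeated on a within-column permuted copy of the matrix, which destroys
  row-coherent structure while preserving each column's value
  distribution. A bicluster is kept only if its robustness exceeds 1.1
  times the best robustness seen on the permuted matrix at the same
  threshold pair. Without this filter, heavy-tailed noise yields dozens of
  small chance signatures per run; with it, pure-noise input produces
  essentially none while planted modules (amplitude ≥ 3 noise SDs) pass
  with a wide margin. The 1.1 safety factor guards against the
  permuted-sweep maximum being an underestimate of the chance-robustness
  tail.
- *Deduplication.* Greedy, in decreasing robustness: a candidate is kept
  if its correlation with every kept module — the larger of the absolute
  Pearson correlations of full-length row and column score vectors — stays
  below the 0.5 limit.

**Conservation.** Matching uses pathway overlap only. Chemical overlap is
reported for context but not required: chemicals driving a conserved
pathway response need not coincide across systems (metabolic bioactivation
differs between liver and cultured hepatocytes), and requiring it would
conflate two distinct questions. The universe for the hypergeometric test
is the common size-filtered pathway collection. Best-hit ties break toward
larger overlap, then smaller module id, for determinism. Raw α thresholds
(0.001 for matches, 0.05 for chemical-class enrichment) are used without
multiple-testing correction, matching standard practice for this design;
both are configuration keys.

## What the synthetic generator emulates — and what it does not

The generator reproduces the structural features the analysis relies on:
the three factorial designs (PHH/PRH: 3 doses × {2, 8, 24} h × 2
replicates + controls; RLV: 3 doses × {3, 6, 9, 24} h × 3 replicates +
controls), per-chemical vehicle controls, a configurable fraction of
chemicals missing their low-dose arm (PHH only, as in the incomplete human
arm), a shared pathway namespace over disjoint species gene universes, and
ground-truth modules planted as dose effects ($\beta_1 = \pm$ effect size)
on the member genes of module pathways under module chemicals. Intercepts
are Normal(7, 1) per gene (log-intensity-like), time slopes
Normal(0, 0.1²) — the 0.1 SD reads the nominal Normal(0, 0.01) as a
variance — the interaction defaults to 0, and noise is i.i.d. Gaussian.
Per-pathway effect signs are Rademacher unless specified, so enrichment
matrices contain both directions.

It does **not** emulate probe-level structure, array artifacts, batch
effects, correlated noise between genes, dose-response nonlinearity, or
partial/graded module membership. Passing recovery tests therefore shows
that the pipeline's stages compose correctly and are calibrated under the
stated model — not that real arrays meet these assumptions.

**Demo dimensions.** The bundled demo (`demo_config()`) uses 6,000 genes
per species, 100 pathways of 15–25 genes, 60 chemicals and three planted
modules of 8 pathways × 10 chemicals at effect 2 noise-SDs, simulated for
all three settings. These sizes keep the chemically responsive genome
sparse (~3% of genes per chemical, as in real exposures) and each module a
modest fraction of both universes. Denser configurations are
scientifically misleading: if a quarter of the genome responds to every
module chemical, background pathways become genuinely enriched through
membership leakage, the permutation null inflates, and NES contrast
collapses — a property of the *data*, not of the method. The demo
completes in roughly two minutes on one core.

## Numerical conventions

- OLS via the QR decomposition of the fixed design matrix, vectorized over
  genes; rank deficiency raises an error naming the collinear columns.
- Zero-residual fits are detected at relative tolerance 1e−16·*n*; an
  exactly reproduced effect gets the p floor, a flat profile the null
  convention.
- ES peak ties resolve to the earliest position within a 1e−9 slack, so
  exact rational ties (which occur structurally, e.g. between the trough
  before the first hit and the crest after the last) are not resolved by
  floating-point accumulation order; batched null ES values
  are computed from hit positions only (the running sum attains extrema
  only at or just before hits) and agree with the full walk to 1e−12.
- NES is undefined when no same-sign null values exist; such cells are
  masked, never thrown.
- All randomness flows from one integer seed through labelled 32-bit
  substreams (stage, setting, chemical, set size), so repeated runs are
  byte-identical and independent of scheduling order.

## Limitations

Nominal GSEA p-values are not corrected across pathways (downstream
biclustering consumes NES, not p). The ISA variant documents its own
normalization and filtering precisely but does not claim bit-compatibility
with other implementations of the family. Conservation anchored on RLV
does not additionally require the two in vitro settings to match each
other; with identical module sets the two rules coincide, and the
RLV-anchored form mirrors how in vitro settings are judged against the in
vivo reference. Real-data headline counts (numbers of modules per setting
and conserved triples) depend on full-scale accessions and curated pathway
snapshots, and are out of scope here; the package validates mechanism,
calibration and recovery on synthetic truth instead.
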