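---
title: "Percentile-rank GPCR profiling: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile-rank GPCR profiling: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrome)
```

## The problem

Microglia — the brain's resident macrophage-like cells — carry a
characteristic surface repertoire of G-protein-coupled receptors (GPCRs):
homeostatic marker genes such as *CX3CR1*, *GPR34*, *GPR183*, *P2RY12*,
*P2RY13*, and *ADGRG1* (GPR56). Which receptors a microglial cell robustly
transcribes, how that differs between white matter (WM) and grey matter
(GM), and how the repertoire collapses in disease-associated subpopulations
(e.g. in active multiple-sclerosis lesions, where homeostatic markers fall
and the chemokine receptor *CXCR4* rises) are questions usually answered by
comparing heterogeneous public bulk and single-cell RNA-seq datasets that
differ in units (FPKM, TPM, counts), depth, and species.

`gpcrome` packages the analysis style used for such cross-dataset receptor
surveys as reusable, tested components:

1. **Percentile profiling** — rank each gene against the whole
   transcriptome of its own dataset, making datasets with different units
   comparable.
2. **Tier classification** — discretize percentiles into
   below-cutoff / low / medium / high expression bands.
3. **Consensus derivation** — intersect tiers across datasets to get a
   core receptor set, with a regional *rescue* rule for WM-enriched genes.
4. **Differential analysis** — paired WM-vs-GM fold-change screening with
   exact nonparametric tests.
5. **Single-cell contrasts** — cluster-level marker summaries and
   disease-vs-homeostatic contrasts on cluster-labeled count matrices.
6. **Synthetic data** — generators that plant known percentiles, regional
   effects, and marker shifts, so every claim above is testable offline.

## The percentile statistic

For a dataset with $N$ genes, gene $g$ receives the midrank $R_g$ of its
expression among all $N$ genes and the percentile $p_g = R_g / N$. Tied
values share their midrank, the top gene sits at exactly $p = 1$, and the
mean percentile is always $(N+1)/2N$. Because the statistic is a rank, it is
invariant under any strictly increasing transform of the expression values —
this is what makes FPKM, TPM, and count matrices comparable after
profiling.

Two aggregation orders are provided because the choice is genuinely open
when a dataset has several samples:

* `mean_then_rank` (default): average expression across samples, rank the
  means once. Less sensitive to sample-level noise; this is the default on
  the reading that published dataset-level profiles are rank summaries of
  mean expression.
* `rank_then_mean`: rank within each sample, average the per-sample
  percentiles. Useful when samples are too heterogeneous to average raw
  values.

The denominator $N$ deliberately counts every gene in the matrix, including
zero-expression rows; users who want a detected-genes background should
pre-filter before profiling.

### Tiers

The published tier bands are printed to two decimals (0.5–0.67,
0.68–0.85, 0.86–1.0). We treat the one-hundredth gaps as rounding of
continuous boundaries and implement half-open intervals on unrounded
percentiles:

| tier | interval |
|---|---|
| below_cutoff | $(0, 0.50)$ |
| low | $[0.50, 0.68)$ |
| medium | $[0.68, 0.86)$ |
| high | $[0.86, 1]$ |

All three boundaries are parameters of `tier_scheme()`; the defaults above
are used everywhere unless overridden.

## Consensus core set and the rescue rule

A catalog receptor gene is a consensus member when it reaches `min_tier`
(default `medium`) in at least `ceiling(min_fraction * D)` of the $D$
profiled datasets (default `min_fraction = 1`, i.e. unanimity). The phrase
"abundantly expressed across datasets" fixes neither the tier nor the
fraction, so both are explicit configuration echoed into every output
rather than hidden constants.

The **rescue rule** reflects the regional biology: a gene with `medium`
tier in the designated grey-matter profile but `high` tier in the
white-matter profile is flagged `rescued` and included. Rescue is
restricted to one designated (GM, WM) profile pair — not any pair — because
the construction is specifically about WM enrichment. A gene already `high`
in GM is not "rescued"; its membership flows from the main rule. Note that
under the default `min_tier = medium` a GM-medium/WM-high gene may satisfy
the main rule too; the `rescued` flag is still informative as the audit
trail of *why* the gene belongs to the core set.

## Exact nonparametric tests

Small-donor comparisons in this field are analyzed with Wilcoxon
signed-rank (paired) and Mann-Whitney U (unpaired) tests. Published work
rarely states the software conventions, so this package fixes them
explicitly:

* **Zero differences** are dropped before ranking (the classical Wilcoxon
  convention); all-zero input is not an error but a degenerate result with
  $p = 1$.
* **Ties** receive midranks everywhere.
* **Exactness**: the signed-rank null distribution is enumerated over all
  $2^n$ sign assignments for $n \le 12$ effective pairs; the Mann-Whitney
  null over all $\binom{n+m}{n}$ labelings when $n, m \le 8$ and no tied
  value spans the two groups. The limits keep enumeration well under a
  second; beyond them a normal approximation with continuity and tie
  correction is used, and the `method` field of the result always says
  which path ran.
* **Two-sidedness**: twice the smaller tail probability, capped at 1.

Because the exact distributions are discrete, the realized type-I error at
$\alpha = 0.05$ is conservative (the test suite checks $\le 6\%$ rejection
over 2000 null simulations).

Multiple testing across a gene panel uses Benjamini–Hochberg step-up
q-values (via `stats::p.adjust`). The regional $\ge$2-fold direction call
is intentionally *not* gated on q — effect-size screening and inference
are reported side by side, mirroring how fold-change-based gene calls are
made in the source literature. One caveat documented here because it is
easy to assert and false: BH adjustment is not idempotent on arbitrary
already-adjusted vectors; only flat (tied) adjusted outputs are fixed
points.

## Regional differential analysis

`region_differential()` computes per-gene region means, the log2 fold
change with a shared pseudocount (half the smallest nonzero region mean in
the analysis), and a direction call at the `fc_threshold` (default 2).
Paired mode (per-donor WM−GM differences into the signed-rank test) is
selected automatically when every donor has exactly one sample per region;
it can be forced or disabled, and forcing it on unmatched donors is an
error that names the offending donors. Tests require at least 4 pairs —
below that, p-values are reported as `NA` rather than pretending power
exists.

## Single-cell conventions

The single-cell module takes cluster labels and embeddings as *inputs*
(computing t-SNE/UMAP or clustering is out of scope — those are upstream
choices we do not want to silently re-make). Counts are normalized per cell
to a fixed library size of 10,000 followed by `log1p`, a standard
depth-invariant transform chosen because the upstream normalization of
published datasets is typically unstated. Contrasts run at the cell level
(Mann-Whitney across cells, BH over the panel, direction by fold change of
cluster means at `fc_threshold = 1.5` and `alpha = 0.05`): public lesion
datasets rarely carry enough donors per cluster for pseudobulk inference,
and this limitation is deliberate and documented — cell-level p-values
treat cells as independent and are optimistic for donor-level claims.

## What the generators emulate (and what they do not)

`simulate_bulk()` draws background gene means from a heavy-tailed
log-normal (`meanlog = 1`, `sdlog = 1.5`, similar in shape to FPKM/TPM
distributions) and inserts planted genes *between* the background order
statistics bracketing the target rank, so the planted percentile is exact
by construction in the noise-free case. `noise_sd` (default 0.05) is one
multiplicative log-normal factor per sample — library-size jitter. A
common per-sample factor rescales all genes alike, so dataset-level ranks
are preserved; this is exactly the property that makes percentile
profiling attractive on real data, where between-sample scaling dominates
technical variation. Gene-level biological variability is modeled where it
drives inference: `simulate_paired_regions()` gives each donor a per-gene
log-normal baseline (`donor_sd = 0.3`) shared between that donor's WM and
GM samples, on top of which planted WM/GM fold effects act.

`simulate_single_cell()` draws negative-binomial counts (dispersion
`size = 2`) with per-cell log-normal depth factors (`sdlog = 0.3`), cluster
proportions mirroring a lesion dataset (75% homeostatic, 10%
disease-associated, 10% monocytes, 5% lymphocytes; 1602 cells by default),
and planted marker shifts on cluster means. The pseudo-embedding is
cluster-separated Gaussian blobs — a clearly synthetic stand-in for a real
t-SNE, sufficient for testing overlay plumbing.

The generators do **not** emulate: gene–gene correlation, batch and
platform effects, gene-length or GC bias, ambient RNA, doublets, or donor
imbalance between datasets. Passing the planted-recovery tests therefore
demonstrates that the pipeline's logic is correct and calibrated under its
stated assumptions, not that real datasets will separate as cleanly.

### The shipped mirror scenario

`inst/extdata/mirror_scenario.yaml` defines the narrative fixture used by
the end-to-end tests: five bulk datasets (four GM, one WM; 2000 genes × 8
samples each), 15 core receptor genes planted high (targets 0.87–0.99)
everywhere, 2 WM-enriched genes (*CXCR4*, *PTGER4*) planted medium
(0.70/0.80) in GM datasets and high in the WM dataset, and every other
catalog receptor planted at or below percentile 0.60 — strictly below the
medium boundary with a ≥ 0.05 margin. Under the default consensus
configuration the derived core set is exactly the 17 planted genes with the
two regional genes flagged rescued. The single-cell component shifts the
six homeostatic markers down 4-fold and *CXCR4* up 3-fold in the 10%
disease cluster. The 15th high-unanimous gene is *FPR1*; the identity of
that gene is a fixture convention covering the human-enriched receptors,
not a biological claim.

## Numerical choices and degenerate inputs

* Pseudocounts default to half the smallest nonzero value in scope (matrix,
  mean pair, or panel), so `(0, 0)` fold changes are 0 by symmetry and the
  choice scales with the data's dynamic range.
* Planting at a target whose rank slot falls inside a tie block of the
  background is an error (infeasible), as is planting two genes into the
  same rank slot.
* Single-gene matrices cannot be profiled (no background); all-zero
  matrices have no relative intensity; empty clusters and all-zero cells
  are errors or exclusions with warnings, as documented per function.
* Duplicate gene rows collapse by sum on read (multi-transcript
  collapsing), with a warning counting collapsed rows.
* All generator output is reproducible from integer seeds;
  `derive_seed()` spreads one master seed across scenario streams without
  exceeding the 32-bit range. Text outputs are written with fixed `%.6g`
  formatting, LF endings, so identical inputs give byte-identical files.

## Problem sizes used by the checks

The test suite and the acceptance script exercise: 200 random matrices up
to 1000 genes against an $O(N^2)$ rank oracle; 500 random instances per
exact test against enumeration oracles; 2000 null simulations per test for
size calibration; 100 seeded planting-recovery runs at 1000 genes; 3 full
mirror-scenario runs; 200 paired-region recovery runs at 500 genes and 6
donors; and 100 seeded single-cell recovery runs at 1602 cells × 300
genes. These sizes give tight Monte-Carlo tolerances while keeping a full
run in the tens of seconds on a single core.

## Known limitations

* The shipped catalog is a frozen snapshot sufficient for the genes
  discussed in the microglia GPCRome literature plus padding across all
  five GRAFS families; it is not a complete IUPHAR export, and family
  counts are metadata, not an oracle.
* Ortholog mapping is symbol-based with an explicit exception table; it
  does not consult ortholog databases and cannot resolve one-to-many
  homology.
* Cell-level contrast p-values are optimistic for donor-level inference
  (see above).
* The consensus rule treats datasets as exchangeable votes; there is no
  weighting by depth, sample count, or quality.
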