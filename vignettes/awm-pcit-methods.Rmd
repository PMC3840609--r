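---
title: "From multi-trait GWAS to gene co-association networks: methods and design"
author: "growthnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-trait GWAS to gene co-association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthnet)
```

# The problem

A single-trait, single-SNP GWAS ranks markers one trait at a time. When a
study measures a complex target trait (here: body growth at the onset of
puberty in an F2 cattle cross) *together* with a panel of intermediate
phenotypes (serum metabolites), much of the interesting biology lives in how
additive SNP effects co-vary across that phenotype panel: genes whose allele
substitutions push the same set of traits in correlated directions plausibly
sit in shared regulatory pathways. This package implements the analysis chain
that extracts this structure:

1. **Mixed-model GWAS** per trait and SNP, with a pedigree-based polygenic
   term, giving an additive effect and a likelihood-ratio p-value per
   (SNP, trait) cell.
2. **Association Weight Matrix (AWM)**: a gene-by-trait matrix of
   column-standardized additive effects, with rows admitted by a cascade of
   selection rules anchored on a small set of *key* phenotypes and a larger
   set of *supportive* phenotypes.
3. **PCIT** (partial correlation and information theory): a data-driven
   significance filter on the pairwise correlations of AWM row profiles,
   followed by a magnitude filter |r| >= 0.80, yielding an undirected gene
   co-association network.
4. **Network analysis**: column-permutation null networks, a
   metabolite-only network and its overlap with the full network, hub
   (connectivity) tables, ego subnetworks and MCODE dense clusters, and a
   binomial over-representation test against a reference gene list.

Because the original cattle data were never deposited, the package ships a
first-class synthetic-data module whose ground truth (planted pleiotropic
gene modules) is known, so that every downstream stage is testable.

# The mixed model

For each trait $y$ and SNP $k$ the model is

$$ y_i = \mathbf{x}_i'\boldsymbol\beta + Z_{ik} g_k + u_i + e_{ik}, $$

with genotype coding $Z \in \{-1, 0, +1\}$ (minor-allele count minus one),
polygenic effects $\mathbf{u} \sim N(0, \mathbf{A}\sigma_u^2)$ where
$\mathbf{A}$ is the numerator relationship matrix from the pedigree (tabular
method; equal to twice the kinship matrix), and residuals
$\mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2)$. Weight-like traits carry one
categorical fixed effect (birth year); metabolite-like traits carry two
(sampling year, measurement day).

**Estimation.** The variance components are estimated once per trait under
the null (no SNP term) by REML: one eigendecomposition
$\mathbf{A} = \mathbf{U}\mathbf{D}\mathbf{U}'$ rotates the model so the
covariance is diagonal in $\lambda = \sigma_u^2/\sigma_e^2$, and the REML
criterion is maximized over $\lambda$ by a coarse grid followed by Brent
search on the log scale (interval $e^{-12}$–$e^{12}$, boundary
$\lambda \to 0$ checked explicitly). Each SNP then enters as a fixed GLS
covariate with the variance components held at the null fit — the standard
single-fit approximation used by EMMAX-type software — and the test
statistic is twice the profile log-likelihood difference at those fixed
components, referred to $\chi^2_1$. An exact per-SNP REML refit is available
behind `exact_reml = TRUE`; at the package's default scale the two agree
closely, and the approximation is orders of magnitude faster. Missing
genotypes are mean-imputed per SNP at the association stage only; a SNP
monomorphic among the analysed animals is reported as `effect = NA, p = 1`
rather than an error.

The calibration of this machinery is itself a test: under a pure-null
simulation (150 F2, 500 SNPs, $h^2 = 0.3$, ten trait replicates) the
fraction of $p \le 0.05$ must fall in $[0.035, 0.065]$ and the
Kolmogorov–Smirnov distance from uniformity below 0.05.

# The AWM cascade

All tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `p_thresh` | 0.05 | nominal per-cell significance, inclusive (`<=`) |
| `max_dist` | 2500 bp | maximal SNP-to-gene distance (span boundary, inclusive) |
| `comparator` | `>=` | supportive-count admission rule vs `A_P` |
| `round_ap` | FALSE | compare against unrounded `A_P` |
| `pc_threshold` | 0.80 | edge filter on profile correlation magnitude |
| `n_random` | 10 | column-permuted replicate networks |

The cascade: standardize every effect column (mean 0, sample SD 1, over
*all* SNPs in the grid, before any selection); admit SNPs significant for at
least one key trait; compute `A_P`, the mean number of supportive traits the
key-selected SNPs are associated with; admit additionally every SNP whose
supportive count reaches `A_P`; discard SNPs farther than 2500 bp from the
nearest annotated gene; and where several SNPs map to one gene keep the SNP
with the most trait associations, ties broken by lower mean p, then genomic
position, then SNP id. Variants that the chip does not carry (the original
study had to add its two known causal mutations by hand) can be injected as
ordinary grid rows with `inject_custom_snps()`; they re-enter
standardization and every later rule unchanged.

Two readings of the admission rule are defensible ("at least `A_P`" vs
"more than `A_P`"); both are implemented, `>=` is the default, and the same
choice applies to the metabolite-only network, which reuses the full
analysis's `A_P` after dropping the key-trait columns.

# PCIT

For genes $x, y$ the edge-carrying quantity is the Pearson correlation
$r_{xy}$ of their AWM row profiles. For every trio $(x, y, z)$ the three
first-order partials, e.g.

$$ r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}, $$

are computed, and the trio's tolerance $\varepsilon$ is the average ratio of
partial to direct correlation (ratios with $|r| < 10^{-12}$ in the
denominator are dropped; a trio with no valid ratio is skipped). The trio
*explains away* the pair $(x,y)$ when
$|r_{xy\cdot z}| < |\varepsilon\, r_{xz\cdot y}|$ **and**
$|r_{xy\cdot z}| < |\varepsilon\, r_{yz\cdot x}|$ — the pair's
conditional association is dominated by the partials linking each endpoint
to the conditioner. A pair is declared non-significant only when *every*
evaluated conditioner explains it away. This comparison is carried out on
the partial correlations: it is the reading under which the canonical
worked cases behave correctly (a pair fully explained by a common
conditioner, $r_{xy} = r_{xz} r_{yz}$, is removed; an equicorrelated clique
survives in full; an uncorrelated conditioner can never remove a pair), and
it matches the verbal description of the method as comparing the PCs of a
pair against the PCs of each endpoint with every other gene. Edges are then
the PCIT-significant pairs with $|r_{xy}| \ge 0.80$ (inclusive); the sign is
kept as metadata and ignored for topology.

Two implementations exist: a pure-R triple loop (the normative reference)
and a compiled scan that mirrors it expression for expression; the suite
requires exact (not approximate) agreement of their edge sets on randomized
inputs. Degenerate inputs are defined, not special-cased away: fewer than
three genes means no trio evidence (all nonzero pairs significant, with a
warning), and a pair with $r = 0$ is never significant.

# Network analysis

*Gene counts* report nodes with at least one edge. *Random validation*
column-permutes the AWM (each trait column independently, labels fixed —
preserving every column's value multiset exactly) and re-runs PCIT and the
edge filter; replicate seeds are `master_seed + replicate`. *Ego
subnetworks* are full induced subgraphs (the query gene, its partners, and
all edges among them, including partner–partner edges). *MCODE* is
implemented with its published defaults (degree cutoff 2, node score cutoff
0.2, 2-core requirement, haircut on, fluff off, depth 100): vertex weight is
the density of the highest k-core of the closed neighbourhood times that
core's $k$; complexes grow breadth-first from the highest-weight unvisited
seed, admitting neighbours with weight $\ge$ seed weight $\times (1 -$ node
score cutoff$)$; the cluster score is density $\times$ size. Note the
direction of the cutoff: *raising* `node_score_cutoff` loosens the
admission bound and can only grow clusters — the property suite pins this
monotonicity down. *Enrichment* is a one-sided exact binomial upper tail
per term with Bonferroni correction over terms; genes without annotation
are excluded from both the list and reference totals (the convention of the
popular over-representation services), and the annotation content is always
user-supplied — no ontology data are bundled.

# The synthetic study and what it does (not) show

`sim_config()` defaults describe the desk-scale study the acceptance
analysis runs on:

* **Design**: 8 + 8 founders in two pools, 20 F1, 150 male F2 in full-sib
  families; five 100-cM chromosomes with 200 SNPs each at 0.5-cM spacing
  (1 cM taken as 1 Mb); genes of ±1 kb planted on every other SNP, so half
  the markers map at distance 0 and half exercise the >2500-bp discard path.
* **Divergent line cross**: pool-A allele-1 frequencies are drawn from
  U(0.02, 0.15) and pool B takes the mirror `1 - p`. The two breeds are
  therefore near-fixed for alternative alleles with consistent phase, which
  is what gives a real F2 resource population its long-range, phase-coherent
  LD; gene-drop uses Haldane (no-interference) recombination. Setting
  `founder_divergent = FALSE` breaks the mirroring and yields an
  (approximately) LD-free population — the right null for p-value
  calibration studies.
* **Traits**: 2 key weight traits and 11 supportive metabolites in four
  residual-correlation blocks (within-block correlation 0.6), polygenic
  variance 0.35 and residual variance 0.65 per trait. Heritabilities are a
  configuration choice, not an empirical claim; the defaults sit in the
  moderate range typical for growth and serum-metabolite traits.
* **Planted modules**: three modules of ten genes, one per chromosome 1–3,
  members spaced ~8 cM apart across the middle 70% of the chromosome — a
  major-QTL region in LD, in the spirit of the large growth loci that
  motivated such studies. Every trait receives an effect of 0.3 SD whose
  sign is constant within a trait block; the three module sign patterns over
  the four blocks are near-orthogonal, so cross-module effect profiles are
  weakly correlated while within-block genetic covariance stays positive.
  The key weight block gets 1.5x that effect, reflecting that such modules
  are ascertained through the growth phenotype in the first place.
  Within-module gene pairs are the ground-truth edges.

The end-to-end acceptance property is that at default thresholds at least
80% of within-module pairs appear as network edges while at most 5% of
cross-module pairs do, and that ten column-permuted replicates produce
fewer than a fifth of the structured network's edges with a strictly smaller
maximum degree. The generator intentionally does **not** emulate
mass-spectrometry noise models, genotyping-cluster artefacts, real bovine
LD maps, or selection/ascertainment of the marker panel — passing tests
demonstrate that the pipeline recovers planted co-association structure
under a faithful genetic design, not that any particular biological network
is correct.

# Numerical choices and degenerate inputs

* Genotype coding ties (allele frequency exactly 0.5) count the
  alphabetically first allele, making PLINK write-then-read an identity.
* The minor-allele flip is determined over observed (non-missing) genotypes;
  planted effects are phased on the pool-B-enriched allele, so the recorded
  ground-truth effect signs follow the flip.
* REML: eigenvalues clipped at 0; the profiled criterion keeps the
  `log det(X'X)`-free convention, verified against a dense multivariate
  normal oracle at n = 8 to 1e-8.
* PCIT guards divisions at 1e-12 and requires exact IEEE agreement between
  the reference and compiled paths, so the comparison order is kept
  identical in both.
* Zero residual variance is allowed in the simulator (the zero-variance
  limit collapses phenotypes onto their fixed-effect shifts), and
  `p_thresh = 0` propagates an informative empty-selection error out of the
  AWM stage.
* All writers sort their output; a fixed master seed reproduces a run
  directory byte for byte.

# Problem sizes

The default test and acceptance scenarios were sized for a laptop-class
single core: the full pipeline run (150 F2 x 1,000 SNPs x 13 traits,
PCIT over ~300 genes, 10 random networks) takes a few seconds; the
calibration study (5,000 tests), the 100-replicate effect-recovery and
heritability studies, and the 100-matrix PCIT equivalence sweep each finish
within a minute. These sizes are the package's default study conditions, and
all reported numbers in the README were produced by these code paths.

# Known limitations

* The per-SNP test reuses null variance components (see above); with very
  strong single loci the exact-REML flag is the conservative cross-check.
* PCIT is the only edge-significance rule offered (no FDR-style
  alternative), and only first-order partials are considered.
* The one-gene-one-SNP rule keeps a single marker per gene even when a gene
  plausibly carries several independent signals.
* Enrichment implements the binomial test only; no ontology graph
  propagation or term clustering.
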