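---
title: "Methods: models and design choices in nachrevo"
author: "nachrevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in nachrevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nachrevo)
```

# Overview

`nachrevo` analyses the contrasting evolutionary trajectories of neuronal
(α4β2, α7) and hair-cell (α9α10) nicotinic acetylcholine receptors on three
coupled levels:

1. **Coding sequences** — pairwise percent identity, neighbor-joining
   distance trees, marginal maximum-likelihood ancestral sequences, and a
   type-II functional divergence estimator with per-site posteriors.
2. **Single-cell coexpression** — an error model for scRNA-seq counts
   (negative binomial plus a dropout Poisson), posterior distributions of
   mean expression per cell type, and a pentamer-assembly fold-range
   repertoire classifier.
3. **Receptor function** — Hill dose-response fits, a max-normalized PCA of
   five biophysical properties across nine receptors (3 subtypes × 3
   species), concatemer trees with 1−SeqID branch lengths, Brownian-motion
   ancestral trait estimation, and projection of inferred ancestral
   receptors into the extant PCA plane.

Every stochastic stage has a matching synthetic-data generator
(`simulateCladeAlignment()`, `simulateCounts()`, `simulateBMTraits()`) that
records its ground truth, so each estimator is validated by recovery
simulations rather than by fiat.

# Sequence stage

## Percent identity and trees

Identity between two aligned sequences is the fraction of matching columns
among comparable columns; `-` and `X` are missing. *Pairwise deletion*
(default) drops missing columns per pair; *complete deletion* drops any
column with a gap anywhere. Pairs without comparable columns are flagged
`NA` rather than scored 0, and tree building refuses such matrices rather
than guessing. Distances are `1 − seqID` (p-distance) or the Poisson
multiple-hit correction `−ln(1 − p)`; trees come from neighbor joining
(`ape::nj`), with tiny negative NJ branch lengths clamped to zero. On
additive matrices NJ is exact, which the test suite checks to `1e-9`.

## Ancestral sequence reconstruction

`ancestralSequencesML()` computes per-site marginal posteriors over the 20
amino acids at every internal node by Felsenstein pruning plus a preorder
pass that propagates evidence from the rest of the tree. Two reversible
models are provided, both scaled to one expected substitution per site per
unit branch length: a Poisson model (equal exchangeabilities, uniform
frequencies) whose likelihoods are cheap to verify by brute-force
enumeration, and a JTT model (empirical exchangeabilities and
frequencies). Discrete-gamma rate variation (4 categories) is optional and
off by default so that the default likelihood remains brute-force
verifiable. Reconstruction is at the amino-acid level because every
downstream consumer (1−SeqID branch lengths, property-group comparisons)
operates on amino acids; nucleotide-level reconstruction under
Tamura–Nei-type models is deliberately out of scope. Ties in the argmax
state break by fixed alphabet order; downstream analyses consume the
posteriors, not the argmax.

Degenerate input is handled explicitly: an all-zero-length tree with
conflicting tip states has no defined ancestral distribution and errors.

## Type-II divergence

A site shows *type-II divergence* between two clades when it is conserved
within each clade but occupies different biochemical property groups
between them (e.g. acidic in mammals, basic in sauropsids). The default
partition is charge-first: {D,E}, {K,R,H}, {S,T,N,Q,C,G,P,Y},
{A,V,L,I,M,F,W}; it is configurable via a TSV
(`inst/extdata/property_groups.tsv`).

Per site, each clade's ancestral residue posterior is reconstructed at the
root of its subtree. Sites are *candidates* (conserved within both clades,
ancestral groups differ), *conserved-agreeing* (identical residue, or
different residues in the same group), or *variable*; sites with less than
95% coverage (configurable) or fewer than two informative residues in
either clade are excluded.

The estimator is a two-component mixture over all classifiable sites. A
genuinely type-II site displays the candidate pattern by definition, so its
pattern probability is fixed at 1 — with a binary per-site record the
product θ·π₁ is the only identifiable quantity, and fixing π₁ = 1 resolves
that cleanly. A background site displays the candidate pattern only if
neutral between-clade substitutions happened to cross property groups while
both clades stayed conserved. Its probability π₀ is calibrated from a
quantity that cannot be contaminated by type-II sites: conserved sites
whose clade-ancestral residues differ *within* a property group. Under the
uniform-target Poisson model the expected ratio of cross-group to
within-group ancestral differences depends only on the partition
(`274/106 ≈ 2.59` for the default groups), so the expected number of
background candidates is that ratio times the observed within-group
differences. This self-calibration was chosen over plugging the tree's
between-clade path length into the Poisson formula, because any
data-derived tree's between-clade path absorbs the divergence signal
itself, which would systematically inflate π₀ and bias θ downward at high
divergence. θ is the candidate excess over that background, clipped to
[0, 1]; its standard error comes from the multinomial information, giving
`z = θ/SE` and a one-sided p-value. θ is a fraction of *all* classifiable
sites, matching the usual definition of the divergence coefficient.
Per-site posteriors multiply the mixture posterior for candidates by the
site's ancestral cross-group probability; thresholding them (e.g. at 0.65)
flags individual divergent sites.

Recovery simulations (500 sites, 6+6 taxa) show |bias| well below 0.1
across divergence fractions 0–0.5, null z-scores essentially never exceed
1.64, and truth sites rank above background sites with AUROC ≈ 1.

# Single-cell stage

## Error model

Counts are modelled per observation as a weighted mixture of a negative
binomial (mean `m_g · s_c`, size `r`) for amplified transcripts and a
low-magnitude Poisson (`λ₀ = 0.1`) for dropouts; the dropout weight is a
decreasing logistic in `log10 m` with midpoint and slope parameters,
because dropout frequency is governed by expression level. Size factors
`s_c` default to library-size factors normalized by their geometric mean —
a deliberate simplification of pooled-deconvolution normalization, kept
honest by truth-recovery tests (Spearman ρ > 0.95 against simulated truth
at 200 cells). The EM fit alternates dropout responsibilities (E-step)
with refits of the logistic curve, the NB size (one safeguarded Newton step
per iteration on the weighted score), and the gene means (weighted ratio
estimator, the Poisson-ML form that is consistent for the NB mean); it
stops when the largest change in (midpoint, slope, log r) falls below
`1e-4`, or returns the last iterate with a warning after 100 iterations.
One curve and one `r` are shared by all cells of a type; the fitted object
stores per-cell rows so the interface extends to per-cell curves.

## Posterior expression and the repertoire classifier

Per gene and cell type, the posterior over mean expression is the
normalized product of mixture likelihoods on a 400-point log10 grid from
10⁻² to 10⁴ under a uniform-in-log prior (the prior of the original error
model is unpublished; uniform-in-log is the symmetric default on this
scale). Posterior means feed the classifier: an assembly is *absent* when
any required subunit's posterior mean is at or below the detection floor
(default 0.1, a declared free parameter); otherwise the fold ratio max/min
over the assembly's *distinct* subunits (stoichiometry copies do not weight
it, and the reference is the extreme ratio rather than the top subunit —
both points where the fold-range rule admits readings; the alternatives
change nothing in the test grid) maps to within-10, within-100,
within-1000, or absent. The classifier is scale-invariant and monotone
under threshold widening, which the suite checks on an enumerated grid
including the exact boundary ratios.

# Functional stage

## Profiles and PCA

The profile matrix holds 9 receptors × 5 properties: ACh EC50 (µM),
desensitization (% current remaining at 20 s, 5 s for α7 — taken as
printed, no rescaling), Ca²⁺ modulation (I at 0.5 mM / 3 mM Ca²⁺), Ca²⁺
permeability (% current after BAPTA-AM), and rectification (I₊₄₀/I₋₉₀).
α4β2 has two dose-response components; the high-sensitivity EC50 enters
the matrix by default, consistent with using the high-sensitivity
(α4)₂(β2)₃ stoichiometry for its concatemer (the low-sensitivity flag is
exposed, and shifts the PC1+PC2 total by about a point). Each column is
divided by its maximum — max-normalization is the stated equal-weighting
device — then centered; PCA is on the covariance of the normalized columns
(correlation is a flag; both land near 82% cumulative variance for
PC1+PC2). Projection of supplementary (ancestral) profiles applies the
extant normalization constants and centers before multiplying by the
loadings, so an extant profile projects exactly onto its own scores and
the column-mean profile to the origin.

## Concatemer trees and ancestral traits

Receptor-level trees use the fixed tetrapod topology
`((rat,chick)amniote,frog)tetrapod` with branch lengths `1 − fractional
identity` between the concatemer sequences at the edge endpoints
(subunits repeated per stoichiometry — (α9)₂(α10)₃, (α4)₂(β2)₃ — in fixed
order; fractional, not percentage, units keep lengths in [0, 1]). Ancestral
node sequences come from `ancestralSequencesML()`; computing edge lengths
against reconstructed ancestors is the package's reading of assigning
branch lengths from sequence identity, with least-squares fitting of tip
identities left as an alternative.

Ancestral trait values are estimated under Brownian motion by GLS: the
root is the generalized least-squares mean under the phylogenetic
covariance, σ² its ML estimate (REML flag available), and internal nodes
the conditional Gaussian expectations — convex combinations of tips, hence
always inside the tip range. 95% CIs use the conditional variance plus the
root-estimate uncertainty at the plug-in σ²; with three tips this behaves
like a t₂ interval (≈80% empirical coverage), which the suite documents
rather than hides. The packaged demonstration tree
(`tetrapod_tree_synthetic.nwk`) is a synthetic stand-in with plausible
1−SeqID-scale branch lengths, used when no receptor-specific concatemer
tree is supplied.

# Synthetic-data generators

The generators define the reference study conditions used by the tests:

* **Alignments** — two clades of 6 taxa, 500 sites; a recorded
  `propType2` fraction of sites is fixed for residues from different
  property groups per clade (conserved within clades); background sites
  share a base residue and mutate independently at 0.02 per taxon,
  giving within-clade identities in the mid-90s, typical of conserved
  receptor subunits. Truth sites are exactly the sites satisfying the
  type-II predicate when the background rate is zero.
* **Counts** — NB size 2, dropout midpoint 0.5 (log10 scale), slope 1.5,
  dropout Poisson mean 0.1, log-normal(0, 0.25) size factors, 200 cells
  per type; these sit in the range reported for droplet-scale scRNA-seq.
* **Traits** — Brownian motion with σ² = 1 from a configurable root state;
  internal-node values retained.

Each generator reseeds deterministically from `SimConfig@seed` with a fixed
per-stage offset (alignment 0, counts 1, traits 2), so stages are
bit-reproducible both standalone and inside the pipeline regardless of
execution order. What the generators do **not** emulate: codon-level
evolution, indels, rate variation along the sequence, doublets and ambient
RNA, and batch structure. Passing recovery tests therefore demonstrates
estimator correctness under the stated model, not robustness to every
artefact of real data.

# Pipeline

`runPipeline()` validates its YAML/list configuration before any compute
(missing input files are config errors), runs the enabled stages in
dependency order, and writes a JSON manifest with package version, seed,
parameters and MD5 checksums of all outputs; a re-run with the same
configuration reproduces the checksums, and disabling one stage leaves the
others' outputs byte-identical. Problem sizes in the bundled demo
configuration (60 genes × 2 types, 500-site alignments) are chosen so a
full run completes in seconds while exercising every stage.

# Known limitations

* The type-II mixture is a documented stand-in for the original
  divergence software's unpublished likelihood; θ, z and the site
  posteriors are comparable in role but not numerically identical to that
  tool's output.
* The error model shares one dropout curve per cell type rather than one
  per cell, and fixes λ₀ instead of estimating it.
* Library-size factors ignore composition effects that pooled
  deconvolution absorbs.
* BM ancestral CIs use plug-in σ²; with few tips they undercover
  (documented above).
* The repertoire classifier bounds the assembly repertoire from mRNA
  coexpression only; assembly, trafficking and chaperone effects are out
  of scope.
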