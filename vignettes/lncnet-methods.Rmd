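---
title: "lncnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

`lncnet` implements the stages of an integrative lncRNA–mRNA analysis for
small case–control RNA-seq cohorts. This vignette documents the models
behind each stage, the parameters that matter and their defaults, the
numerical conventions for degenerate inputs, and the choices we made where
the analysis convention leaves room — together with what the synthetic
benchmark does and does not establish about real data.

## The synthetic cohort generator

Every pipeline stage is testable because `sim_config()` +
`simulate_expression()` generate a cohort with known ground truth. The
generative model is deliberately the simplest one that produces the
statistical features the analysis relies on:

* **Abundance.** Per-gene baseline log₂ FPKM is drawn from
  N(`baseline_log2_mean` = 4, `baseline_log2_sd` = 1) — a bulk RNA-seq
  mid-expression regime — and per-sample values add N(0, `noise_sd`)
  noise on the log₂ scale, i.e. abundances are log-normal.
* **Differential expression.** A fraction `de_fraction` (default 0.2) of
  genes receives a ± `log2fc_effect` shift (default 2, a 4-fold effect)
  in the case group. The cohort default is `n_per_group = 6` sequenced
  samples per arm, with 12 vs 12 for the qPCR validation table,
  mirroring the usual design split between discovery and validation.
* **Coexpression modules.** Genes of a module share one latent factor
  per sample: gene g in module k has
  z = √ρ·f + √(1−ρ)·ε, so any two members have expected Pearson
  correlation ρ (= the module's target `r`, default 0.9). lncRNA
  members take the negative loading when `r < 0`. A module's members
  are lncRNAs and mRNAs in equal parts and are DE in one common
  direction, since the network stage only sees DE genes.
* **Genomic placement.** One single-exon transcript per gene; members
  of a planted cis pair land on one chromosome with a span gap drawn
  below the 300 kb window, and every other pair of neighbours is
  separated by window + 10 kb, so the planted cis set is exactly the
  within-window set.
* **Sequences and duplexes.** Transcript sequences are uniform random
  A/C/G/T; each planted duplex pair carries an exact
  reverse-complementary stretch of `complement_len` nt (default 25 —
  long enough that even an all-A/T stretch reaches the −50 energy
  cutoff at A·T = −2 per pair, since 25 × 2 = 50).
* **qRT-PCR.** Three technical replicates per well
  (`replicate_sd` = 0.15 cycles), a near-constant reference gene, a
  between-sample biological SD of 0.8 ΔCt cycles, and case-group ΔCt
  shifts equal to the planted log₂ effects. With a 2-cycle shift this
  yields strong but imperfect markers, which is the regime single-digit
  AUC comparisons need.

All generators take one explicit integer seed and restore the caller's
RNG state; identical configurations produce byte-identical TSV/GTF/FASTA
outputs, which the test suite asserts.

**What the generator does not emulate.** Library-size and GC biases,
count-level sampling noise (mean–variance dispersion), multi-exon
structure, batch effects, and read-level artefacts. Passing the planted
recovery tests therefore shows the *algorithms* behave as specified under
their own assumptions; it does not certify performance on real RNA-seq,
where the DE test's normality assumption and the correlation thresholds
interact with dispersion and outliers.

One property of the homogeneous-effect design deserves emphasis: when all
DE genes shift by the same |log₂ FC| = 2 with `noise_sd` = 0.3, *any* two
DE genes correlate at |r| ≈ 0.9 across the pooled 12 samples, because the
group indicator dominates both profiles. On such data, an all-DE
coexpression network is nearly complete and no clustering method can
single out the planted modules. Module-recovery tests therefore run on
shift-free (`de_fraction = 0`) module networks, where coexpression
reflects the planted latent factors alone. Real cohorts have
heterogeneous effect sizes, so their DE–DE correlations are far more
graded.

## Differential expression

The published convention this implements filters genes at
*fold change ≥ 2 and p < 0.05*. Count-model inference (dispersion
estimation à la DESeq) is out of scope at this package's scale; the test
statistic is a Welch *t* on log₂(x + 1), with the fold change computed on
the natural scale as (mean_case + ε)/(mean_control + ε), ε = 1 FPKM. The
pseudo-abundance keeps low-expression ratios finite and damps
fold-change explosions near zero. "Fold change ≥ fc" is two-sided: ratio
≥ fc or ≤ 1/fc. The test interface is a plain per-gene table, so a
count-model test can be swapped in upstream of the same thresholds.

Degenerate conventions: a gene whose two groups have zero variance gets
p = 1 when the means are equal (an exact tie) and p = 0 otherwise (exact
replication at different levels). No multiple-testing correction is
applied by default because the convention filters on raw p; `adjust =
"BH"` is available. Under the global null the rejection rate of the test
at α = 0.05 is checked by simulation (20 seeds × 200 genes) and must lie
in [0.03, 0.07].

QC follows the usual recipes: sample–sample Pearson on log₂(x + 1), PCA
as the SVD of the gene-centred matrix (scores ordered by singular value;
each component's sign fixed so its largest-magnitude loading is
positive — a deterministic orientation), and average-linkage hierarchical
clustering on 1 − r distance via `stats::hclust`, whose tie-break is the
smallest item index.

## Coexpression network and MCL

Edges are all DE-lncRNA × DE-mRNA pairs with |r| ≥ 0.8 and p < 0.05 (t
distribution on n − 2 df). We use |r| because both correlation signs are
biologically meaningful for lncRNA regulation; `positive_only = TRUE`
restores the r ≥ 0.8 reading. Zero-variance genes are excluded with a
warning rather than an error: a constant profile carries no correlation
information but should not abort a batch run. The top-k selection
(default 500) sorts by p ascending, |r| descending, then both ids — a
total order, so the output is independent of the input permutation.

`mcl()` is a from-scratch Markov clustering: the |r|-weighted adjacency
matrix gains self-loops of weight equal to each node's maximum incident
|r| (the standard guard against period-2 oscillation), is column
normalised, and is iterated through expansion (matrix power, default 2),
inflation (entrywise power 2.0, column renormalised) and pruning (entries
< 10⁻⁵ zeroed, renormalised) until the largest entry change falls below
10⁻⁸ or 100 iterations. These are the canonical MCL defaults; inflation
is the granularity dial. Clusters are the connected components of the
limit matrix's support; when attractor systems overlap, a node follows
the attractor holding its largest steady-state mass, ties to the lowest
cluster index. Column sums stay 1 within 10⁻¹² at every step (asserted in
tests), disconnected components never merge, and two 5-cliques joined by
a single 0.8 bridge split into two clusters at inflation 2.

A structural caveat: on a *strictly bipartite* graph (only lnc–mRNA
edges), even-step MCL flow connects same-side nodes through many 2-paths
while the two sides communicate only via self-loops, so inflation drives
a complete bipartite module toward its two sides. This is a property of
the algorithm, not a bug; on real networks edge-weight heterogeneity
breaks the symmetry. It is why exact module recovery is asserted on the
full (all-pairs) coexpression graph, with a weaker no-module-mixing
assertion on the bipartite network.

## Cis and trans target inference

*Cis*: genes on the same chromosome whose transcript span lies within
300 kb of the lncRNA's span, inclusive at exactly 300,000 bp. Distance is
the gap between spans (0 for overlap) rather than TSS-to-TSS: the
window is described as "upstream or downstream" without an anchor, and
span gap is the symmetric, strand-agnostic reading. Requiring
coexpression is optional (`require_coexpr`), since the cis convention
admits pairs coexpressed in either direction.

*Trans*: a pair must satisfy coexpression (|r| > 0.8, p < 0.05), a
duplex with ≥ 10 paired bases, and duplex energy ≤ −50, and must not be a
cis pair. The published energy threshold is quoted as a magnitude
("no more than 50"); since binding free energies are negative we read it
as energy ≤ −50 in the scorer's units, and the cutoff is a parameter with
the sign convention documented here.

The duplex scorer replaces a thermodynamic hybridisation tool with an
additive model chosen to be exactly testable: pair energies G·C −3,
A·T −2, G·U wobble −1, mismatch +4; a reportable stretch must contain a
seed of ≥ 6 consecutive exact Watson–Crick pairs; the stretch is the
minimum-energy window containing a seed on its antiparallel ungapped
diagonal. The search computes, per diagonal, prefix-maximum and
suffix-minimum cuts around every seed, which returns the *global*
optimum — a greedy extend-while-improving scan can stall at a local
plateau (e.g. a +4 mismatch followed by two −3 pairs) and would not match
the exhaustive all-substring-pair oracle the tests run on sequences
≤ 40 nt. Ties in energy prefer the longer stretch. `paired_bases` counts
non-mismatch positions, so internal mismatches are tolerated only when
the flanks more than repay them. The scorer sits behind a plain
function interface so an external-tool adapter can replace it.

## Enrichment

For a query of n annotated genes in an annotated background of N, a term
with M background members and m query members scores fold enrichment
(m/n)/(M/N) and p = P(X ≥ m), X ~ Hypergeometric(N, M, n), via
`stats::phyper` (log-space internally); m = 0 returns exactly 1. The
universe is annotated genes only — genes in no set are excluded from both
N and n, per the convention that un-annotated genes are uninformative.
Raw p is reported (the convention this follows tabulates raw p);
Benjamini–Hochberg is available by flag. The printed formula for the
score in our source material is garbled ("mn/Mn"); the variable
definitions given alongside it support (m/n)/(M/N), which is what we
implement.

## qRT-PCR and ROC validation

2^−ΔΔCt: technical replicates are averaged (arithmetic mean of Ct; the
convention is silent, and Ct is already a log-scale quantity), ΔCt =
Ct_target − Ct_reference per sample, ΔΔCt subtracts the calibrator-group
mean ΔCt, relative expression is 2^−ΔΔCt. The healthy-control mean is
the assumed calibrator, the natural choice when the contrast is patients
vs controls. A constant Ct offset across all wells cancels exactly
(asserted as a property test).

AUC uses the Mann–Whitney U with ties counted ½, divided by n₁n₀ — the
probability a random case outranks a random control — and equals the
brute-force enumeration over all case × control pairs (asserted for all
random fixtures up to 10 + 10). Scores are auto-oriented so AUC ≥ 0.5
with the orientation recorded.

The combined two-marker ROC fits a binomial logistic model by IRLS
(internally; 50 iterations, tolerance 10⁻¹⁰, features standardised) and
takes the ROC of the linear predictor — the standard way to pool two
markers into one score when the combination rule is unspecified. The
scorer is pluggable. Constant markers are dropped (a logistic model
cannot use them, and the AUC of the remaining marker is unchanged by any
monotone rescaling); under perfect separation the likelihood has no
maximiser, so the fit falls back to the better single marker and flags
`separated = TRUE`. Because the combiner is linear, a jointly-but-not-
marginally separating (XOR-like) pair can legitimately score near 0.5;
tests assert only the orientation bound there, and validate the fit
against the bivariate-normal closed form AUC = Φ(δ) for two independent
unit-variance markers shifted by δ.

## Clinical statistics

Summaries are mean ± sample SD (n − 1), rounded only for presentation.
The two-sample t defaults to Student's pooled-variance variant — the
convention named by the analyses this mirrors — with Welch available;
both accept (n, mean, SD) summaries, because published tables often give
only the control arm as a summary. Both variances zero with equal means
returns t = 0, p = 1 by convention. Whether a published table pooled
variances is usually unstated; exposing both variants is the honest
option, and they agree exactly when group sizes and variances are equal.

## Problem sizes and determinism

The bundled end-to-end configuration (`inst/extdata/toy_config.yaml`)
runs 200 genes × 12 samples with two planted modules, four cis and four
duplex pairs — sizes chosen so a full pipeline run takes seconds while
every stage still has non-trivial input. The recovery and calibration
studies in the tests and the acceptance script use 120–200 genes over
10–20 seeds, which puts Monte-Carlo error well inside the asserted
bands. Re-running any configuration reproduces byte-identical outputs;
the manifest records an md5 per file and a configuration hash.

## Known limitations

* The DE stand-in ignores count dispersion; at very low abundance the
  log₂(x + 1) transform compresses fold changes (an exact 2× gene at
  mean 10 FPKM has ε-fold change 21/11 < 2 and is *not* called — the
  threshold is on the stabilised ratio, deliberately).
* The duplex scorer is not thermodynamic: no nearest-neighbour stacking,
  bulges or loops; its energies are comparable only to its own cutoff.
* The coding-potential stub is ORF length alone; it mimics the
  *consensus logic* of multi-tool pipelines, not the tools' accuracy.
* Bipartite MCL side-splitting (above) means cluster counts on
  lnc × mRNA networks should be read per connected component.
* Enrichment assumes the annotation (GMT) defines the universe; results
  are only as current as the supplied gene sets.
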