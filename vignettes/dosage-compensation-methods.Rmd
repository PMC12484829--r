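---
title: "Methods: allele-resolved dosage-compensation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-resolved dosage-compensation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelicomp)
library(tibble)
```

## The scientific problem

In hybrid (Mus × Cast) mouse pluripotent stem cells, expression can be
assigned to parental alleles through strain-specific SNPs. This makes gene
dosage directly observable: a biallelic XX cell expresses a gene from two X
copies, an XO or XY cell from one. X-chromosome upregulation (XCU) is the
compensation response — cells with a single active X upregulate it so that
X-linked output approaches the diploid autosomal level. The same logic
extends to heterozygous segmental deletions (one allele of a region lost)
and to autosomal cis-silencing (one allele of a region switched off):
in both cases the question is whether the remaining allele is upregulated
*in trans*.

`allelicomp` implements the downstream analysis of such experiments,
starting from allele-split count matrices:

* per-sample TPM normalization that preserves allelic imbalance,
* genotype sensing and QC from allelic expression alone,
* XCU gene calling against a *half-of-biallelic* null,
* copy-number-corrected region-wise compensation reports,
* protein-level compensation and RNA–protein concordance,
* allele-resolved ChIP coverage quantification (promoters, gene bodies,
  scale-regions metaprofiles),
* a synthetic-data generator with ground truth, used by every recovery
  test in the package.

## The core model and its null hypotheses

**Joint TPM.** Counts are scaled per sample by a single factor across both
alleles so that the grand total is $10^6$. Scaling each allele to $10^6$
separately would erase monosomy: the defining signal — elevated per-allele
expression when only one allele is active — only survives joint scaling.
Within-gene allelic fractions are invariant under this normalization. UMI
counts get no length correction (they count molecules); read-based bulk
counts are first converted to rates per kb of gene length.

**The half-of-XX null.** For gene $g$, let $m_{gc}$ be the active-allele
TPM in monosomic cell $c$ and $x_{gc}$ the total allelic TPM in biallelic
cell $c$. Without compensation a single active copy produces half the
biallelic output, so the null is
$E[m_g] = E[x_g]/2$. The caller runs a two-sided Welch $t$-test of
$\{m_{gc}\}$ against $\{x_{gc}/2\}$ and gates the call on fold change:
upregulated $\iff p < \alpha$ and $\mathrm{FC} > 1.2$. The fold-change
gate makes the two-sided test effectively directional and strictly
conservative under the null. The per-cell formulation (rather than a test
on genotype means of means) matches how single-cell monosomy experiments
are summarised, one observation per cell.

**Copy-number correction.** Bulk and protein data lack (or under-use)
allelic resolution, so values are divided by the gene's total copy number
in each genotype — 2 for autosomes and biallelic X, 1 inside a monosomy or
heterozygous deletion. Compensation then appears as a copy-corrected
XO/XX (or Del/XX) fold change above 1; full compensation reaches 2.

**X:A ratio.** Per cell and allele: the trimmed mean of X-linked TPM
divided by the median autosomal TPM *on the same allele* (the same trim is
applied to the autosomal set before its median). Allele matching is a
deliberate design choice; it is the only convention under which the
per-allele X:A of an XX cell equals that of a monosomic cell without
upregulation, which is exactly the comparison the statistic exists to
make. Whether the autosomal set should be trimmed before taking the median
is ambiguous in the field; we trim for symmetry — for the 10/90 trim this
leaves the median unchanged, so the choice is inert at the defaults.

**Percentile convention.** All trims use linear interpolation between
order statistics (R's `quantile` type 7) with *inclusive* bounds
($q_{low} \le v \le q_{high}$). Inclusivity maximizes retained genes in
sparse cells, and fixing the interpolation rule keeps every documented
worked example stable. Defaults: 10th–90th percentile for single-cell
gene-set means, 5th–95th for bulk autosomal summaries.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_umis` | 10 000 | UMIs/allele | cell QC; strict "less than" removal |
| X-status `threshold` | 2 | TPM | mean allelic X expression cut |
| pluripotency `log2_threshold` | 2.5 | log2 TPM | per-marker (Esrrb, Nanog, Pou5f1) gate |
| `expressed_min_tpm` | 5 | TPM | bulk expressed-gene filter (reference samples) |
| `fc_threshold` | 1.2 | ratio | upregulation gate |
| `alpha` | 0.05 | — | significance level |
| `clip_bounds` | (−1, 4) | log2 | visualization-only clipping |
| `min_region_genes` | 10 | genes | region tests abstain below this |
| silencing threshold | 0.15 | ratio | cis-silenced call (+dox/−dox) |
| trans threshold | 0.5 | log2 | trans-upregulation call (see below) |
| protein XX filter | 1.2e7 | LFQ units | X:A detection-bias guard |
| metaprofile | 100/3000/1500 | bp | bin, scaled body, flank |

The trans-upregulation threshold deserves a note: a *linear* fold change
greater than 0.5 is nearly vacuous (any non-crashing gene passes), so the
package defaults to log2FC > 0.5 and exposes the literal linear rule as
`mode = "linear"`. Both are documented rather than silently guessing the
intent.

Two spots where the upstream procedure is not fully specified are
implemented as documented stand-ins: deletion-boundary inference (running
mean of allelic fractions, window 10 genes, run length ≥ 5 below fraction
0.1 — tolerant of single-gene dropout in sparse cells) and silenced-region
detection (10 Mb windows, 1 Mb step, ≥ 5 silenced genes per window, with
telomere extension and a configurable fixed-region fallback).

## Statistical primitives

Pairwise genotype contrasts use Tukey's HSD with the Tukey–Kramer
correction:
$q_{ij} = |\bar y_i - \bar y_j| / \sqrt{(\mathrm{MSW}/2)(1/n_i + 1/n_j)}$
referred to the studentized-range distribution with $k$ groups and $N-k$
df. At $k=2$ this reduces exactly to the pooled two-sided $t$-test
($q = t\sqrt 2$), which the tests assert to $10^{-6}$, and at $k=3$ it is
cross-checked against a 100 000-permutation max-$q$ oracle and against
`TukeyHSD(aov(...))`. Region contrasts between genotypes use two-sided
paired $t$-tests over per-gene means with Bonferroni correction over the
pairs; ChIP timepoint contrasts use paired $t$ with Benjamini–Hochberg
over the family of marks submitted together (the family is an explicit
input, since implicit families are irreproducible). Proportion
comparisons between gene sets use Pearson's chi-square without continuity
correction (the corrected variant is a flag). Degenerate inputs follow
fixed conventions: all-zero paired differences give $p = 1$ (no evidence
of difference), zero within-group variance with unequal means gives the
0-limit, and a 2×2 table whose annotation margin is empty is reported as
statistic 0 rather than an error when it arises from a set-proportion
comparison (identical proportions by construction).

## What the generator emulates

`simulate_allelic_counts()` draws negative-binomial counts
($\mathrm{Var} = \mu + \alpha\mu^2$; $\alpha = 0.3$ for single-cell UMI
data, $0.05$ for bulk) around log-normal per-gene base means, with:

* **genotypes as copy profiles** — XX, both XO directions, XY, and
  arbitrary heterozygous deletions are per-allele copy intervals;
* **compensation as mean scaling** — a fraction $\pi_u$ (default 0.4) of
  genes is designated compensated; wherever such a gene is monoallelically
  expressed (deletion, monosomy, or cis-silencing of the other allele)
  its remaining allele's mean gains the factor $u$ (default 2). The
  analysis only observes means, so burst-kinetics modelling is
  deliberately out of scope;
* **mapping bias** — allele-1 (Mus) means carry a factor $b = 1.05$,
  mirroring the slight reference bias of hybrid alignments;
* **fixed per-cell budget** — expected depth (default $4\times10^5$
  UMIs/cell, CV 0.2) is identical across genotypes, so monosomy
  manifests as redistribution after TPM scaling exactly as in real data;
* **realistic X share** — the default plan places 400 X-linked genes
  among 8 000, so X transcripts are ~5% of the budget and the TPM
  redistribution artifact stays at its realistic small size;
* **cis-silencing** — dox genotypes multiply the targeted allele of genes
  in the configured region by the residual 0.1.

The expectation behind the X:A recovery check follows directly: the
active-allele X:A in monosomy over the per-allele X:A in XX is
$1 + \pi_u(u-1)$ (1.4 at defaults). Trimming biases this slightly
downward (doubling a random 40% of genes reshuffles the trimmed set);
numerically the trimmed statistic sits near 1.35, comfortably within the
±10% recovery band.

Matched proteins are a scaled copy of each gene's total expected RNA
output with log-normal replicate noise; `protein_noise_sigma` is the SD of
**log2** abundance (default 0.3 ≈ 23% CV, typical of DIA label-free
quantification — log2 is the working scale of that field, and the
differential test runs on log2 values). A fraction `pi_protein_only`
(default 0.35) of non-RNA-compensated genes gains the factor $u$ at the
protein level only, creating the RNA-only/protein-only/both/neither
concordance structure. At these settings the per-gene power of the
both-contrast Tukey rule is ≈ 0.70–0.75 — the protein recovery bound is
intentionally tight. Coverage tracks are a constant background (0.5) plus
per-promoter signal proportional to the allele's expected expression with
zero-truncated Gaussian noise.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: transcriptional bursting, doublets and
ambient RNA, batch effects, length-biased bulk counts (simulated bulk
counts are UMI-like, so the pipeline normalizes them with `umi_tpm`),
peptide-level missingness structure in proteomics, and fragment-level
ChIP artifacts. Recovery results certify the *analysis logic*, not the
upstream measurement process.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED convention);
  GFF3 is converted at the I/O boundary and the conversion is involutive.
* Matrix TSVs are written with `%.17g` and parsed with base `strtod`,
  so write → read round-trips are bit-exact, and pipeline artifacts are
  byte-identical under identical config + seed (`rlang::hash` of the
  config is embedded in every report).
* Unassigned reads are carried but excluded from allelic statistics and,
  by default, from the TPM denominator (a flag includes them; the right
  choice depends on upstream SNP density, which the package cannot know).
* Region membership is decided by the TSS (unambiguous for
  boundary-straddling genes); promoters extend biologically upstream
  (genomically rightward for minus-strand genes) and are clipped at
  chromosome bounds.
* Metaprofile bodies are rescaled by evaluating base-weighted means over
  equal fractions of the actual body — linear rescaling of the stepwise
  signal at the contract level, not a bit-level emulation of any
  particular external tool. Genes shorter than one bin are skipped with a
  warning rather than zero-filled.
* Ambiguous X-status calls are flagged and excluded downstream, never
  guessed; XY is only distinguishable from XO via sample metadata, and
  the classifier does not pretend otherwise.

## Problem sizes used in the shipped checks

The package's acceptance checks run the generator at the sizes the study
design prescribes: 200 cells per genotype for genotype sensing; 400
X-linked genes with 60 XX + 40 XO cells for the null-calibration and
recovery checks; 8 bulk replicates per genotype for the deletion
compensation pattern; 20 random deletion configurations for boundary
recovery; 3 proteomic replicates per genotype at noise SD 0.3; 50 genes
per set for the ChIP contrast. These sizes were chosen once, as the
smallest designs at which the corresponding statistics are stable.

## Known limitations

* The half-of-XX test assumes the biallelic reference and monosomic cells
  share library-quality characteristics; strong depth confounding between
  genotypes would bias fold changes (the TPM redistribution effect is
  ~3–5% at realistic X shares and is absorbed by the FC gate).
* Deletion-boundary inference reports gene-resolution boundaries; sub-gene
  breakpoints are out of scope.
* `classify_x_status` cannot separate XY from XO without metadata.
* The concordance classifier's default raw fold-change rule (FC > 1) is
  deliberately lenient; the significance-based rule is available and the
  two disagree for genes near the boundary — both are reported rather
  than merged.
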