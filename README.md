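# allelicomp

Allele-resolved analysis of gene dosage compensation in hybrid mouse
pluripotent stem cells.

When expression can be split by parental allele (Mus × Cast hybrids with
strain-specific SNPs), gene dosage becomes directly observable: a
biallelic XX cell expresses each X-linked gene from two copies, an XO or
XY cell from one. X-chromosome upregulation (XCU) — and its analogue for
heterozygous segmental deletions and autosomal cis-silencing — is the
compensatory increase on the remaining active allele *in trans*.
`allelicomp` implements the downstream statistics of such experiments for
transcriptome (single-cell and bulk), proteome and ChIP coverage data,
plus a ground-truthed synthetic-data generator that every recovery test
in the package runs against.

## The core statistic

For gene *g*, with active-allele TPM *m* in monosomic cells and total
allelic TPM *x* in biallelic cells, the no-compensation null is
E[m] = E[x]/2. A gene is called upregulated when a two-sided Welch
t-test of {m} against {x/2} gives p < 0.05 **and** the fold change
mean(m) / mean(x/2) exceeds 1.2. Around this sit:

* joint per-sample TPM scaling across both alleles (separate scaling
  would erase monosomy signal),
* allele-matched X:autosome ratios on 10/90-trimmed means,
* copy-number correction (value ÷ copies) for bulk and protein data,
* Tukey HSD (Tukey–Kramer), paired t + Bonferroni, BH, and chi-square
  primitives for group, region and proportion contrasts,
* scale-regions metaprofiles and promoter/gene-body means for
  allele-resolved ChIP tracks.

## Worked example

Simulate the default monosomy experiment (8 000 genes, 400 X-linked,
60 XX + 40 X<sup>Cast</sup>O<sup>Mus</sup> cells, upregulation factor
u = 2 on a compensated fraction π<sub>u</sub> = 0.4), then run QC and
the XCU caller:

```r
library(allelicomp)

cfg  <- simulation_config(seed = 42)
sim  <- simulate_allelic_counts(cfg)
tpm  <- normalize_expression(sim$matrix, "umi_tpm")

qc_report(sim$matrix, sim$annotation)
#> # A tibble: 3 x 6   (first rows)
#>   sample_id total_allele1 total_allele2 pass_umi_filter x_status     pluripotent
#>   <chr>             <dbl>         <dbl> <lgl>           <chr>        <lgl>
#> 1 XX_s001          194005        187958 TRUE            biallelic_XX TRUE
#> 2 XX_s002          196291        182139 TRUE            biallelic_XX TRUE
#> 3 XX_s003          186365        176702 TRUE            biallelic_XX TRUE

calls <- call_xcu_from_experiment(tpm, sim$sample_table, sim$annotation)
glance(calls)
#> # A tibble: 1 x 3
#>   n_genes n_upregulated fraction_upregulated
#> 1     400           154                0.385
```

38.5% of the 400 X-linked genes are called upregulated — close to the
simulated compensated fraction of 40%. Against the generator's ground truth
this run recovers the compensated set with sensitivity 1.000 and
precision 0.974, and the Cast-allele X:A ratio rises from 1.356 in XX
cells to 1.783 in XO cells (a 1.31-fold increase; the mean-scaling
expectation is 1 + π<sub>u</sub>(u − 1) = 1.4, shaded slightly downward
by trimming). `autoplot(calls)` draws the volcano view;
`tidy(calls)` returns the per-gene table:

```r
tidy(calls)[order(-tidy(calls)$fold_change), ][1:3, c(1, 4:6)]
#>   gene_id    fold_change      p_value upregulated
#> 1 chrX_g0268        2.49 0.000000126  TRUE
#> 2 chrX_g0225        2.48 0.0000000912 TRUE
#> 3 chrX_g0227        2.48 0.000000590  TRUE
```

The full stage sequence (simulate → qc → xcu → region-report →
autosomal → protein → chip → report) is orchestrated by
`run_pipeline()`, which writes deterministic TSV/JSON artifacts; a thin
command-line wrapper lives at `inst/scripts/allelicomp-pipeline.R`.

## Package layout

* `R/` — I/O and the `allelic_matrix` container; the synthetic-data
  generator; QC/genotype sensing; dosage statistics; compensation
  calling; proteomics integration; ChIP quantification; pipeline.
* `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
* `vignettes/dosage-compensation-methods.Rmd` — the model, parameter
  defaults and their rationale, generator scope, numerical conventions,
  and known limitations.
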