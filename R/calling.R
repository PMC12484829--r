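#' Call X-upregulated (XCU) genes against the half-of-biallelic null
#'
#' For each gene, the per-cell expression of the single active allele in
#' monosomic cells is tested against half of the total allelic expression of
#' biallelic XX cells: without upregulation a single active copy should
#' produce exactly half the biallelic output. The test is a two-sided
#' unequal-variance (Welch) t-test by default; a gene is called upregulated
#' when p < alpha and fold change > `fc_threshold` -- the directional
#' fold-change gate makes the two-sided test effectively one-directional.
#'
#' @param mono_values Matrix genes x cells of active-allele TPM in monosomic
#'   cells.
#' @param xx_values Matrix genes x cells of total (both-allele) TPM in
#'   biallelic cells; row universe must match `mono_values`.
#' @param cfg An `analysis_config`.
#' @param var_equal Use the equal-variance Student variant.
#' @return An `xcu_calls` tibble: `gene_id`, `mean_mono_active`, `half_ref`,
#'   `fold_change`, `p_value`, `upregulated`.
#' @export
call_xcu_genes <- function(mono_values, xx_values, cfg = analysis_config(),
                           var_equal = FALSE) {
  genes <- intersect(rownames(mono_values), rownames(xx_values))
  if (length(genes) == 0) stop("no shared genes", call. = FALSE)
  if (ncol(mono_values) < 2 || ncol(xx_values) < 2) {
    stop("need at least two observations per group", call. = FALSE)
  }
  half <- xx_values[genes, , drop = FALSE] / 2
  mono <- mono_values[genes, , drop = FALSE]
  res <- purrr::map_dfr(seq_along(genes), function(i) {
    hr <- mean(half[i, ])
    mm <- mean(mono[i, ])
    if (hr == 0) {
      return(tibble::tibble(gene_id = genes[i], mean_mono_active = mm,
                            half_ref = hr, fold_change = NA_real_,
                            p_value = NA_real_, upregulated = NA))
    }
    tt <- safe_t_test(mono[i, ], half[i, ], var.equal = var_equal)
    fc <- mm / hr
    tibble::tibble(gene_id = genes[i], mean_mono_active = mm, half_ref = hr,
                   fold_change = fc, p_value = tt$p.value,
                   upregulated = !is.na(tt$p.value) && tt$p.value < cfg$alpha &&
                     fc > cfg$fc_threshold)
  })
  structure(res, class = c("xcu_calls", class(res)))
}

#' @exportS3Method generics::tidy
tidy.xcu_calls <- function(x, ...) tibble::as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.xcu_calls <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_upregulated = sum(x$upregulated, na.rm = TRUE),
                 fraction_upregulated = mean(x$upregulated, na.rm = TRUE))
}

#' Select upregulated genes from bulk copy-corrected TPM
#'
#' Genes expressed in the reference (mean copy-corrected TPM above
#' `cfg$expressed_min_tpm` in the biallelic samples) whose XO/XX mean fold
#' change strictly exceeds `cfg$fc_threshold`.
#'
#' @param xo_cc,xx_cc Matrices genes x samples of copy-number-corrected TPM.
#' @param cfg An `analysis_config`.
#' @return Tibble with `gene_id`, `mean_xo`, `mean_xx`, `fold_change`,
#'   `expressed`, `selected`.
#' @export
select_upregulated_bulk <- function(xo_cc, xx_cc, cfg = analysis_config()) {
  genes <- intersect(rownames(xo_cc), rownames(xx_cc))
  mxo <- rowMeans(xo_cc[genes, , drop = FALSE])
  mxx <- rowMeans(xx_cc[genes, , drop = FALSE])
  expressed <- !is.na(mxx) & mxx > cfg$expressed_min_tpm
  fc <- ifelse(mxx > 0, mxo / mxx, NA_real_)
  tibble::tibble(gene_id = genes, mean_xo = unname(mxo),
                 mean_xx = unname(mxx), fold_change = unname(fc),
                 expressed = unname(expressed),
                 selected = unname(expressed & !is.na(fc) &
                                     fc > cfg$fc_threshold))
}

#' Region compensation test across genotypes
#'
#' Compares region-level expression between genotypes. With
#' `method = "paired_t_bonferroni"` each pair of genotypes is compared by a
#' two-sided paired t-test over per-gene means (paired by gene), Bonferroni-
#' corrected over the number of pairs. With `method = "tukey_hsd"` the
#' per-replicate region means are compared by the studentized-range test.
#' When the region holds fewer than `cfg$min_region_genes` genes the test
#' abstains (all results `NA` with a reason), mirroring the refusal to test
#' sparse within-deletion gene sets.
#'
#' @param values_by_genotype Named list of matrices (genes x replicates)
#'   sharing a gene universe.
#' @param method `"paired_t_bonferroni"` or `"tukey_hsd"`.
#' @param cfg An `analysis_config`.
#' @param region_name Label stored in the result.
#' @return A `region_test` tibble with `contrast`, `estimate`, `p_value`,
#'   `p_adj`, plus attributes `method`, `n_genes`, `tested`, `reason`.
#' @export
test_region_compensation <- function(values_by_genotype,
                                     method = c("paired_t_bonferroni",
                                                "tukey_hsd"),
                                     cfg = analysis_config(),
                                     region_name = "region") {
  method <- match.arg(method)
  k <- length(values_by_genotype)
  if (k < 2) stop("need at least two genotypes", call. = FALSE)
  labs <- names(values_by_genotype)
  mats <- purrr::map(values_by_genotype, as.matrix)
  genes <- Reduce(intersect, purrr::map(mats, rownames))
  n_genes <- length(genes)
  pairs <- utils::combn(k, 2)
  empty <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    tibble::tibble(region = region_name,
                   contrast = paste(labs[pairs[2, j]], "-", labs[pairs[1, j]]),
                   estimate = NA_real_, p_value = NA_real_, p_adj = NA_real_)
  })
  if (method == "paired_t_bonferroni" && n_genes < cfg$min_region_genes) {
    return(structure(empty, method = method, n_genes = n_genes,
                     tested = FALSE, reason = "too few genes",
                     class = c("region_test", class(empty))))
  }
  if (method == "tukey_hsd") {
    groups <- purrr::map(mats, function(m) colMeans(m[genes, , drop = FALSE]))
    th <- tukey_hsd(groups)
    out <- tibble::tibble(region = region_name,
                          contrast = paste(th$group2, "-", th$group1),
                          estimate = th$diff, p_value = th$p_adj,
                          p_adj = th$p_adj)
  } else {
    gm <- purrr::map(mats, function(m) rowMeans(m[genes, , drop = FALSE]))
    rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      x <- gm[[pairs[2, j]]]
      y <- gm[[pairs[1, j]]]
      tt <- safe_t_test(x, y, paired = TRUE)
      tibble::tibble(region = region_name,
                     contrast = paste(labs[pairs[2, j]], "-",
                                      labs[pairs[1, j]]),
                     estimate = tt$estimate, p_value = tt$p.value)
    })
    rows$p_adj <- adjust_pvalues(rows$p_value, "bonferroni")
    out <- rows
  }
  structure(out, method = method, n_genes = n_genes, tested = TRUE,
            reason = NA_character_,
            class = c("region_test", class(out)))
}

#' Call cis-silenced genes from a dox induction experiment
#'
#' A gene is silenced when the mean targeted-allele expression with
#' doxycycline falls below `threshold` times the mean without.
#'
#' @param plus_dox,minus_dox Matrices genes x replicates of targeted-allele
#'   TPM.
#' @param threshold Fold-change threshold (default 0.15).
#' @return Tibble `gene_id`, `cis_fc`, `silenced` (`NA` when the baseline
#'   mean is zero).
#' @export
call_silenced_genes <- function(plus_dox, minus_dox, threshold = 0.15) {
  genes <- intersect(rownames(plus_dox), rownames(minus_dox))
  mp <- rowMeans(plus_dox[genes, , drop = FALSE])
  mm <- rowMeans(minus_dox[genes, , drop = FALSE])
  fc <- ifelse(mm > 0, mp / mm, NA_real_)
  tibble::tibble(gene_id = genes, cis_fc = unname(fc),
                 silenced = unname(fc < threshold))
}

#' Define the silenced region from silenced-gene density
#'
#' Slides a window along the chromosome and keeps windows whose
#' silenced-gene density reaches `min_density`; the union of consecutive
#' qualifying windows is the silenced region, extended to the telomere when
#' the last window qualifies. With `detect = FALSE` the configured fallback
#' region is returned verbatim.
#'
#' @param silenced_tss Numeric TSS positions of silenced genes.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length (bp).
#' @param window,step Window and step sizes in bp.
#' @param min_density Minimum silenced genes per window.
#' @param detect Run detection; if `FALSE`, return `fallback`.
#' @param fallback Region list/tibble with `chrom`, `start`, `end`.
#' @return Tibble with `name`, `chrom`, `start`, `end` (zero rows when no
#'   window qualifies, with a warning).
#' @export
define_silenced_region <- function(silenced_tss, chrom, chrom_length,
                                   window = 10e6, step = 1e6,
                                   min_density = 5, detect = TRUE,
                                   fallback = NULL) {
  if (!detect) {
    if (is.null(fallback)) stop("detect = FALSE needs a fallback region",
                                call. = FALSE)
    return(tibble::tibble(name = "silenced", chrom = fallback$chrom,
                          start = fallback$start, end = fallback$end))
  }
  if (length(silenced_tss) == 0) {
    warning("no silenced genes; empty region")
    return(tibble::tibble(name = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  starts <- seq(0, max(0, chrom_length - window), by = step)
  dens <- vapply(starts, function(s) {
    sum(silenced_tss >= s & silenced_tss < s + window)
  }, numeric(1))
  ok <- dens >= min_density
  if (!any(ok)) {
    warning("no window reaches min_density; empty region")
    return(tibble::tibble(name = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  r <- rle(ok)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  keep <- which(r$values)
  purrr::map_dfr(seq_along(keep), function(j) {
    i1 <- starts_i[keep[j]]
    i2 <- ends_i[keep[j]]
    reg_end <- if (i2 == length(starts)) chrom_length else
      starts[i2] + window
    tibble::tibble(name = paste0("silenced_", j), chrom = chrom,
                   start = starts[i1], end = min(reg_end, chrom_length))
  })
}

#' Call trans-upregulated genes in a cis-silencing experiment
#'
#' The trans (untargeted) allele's dox+/dox- log2 fold change is compared to
#' a threshold; the default rule is log2FC > `log2fc_threshold` (the
#' literal linear-ratio rule `fc > threshold` is near-vacuous and provided
#' as `mode = "linear"` for completeness).
#'
#' @param plus_dox,minus_dox Matrices genes x replicates of trans-allele TPM.
#' @param log2fc_threshold Threshold (log2 units in the default mode,
#'   linear ratio in `"linear"` mode).
#' @param mode `"log2"` or `"linear"`.
#' @return Tibble `gene_id`, `trans_log2fc`, `trans_upregulated`.
#' @export
call_trans_upregulated <- function(plus_dox, minus_dox,
                                   log2fc_threshold = 0.5,
                                   mode = c("log2", "linear")) {
  mode <- match.arg(mode)
  genes <- intersect(rownames(plus_dox), rownames(minus_dox))
  mp <- rowMeans(plus_dox[genes, , drop = FALSE])
  mm <- rowMeans(minus_dox[genes, , drop = FALSE])
  fc <- ifelse(mm > 0, mp / mm, NA_real_)
  lfc <- log2(fc)
  up <- if (mode == "log2") lfc > log2fc_threshold else fc > log2fc_threshold
  tibble::tibble(gene_id = genes, trans_log2fc = unname(lfc),
                 trans_upregulated = unname(up))
}

#' Compare the annotation overlap of two gene sets
#'
#' Builds the 2x2 table (set membership x annotation membership) and applies
#' the chi-square proportion test. When the annotation covers the entire
#' universe (or none of it) the proportions are identical by construction
#' and the test degenerates to statistic 0, p 1.
#'
#' @param setA,setB Character vectors of gene ids (disjoint sets from a
#'   common universe, e.g. upregulated vs non-upregulated).
#' @param annotation_set Character vector of annotated gene ids (escapees,
#'   complex members, ...).
#' @return List with `table`, `proportions` (tibble) and `test` (tibble from
#'   [chi_square_2x2()]).
#' @export
compare_gene_set_proportions <- function(setA, setB, annotation_set) {
  if (length(setA) == 0 || length(setB) == 0) {
    stop("empty gene set", call. = FALSE)
  }
  aIn <- sum(setA %in% annotation_set)
  bIn <- sum(setB %in% annotation_set)
  tab <- matrix(c(aIn, length(setA) - aIn, bIn, length(setB) - bIn),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("setA", "setB"),
                                c("annotated", "not_annotated")))
  props <- tibble::tibble(set = c("setA", "setB"),
                          n = c(length(setA), length(setB)),
                          n_annotated = c(aIn, bIn),
                          proportion = c(aIn / length(setA),
                                         bIn / length(setB)))
  test <- if (any(colSums(tab) == 0)) {
    tibble::tibble(statistic = 0, p_value = 1, df = 1L)
  } else {
    chi_square_2x2(tab)
  }
  list(table = tab, proportions = props, test = test)
}

#' Single-cell XCU calling on a full experiment
#'
#' Convenience wrapper assembling the monosomic active-allele and biallelic
#' total matrices from a sample table with genotype calls, then running
#' [call_xcu_genes()] on the X-linked genes.
#'
#' @param m An `allelic_matrix` in TPM.
#' @param sample_table Tibble with `sample_id` and `genotype_label`
#'   (profiles named as in [standard_copy_profiles()]).
#' @param annotation Annotation tibble.
#' @param x_chrom X chromosome name.
#' @param cfg An `analysis_config`.
#' @param mono_genotypes Named list mapping genotype labels to the active
#'   allele (1 or 2); defaults to the standard monosomy genotypes.
#' @param xx_genotype Label of the biallelic genotype.
#' @return An `xcu_calls` tibble.
#' @export
call_xcu_from_experiment <- function(m, sample_table, annotation,
                                     x_chrom = "chrX",
                                     cfg = analysis_config(),
                                     mono_genotypes = list(XCastOMus = 2,
                                                           XMusOCast = 1,
                                                           XY = 1),
                                     xx_genotype = "XX") {
  xg <- intersect(annotation$gene_id[annotation$chrom == x_chrom],
                  gene_ids(m))
  xx_ids <- sample_table$sample_id[
    sample_table$genotype_label == xx_genotype]
  xx_ids <- intersect(xx_ids, sample_ids(m))
  mono_cols <- list()
  for (g in names(mono_genotypes)) {
    ids <- intersect(
      sample_table$sample_id[sample_table$genotype_label == g],
      sample_ids(m))
    if (length(ids) == 0) next
    mat <- if (mono_genotypes[[g]] == 1) m$a1 else m$a2
    mono_cols[[g]] <- mat[xg, ids, drop = FALSE]
  }
  if (length(mono_cols) == 0) stop("no monosomic samples found", call. = FALSE)
  mono <- do.call(cbind, mono_cols)
  xx_tot <- total_expression(m)[xg, xx_ids, drop = FALSE]
  call_xcu_genes(mono, xx_tot, cfg = cfg)
}
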