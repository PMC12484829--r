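#' Analysis configuration
#'
#' Thresholds of the dosage analysis, defaulted to the values the study
#' design prescribes: single-cell gene-set means trim to the 10th-90th
#' percentile, bulk autosomal summaries to the 5th-95th; bulk genes count as
#' expressed above 5 TPM; upregulation requires fold change > 1.2 at
#' alpha = 0.05; visualization log2 fold changes are clipped to [-1, 4].
#' Percentiles use linear interpolation between order statistics (R quantile
#' type 7) throughout, so trimmed means are stable and reproducible.
#'
#' @param trim_lower_pct,trim_upper_pct Trim percentiles.
#' @param expressed_min_tpm Expressed-gene TPM filter for bulk data.
#' @param fc_threshold Fold-change gate for upregulation calls.
#' @param alpha Significance level.
#' @param clip_bounds Two-element clip range in log2 units.
#' @param min_region_genes Minimum gene count below which region tests
#'   abstain.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(trim_lower_pct = 10, trim_upper_pct = 90,
                            expressed_min_tpm = 5, fc_threshold = 1.2,
                            alpha = 0.05, clip_bounds = c(-1, 4),
                            min_region_genes = 10) {
  stopifnot(trim_lower_pct >= 0, trim_lower_pct < trim_upper_pct,
            trim_upper_pct <= 100, fc_threshold > 1,
            length(clip_bounds) == 2)
  structure(list(trim_lower_pct = trim_lower_pct,
                 trim_upper_pct = trim_upper_pct,
                 expressed_min_tpm = expressed_min_tpm,
                 fc_threshold = fc_threshold, alpha = alpha,
                 clip_bounds = clip_bounds,
                 min_region_genes = min_region_genes),
            class = "analysis_config")
}

#' Trimmed mean of a gene-set expression vector
#'
#' Percentile bounds are computed by linear interpolation over the values of
#' the set within one sample; the mean is then taken over values lying
#' inclusively between the bounds (inclusive bounds maximize retained genes
#' in sparse cells). A single value is its own trimmed mean.
#'
#' @param values Numeric vector of per-gene expression for one sample.
#' @param cfg An `analysis_config` (or lower/upper via `...`).
#' @param lower,upper Override trim percentiles.
#' @return The trimmed mean (scalar).
#' @export
trimmed_mean_expression <- function(values, cfg = analysis_config(),
                                    lower = cfg$trim_lower_pct,
                                    upper = cfg$trim_upper_pct) {
  if (length(values) == 0) stop("empty gene set", call. = FALSE)
  q <- stats::quantile(values, c(lower, upper) / 100, type = 7, names = FALSE)
  keep <- values >= q[1] & values <= q[2]
  if (!any(keep)) stop("trim retained no values", call. = FALSE)
  mean(values[keep])
}

#' Allele-matched X:autosome expression ratio
#'
#' Per sample: the trimmed mean of the X-linked (or supplied) gene set on one
#' allele, divided by the median of autosomal genes on the same allele (the
#' same trim is applied to the autosomal set before taking its median).
#' Allele matching is essential: it is the only convention under which the
#' per-allele X:A of biallelic XX cells matches that of a monosomic cell
#' without upregulation.
#'
#' @param m An `allelic_matrix` in TPM.
#' @param annotation Annotation tibble.
#' @param allele 1 or 2.
#' @param gene_set Gene ids of the numerator set (default: all X-linked).
#' @param x_chrom X chromosome name.
#' @param cfg An `analysis_config`.
#' @return Tibble with `sample_id`, `allele`, `set_trimmed_mean`,
#'   `autosomal_median`, `x_to_a`.
#' @export
x_to_autosome_ratio <- function(m, annotation, allele = 1, gene_set = NULL,
                                x_chrom = "chrX", cfg = analysis_config()) {
  if (m$unit != "tpm") stop("x_to_autosome_ratio expects TPM", call. = FALSE)
  mat <- if (allele == 1) m$a1 else m$a2
  xg <- gene_set %||% annotation$gene_id[annotation$chrom == x_chrom]
  xg <- intersect(xg, rownames(mat))
  ag <- intersect(annotation$gene_id[annotation$chrom != x_chrom],
                  rownames(mat))
  if (length(xg) == 0) stop("empty numerator gene set", call. = FALSE)
  if (length(ag) == 0) stop("no autosomal genes", call. = FALSE)
  res <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    xv <- mat[xg, j]
    av <- mat[ag, j]
    q <- stats::quantile(av, c(cfg$trim_lower_pct, cfg$trim_upper_pct) / 100,
                         type = 7, names = FALSE)
    amed <- stats::median(av[av >= q[1] & av <= q[2]])
    if (!is.finite(amed) || amed == 0) {
      stop("zero autosomal median in sample ", colnames(mat)[j],
           call. = FALSE)
    }
    tm <- trimmed_mean_expression(xv, cfg)
    tibble::tibble(sample_id = colnames(mat)[j], allele = allele,
                   set_trimmed_mean = tm, autosomal_median = amed,
                   x_to_a = tm / amed)
  })
  res
}

#' Copy-number correction of expression or abundance values
#'
#' Divides each gene's value by its total copy number under the profile so
#' per-copy output is comparable across genotypes; zero-copy genes become
#' `NA`. Operates on a plain gene-by-sample matrix or on the total (a1 + a2)
#' of an `allelic_matrix`.
#'
#' @param x Matrix (genes x samples) or `allelic_matrix`.
#' @param profile A `copy_profile`.
#' @param annotation Annotation tibble.
#' @return Numeric matrix of copy-corrected values.
#' @export
copy_number_correct <- function(x, profile, annotation) {
  mat <- if (inherits(x, "allelic_matrix")) total_expression(x) else as.matrix(x)
  cn <- gene_copy_numbers(annotation, profile)
  copies <- cn$copies_total[match(rownames(mat), cn$gene_id)]
  if (anyNA(copies)) {
    stop("genes absent from annotation: ",
         paste(utils::head(rownames(mat)[is.na(copies)], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- mat / copies
  out[copies == 0, ] <- NA_real_
  out
}

#' Partition genes on a chromosome by region membership
#'
#' A gene is inside the region iff its TSS lies in `[start, end)` -- the TSS
#' rule is unambiguous for genes straddling a boundary. Genes on other
#' chromosomes belong to neither set.
#'
#' @param annotation Annotation tibble.
#' @param region One-row tibble/list with `chrom`, `start`, `end`.
#' @return List with character vectors `inside` and `outside`.
#' @export
partition_genes_by_region <- function(annotation, region) {
  on_chrom <- annotation[annotation$chrom == region$chrom, ]
  inside <- on_chrom$tss >= region$start & on_chrom$tss < region$end
  list(inside = on_chrom$gene_id[inside],
       outside = on_chrom$gene_id[!inside])
}

#' Per-gene log2 fold change against a reference mean
#'
#' @param values Matrix (genes x samples) or named vector of expression.
#' @param reference Named per-gene reference means (e.g. mean of XX samples).
#' @param clip Clip the result to `cfg$clip_bounds` (visualization path
#'   only; statistics always use unclipped values).
#' @param cfg An `analysis_config`.
#' @return Matrix (or vector) of log2 fold changes; `NA` where the reference
#'   is not positive.
#' @export
per_gene_log2fc <- function(values, reference, clip = FALSE,
                            cfg = analysis_config()) {
  vec_in <- is.null(dim(values))
  mat <- if (vec_in) matrix(values, ncol = 1,
                            dimnames = list(names(values), "value"))
         else as.matrix(values)
  ref <- reference[rownames(mat)]
  lfc <- log2(mat / ref)
  lfc[!is.finite(ref) | ref <= 0, ] <- NA_real_
  if (clip) {
    lfc[] <- pmin(pmax(lfc, cfg$clip_bounds[1]), cfg$clip_bounds[2])
  }
  if (vec_in) lfc[, 1] else lfc
}

#' Pairwise Pearson correlation between samples
#'
#' Computed on total TPM of autosomal genes (the standard global-similarity
#' check that heterozygous deletions leave the transcriptome intact).
#' Zero-variance samples yield `NA` rows/columns.
#'
#' @param m An `allelic_matrix` in TPM.
#' @param annotation Annotation tibble.
#' @param x_chrom X chromosome name (excluded).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(m, annotation, x_chrom = "chrX") {
  if (ncol(m$a1) < 2) stop("need at least two samples", call. = FALSE)
  ag <- intersect(annotation$gene_id[annotation$chrom != x_chrom],
                  gene_ids(m))
  tot <- total_expression(m)[ag, , drop = FALSE]
  suppressWarnings(cc <- stats::cor(tot, method = "pearson"))
  diag(cc) <- 1
  cc
}

#' Region-wise dosage summary
#'
#' Trimmed-mean expression per allele for a gene set in every sample,
#' together with the allele-matched X:A ratio -- the per-cell quantity behind
#' the violin summaries of monosomy experiments.
#'
#' @param m An `allelic_matrix` in TPM.
#' @param annotation Annotation tibble.
#' @param gene_set Gene ids (default all X-linked).
#' @param set_name Label stored in the output.
#' @param x_chrom X chromosome name.
#' @param cfg An `analysis_config`.
#' @return Tibble with one row per sample and allele.
#' @export
dosage_summary <- function(m, annotation, gene_set = NULL,
                           set_name = "chrX", x_chrom = "chrX",
                           cfg = analysis_config()) {
  out <- dplyr::bind_rows(
    x_to_autosome_ratio(m, annotation, 1, gene_set, x_chrom, cfg),
    x_to_autosome_ratio(m, annotation, 2, gene_set, x_chrom, cfg)
  )
  out$gene_set <- set_name
  n_used <- length(gene_set %||%
                     intersect(annotation$gene_id[annotation$chrom == x_chrom],
                               gene_ids(m)))
  out$n_genes_used <- n_used
  class(out) <- c("dosage_summary", class(out))
  out
}
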