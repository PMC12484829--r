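#' Filter cells on minimum per-allele UMI counts
#'
#' Cells with fewer than `min_umis` total counts on either allele are
#' removed; the comparison is strict ("less than"), so a cell at exactly the
#' threshold is retained. Idempotent by construction.
#'
#' @param m An `allelic_matrix` with raw counts, cell modality.
#' @param min_umis Minimum total UMIs required on each allele.
#' @return The filtered `allelic_matrix`; attribute `removed` holds a tibble
#'   of dropped cells with their per-allele totals.
#' @export
filter_min_allelic_umis <- function(m, min_umis = 10000) {
  if (m$unit != "raw_count") {
    stop("filter_min_allelic_umis requires raw counts (unit is '",
         m$unit, "')", call. = FALSE)
  }
  t1 <- colSums(m$a1)
  t2 <- colSums(m$a2)
  keep <- !(t1 < min_umis | t2 < min_umis)
  removed <- tibble::tibble(sample_id = sample_ids(m)[!keep],
                            total_allele1 = t1[!keep],
                            total_allele2 = t2[!keep])
  out <- subset_allelic(m, samples = which(keep))
  attr(out, "removed") <- removed
  out
}

#' Classify X-chromosome status from allelic expression
#'
#' Per sample, the mean TPM over X-linked genes is computed for each allele.
#' If one allele's mean exceeds `threshold` while the other falls below it,
#' the sample is monosomic for the expressed allele; both above threshold is
#' biallelic XX; anything else is ambiguous (flagged for downstream
#' exclusion rather than guessed). XY cells carry the same allelic signature
#' as XO and can only be separated via sample metadata.
#'
#' @param m An `allelic_matrix` in TPM.
#' @param annotation Annotation tibble.
#' @param threshold Mean-TPM threshold (default 2).
#' @param x_chrom X chromosome name.
#' @return Tibble with `sample_id`, `mean_x_allele1`, `mean_x_allele2`,
#'   `call` in \{`biallelic_XX`, `X1_monosomic`, `X2_monosomic`,
#'   `ambiguous`\}.
#' @export
classify_x_status <- function(m, annotation, threshold = 2,
                              x_chrom = "chrX") {
  if (m$unit != "tpm") {
    stop("classify_x_status expects TPM values", call. = FALSE)
  }
  xg <- annotation$gene_id[annotation$chrom == x_chrom]
  xg <- intersect(xg, gene_ids(m))
  if (length(xg) == 0) stop("no X-linked genes in matrix", call. = FALSE)
  m1 <- colMeans(m$a1[xg, , drop = FALSE])
  m2 <- colMeans(m$a2[xg, , drop = FALSE])
  call <- dplyr::case_when(
    m1 > threshold & m2 > threshold ~ "biallelic_XX",
    m1 > threshold & m2 < threshold ~ "X1_monosomic",
    m2 > threshold & m1 < threshold ~ "X2_monosomic",
    TRUE ~ "ambiguous"
  )
  tibble::tibble(sample_id = sample_ids(m), mean_x_allele1 = unname(m1),
                 mean_x_allele2 = unname(m2), call = call)
}

#' Check pluripotency from marker-gene expression
#'
#' A sample passes when every marker's total (both-allele) TPM satisfies
#' log2(TPM) > `log2_threshold`; a zero-TPM marker fails without numeric
#' exceptions.
#'
#' @param m An `allelic_matrix` in TPM.
#' @param marker_genes Marker gene ids.
#' @param log2_threshold Threshold on log2(TPM).
#' @return List with `samples` (tibble `sample_id`, `pluripotent`) and
#'   `markers` (long tibble of per-marker TPM and pass flags).
#' @export
check_pluripotency <- function(m, marker_genes = c("Esrrb", "Nanog", "Pou5f1"),
                               log2_threshold = 2.5) {
  if (m$unit != "tpm") stop("check_pluripotency expects TPM", call. = FALSE)
  missing <- setdiff(marker_genes, gene_ids(m))
  if (length(missing)) {
    stop("marker gene(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tot <- total_expression(m)[marker_genes, , drop = FALSE]
  pass_mat <- tot > 2^log2_threshold   # log2(tpm) > thr, zero-safe
  markers <- tibble::tibble(
    sample_id = rep(colnames(tot), each = nrow(tot)),
    marker = rep(marker_genes, times = ncol(tot)),
    tpm = as.vector(tot),
    pass = as.vector(pass_mat)
  )
  samples <- tibble::tibble(sample_id = colnames(tot),
                            pluripotent = unname(apply(pass_mat, 2, all)))
  list(samples = samples, markers = markers)
}

#' Infer heterozygous deletion boundaries from allelic fractions
#'
#' For every expressed gene on `chrom` the allelic fraction
#' a_i / (a_1 + a_2), averaged over the samples in `m`, is smoothed with a
#' centred running mean over `window_genes` genes (in chromosomal order).
#' A deleted segment on an allele is a maximal run of at least `min_run`
#' consecutive genes whose smoothed fraction falls below
#' `fraction_threshold`; its boundaries are the outermost gene span limits.
#' A run covering the whole chromosome is flagged as monosomy.
#'
#' @param m An `allelic_matrix` in TPM (the samples should be replicates of
#'   one line).
#' @param annotation Annotation tibble.
#' @param chrom Chromosome to scan.
#' @param window_genes Running-mean window (genes).
#' @param fraction_threshold Smoothed-fraction threshold calling a gene
#'   allele-absent.
#' @param min_run Minimum run length (genes).
#' @return Tibble with one row per detected segment: `allele`, `chrom`,
#'   `start`, `end`, `n_genes`, `monosomy`.
#' @export
infer_deletion_boundaries <- function(m, annotation, chrom,
                                      window_genes = 10,
                                      fraction_threshold = 0.1,
                                      min_run = 5) {
  ann <- annotation[annotation$chrom == chrom, ]
  ann <- ann[order(ann$start), ]
  ann <- ann[ann$gene_id %in% gene_ids(m), ]
  tot1 <- rowMeans(m$a1[ann$gene_id, , drop = FALSE])
  tot2 <- rowMeans(m$a2[ann$gene_id, , drop = FALSE])
  expressed <- (tot1 + tot2) > 0
  ann <- ann[expressed, ]
  if (nrow(ann) < min_run) {
    stop("fewer than min_run expressed genes on ", chrom, call. = FALSE)
  }
  f1 <- tot1[expressed] / (tot1[expressed] + tot2[expressed])
  runmean <- function(x, w) {
    # centred running mean, window shrinking at the edges
    n <- length(x)
    half <- floor(w / 2)
    vapply(seq_len(n), function(i) {
      mean(x[max(1, i - half):min(n, i + half)])
    }, numeric(1))
  }
  find_runs <- function(flag, allele) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    purrr::map_dfr(which(keep), function(k) {
      i <- starts[k]:ends[k]
      tibble::tibble(allele = allele, chrom = chrom,
                     start = min(ann$start[i]), end = max(ann$end[i]),
                     n_genes = length(i),
                     monosomy = length(i) == nrow(ann))
    })
  }
  out <- dplyr::bind_rows(
    find_runs(runmean(f1, window_genes) < fraction_threshold, "a1"),
    find_runs(runmean(1 - f1, window_genes) < fraction_threshold, "a2")
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(allele = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_genes = integer(), monosomy = logical()))
  }
  out
}

#' Per-gene expression ratio of a sample to reference samples
#'
#' Total (both-allele) TPM of `sample_id` divided by the mean total TPM of
#' the reference samples, gene by gene; genes with zero reference mean are
#' reported as `NA`. Used to validate heterozygous deletions (the ratio drops
#' to ~0.5 over a deleted segment in the absence of compensation).
#'
#' @param m An `allelic_matrix` in TPM containing sample and references.
#' @param sample_id Sample to test.
#' @param reference_ids Reference sample ids.
#' @return Tibble with `gene_id`, `sample_tpm`, `reference_mean`, `ratio`.
#' @export
validate_deletion_ratio <- function(m, sample_id, reference_ids) {
  if (length(reference_ids) == 0) {
    stop("empty reference sample set", call. = FALSE)
  }
  tot <- total_expression(m)
  s <- tot[, sample_id]
  ref <- rowMeans(tot[, reference_ids, drop = FALSE])
  tibble::tibble(
    gene_id = rownames(tot),
    sample_tpm = unname(s),
    reference_mean = unname(ref),
    ratio = unname(ifelse(ref > 0, s / ref, NA_real_))
  )
}

#' QC report for a dataset
#'
#' Combines per-sample allele totals, the UMI filter verdict, the genotype
#' call and pluripotency into one tidy table (the TSV written by the
#' pipeline's qc stage).
#'
#' @param m Raw-count `allelic_matrix`.
#' @param annotation Annotation tibble.
#' @param min_umis UMI threshold (cell modality only).
#' @param mode TPM mode for the internal normalization.
#' @return Tibble with one row per sample.
#' @export
qc_report <- function(m, annotation, min_umis = 10000,
                      mode = c("umi_tpm", "length_tpm")) {
  mode <- match.arg(mode)
  t1 <- colSums(m$a1)
  t2 <- colSums(m$a2)
  pass_umi <- if (m$modality == "cell") {
    !(t1 < min_umis | t2 < min_umis)
  } else rep(TRUE, ncol(m$a1))
  tpm <- normalize_expression(m, mode = mode, annotation = annotation)
  calls <- classify_x_status(tpm, annotation)
  pluri <- tryCatch(check_pluripotency(tpm)$samples$pluripotent,
                    error = function(e) rep(NA, ncol(m$a1)))
  tibble::tibble(
    sample_id = sample_ids(m),
    total_allele1 = unname(t1), total_allele2 = unname(t2),
    pass_umi_filter = unname(pass_umi),
    x_status = calls$call,
    pluripotent = pluri
  )
}
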