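#' Normalize allelic counts to TPM
#'
#' Both alleles of a sample are scaled jointly by a single factor so that the
#' sum over all genes and both alleles is one million. Scaling each allele
#' separately would erase monosomy signal (an XO cell would look identical to
#' an XX cell) and make upregulation undetectable, so the per-sample factor is
#' always shared. Within-gene allelic fractions are therefore unchanged.
#'
#' `umi_tpm` treats counts as molecule counts and applies no length
#' correction; `length_tpm` first converts counts to rates per kilobase of
#' gene length (exonic length when the annotation provides one) before the
#' joint scaling, the conventional TPM for read-based bulk data.
#'
#' @param m An `allelic_matrix` with `unit = "raw_count"`.
#' @param mode `"umi_tpm"` or `"length_tpm"`.
#' @param annotation Annotation tibble; required for `length_tpm`.
#' @param include_unassigned Include the unassigned matrix in the scaling
#'   denominator (and scale it along). Default `FALSE`.
#' @return An `allelic_matrix` with `unit = "tpm"`.
#' @export
normalize_expression <- function(m, mode = c("umi_tpm", "length_tpm"),
                                 annotation = NULL,
                                 include_unassigned = FALSE) {
  mode <- match.arg(mode)
  if (m$unit != "raw_count") {
    stop("normalize_expression expects raw counts, got unit '", m$unit, "'",
         call. = FALSE)
  }
  r1 <- m$a1
  r2 <- m$a2
  ru <- m$unassigned
  if (mode == "length_tpm") {
    if (is.null(annotation)) {
      stop("length_tpm requires a gene annotation", call. = FALSE)
    }
    len <- annotation$length[match(rownames(r1), annotation$gene_id)]
    if (anyNA(len)) {
      stop("length_tpm requires lengths for all genes; missing: ",
           paste(utils::head(rownames(r1)[is.na(len)], 5), collapse = ", "),
           call. = FALSE)
    }
    kb <- len / 1000
    r1 <- r1 / kb
    r2 <- r2 / kb
    if (!is.null(ru)) ru <- ru / kb
  }
  denom <- colSums(r1) + colSums(r2)
  if (include_unassigned && !is.null(ru)) denom <- denom + colSums(ru)
  zero <- denom == 0
  if (any(zero)) {
    stop("sample(s) with zero total assigned counts: ",
         paste(colnames(r1)[zero], collapse = ", "), call. = FALSE)
  }
  scale <- 1e6 / denom
  out1 <- sweep(r1, 2, scale, `*`)
  out2 <- sweep(r2, 2, scale, `*`)
  outu <- if (is.null(ru)) NULL else sweep(ru, 2, scale, `*`)
  allelic_matrix(out1, out2, unassigned = outu, unit = "tpm",
                 modality = m$modality)
}
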