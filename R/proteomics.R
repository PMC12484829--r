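#' Protein abundance matrix
#'
#' Label-free quantification abundances with a many-to-one protein-to-gene
#' map and a detection mask (`NA` abundances are undetected; no imputation
#' anywhere in the package).
#'
#' @param abundances Numeric proteins x samples matrix (`NA` = undetected).
#' @param map Tibble with `protein_id`, `gene_id`.
#' @param detected Logical matrix matching `abundances`; defaults to
#'   `!is.na(abundances)`.
#' @param sample_table Tibble with `sample_id`, `genotype_label`,
#'   `copy_profile_id`.
#' @return A `protein_matrix` object.
#' @export
protein_matrix <- function(abundances, map, detected = NULL,
                           sample_table = NULL) {
  abundances <- as.matrix(abundances)
  if (is.null(detected)) detected <- !is.na(abundances)
  stopifnot(identical(dim(detected), dim(abundances)))
  if (!all(rownames(abundances) %in% map$protein_id)) {
    stop("every protein needs a gene mapping", call. = FALSE)
  }
  if (any(abundances <= 0, na.rm = TRUE)) {
    stop("detected abundances must be positive", call. = FALSE)
  }
  structure(list(abund = abundances, map = map, detected = detected,
                 sample_table = sample_table),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("<protein_matrix> %d proteins x %d samples (%.1f%% detected)\n",
              nrow(x$abund), ncol(x$abund), 100 * mean(x$detected)))
  invisible(x)
}

#' Keep proteins detected in every sample
#'
#' @param m A `protein_matrix`.
#' @return The filtered `protein_matrix`; attribute `n_dropped` counts the
#'   removed proteins. An empty result is allowed (with a warning).
#' @export
filter_fully_detected <- function(m) {
  keep <- apply(m$detected, 1, all)
  if (!any(keep)) warning("no protein detected in every sample")
  out <- protein_matrix(m$abund[keep, , drop = FALSE],
                        m$map[m$map$protein_id %in% rownames(m$abund)[keep], ],
                        detected = m$detected[keep, , drop = FALSE],
                        sample_table = m$sample_table)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Copy-number correction of protein abundances
#'
#' Each protein's abundance is divided by the total copy number of its gene
#' in that sample's genotype: 2 for autosomal proteins everywhere and for
#' X-linked proteins in XX samples, 1 for X-linked proteins in monosomic
#' samples and for proteins inside a heterozygous deletion.
#'
#' @param m A `protein_matrix` with a `sample_table`.
#' @param profiles Named list of `copy_profile`s keyed by the sample table's
#'   `copy_profile_id`.
#' @param annotation Annotation tibble (gene coordinates for the profile
#'   lookup).
#' @return A `protein_matrix` of corrected abundances.
#' @export
copy_number_correct_protein <- function(m, profiles, annotation) {
  st <- m$sample_table
  if (is.null(st)) stop("protein matrix lacks a sample table", call. = FALSE)
  genes <- m$map$gene_id[match(rownames(m$abund), m$map$protein_id)]
  missing <- setdiff(genes, annotation$gene_id)
  if (length(missing)) {
    stop("gene(s) not resolvable in annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- m$abund
  for (pid in unique(st$copy_profile_id)) {
    cn <- gene_copy_numbers(annotation, profiles[[pid]])
    copies <- cn$copies_total[match(genes, cn$gene_id)]
    cols <- st$sample_id[st$copy_profile_id == pid]
    out[, cols] <- m$abund[, cols, drop = FALSE] / copies
    out[copies == 0, cols] <- NA_real_
  }
  res <- m
  res$abund <- out
  res
}

#' Protein-level X:autosome ratio per sample
#'
#' Restricted to proteins whose mean abundance in the XX samples exceeds
#' `min_xx_mean_abundance` (this guards against the detection bias of
#' low-abundance one-copy proteins); the ratio is each X-linked protein's
#' abundance divided by the mean autosomal abundance of the same sample.
#'
#' @param m A `protein_matrix`.
#' @param annotation Annotation tibble.
#' @param xx_samples Sample ids of the biallelic XX group.
#' @param min_xx_mean_abundance Abundance filter (default 1.2e7).
#' @param x_chrom X chromosome name.
#' @return List with `per_protein` (long tibble) and `per_sample` (mean X:A
#'   per sample).
#' @export
protein_x_to_a <- function(m, annotation, xx_samples,
                           min_xx_mean_abundance = 12e6,
                           x_chrom = "chrX") {
  genes <- m$map$gene_id[match(rownames(m$abund), m$map$protein_id)]
  chrom <- annotation$chrom[match(genes, annotation$gene_id)]
  xx_mean <- rowMeans(m$abund[, xx_samples, drop = FALSE], na.rm = TRUE)
  keep <- !is.na(xx_mean) & xx_mean > min_xx_mean_abundance
  if (!any(keep)) stop("no protein passes the XX abundance filter",
                       call. = FALSE)
  xp <- keep & chrom == x_chrom
  ap <- keep & chrom != x_chrom
  if (!any(xp)) stop("no X-linked protein passes the filter", call. = FALSE)
  auto_mean <- colMeans(m$abund[ap, , drop = FALSE], na.rm = TRUE)
  per_protein <- purrr::map_dfr(which(xp), function(i) {
    tibble::tibble(protein_id = rownames(m$abund)[i],
                   sample_id = colnames(m$abund),
                   x_to_a = unname(m$abund[i, ] / auto_mean))
  })
  per_sample <- dplyr::summarise(
    dplyr::group_by(per_protein, .data$sample_id),
    mean_x_to_a = mean(.data$x_to_a, na.rm = TRUE), .groups = "drop")
  list(per_protein = per_protein, per_sample = per_sample)
}

#' Differential protein abundance across XX / XY / XO genotypes
#'
#' Copy-corrected abundances are log2-transformed (variance stabilization
#' for LFQ data; `log_transform = FALSE` tests the raw scale) and compared
#' with the Tukey HSD studentized-range test across the three genotypes. A
#' protein is up-called when log2(fold change) > 0 and p < alpha in BOTH the
#' XO-vs-XX and XY-vs-XX contrasts; volcano labeling conventionally uses
#' |log2FC| > 0.5 on top.
#'
#' @param m_cc A copy-corrected `protein_matrix` with a `sample_table`.
#' @param xx,xo,xy Genotype labels.
#' @param alpha Significance level.
#' @param log_transform Test on the log2 scale.
#' @return A `protein_da` tibble: per protein log2FC and adjusted p per
#'   contrast plus the `upregulated` call.
#' @export
differential_protein_abundance <- function(m_cc, xx = "XX",
                                           xo = "XCastOMus", xy = "XY",
                                           alpha = 0.05,
                                           log_transform = TRUE) {
  st <- m_cc$sample_table
  groups_ids <- list(xx = st$sample_id[st$genotype_label == xx],
                     xo = st$sample_id[st$genotype_label == xo],
                     xy = st$sample_id[st$genotype_label == xy])
  if (any(lengths(groups_ids) < 2)) {
    stop("need >= 2 replicates in each of the XX, XO and XY groups",
         call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(nrow(m_cc$abund)), function(i) {
    vals <- purrr::map(groups_ids, function(ids) m_cc$abund[i, ids])
    if (any(vapply(vals, anyNA, TRUE))) {
      return(tibble::tibble(protein_id = rownames(m_cc$abund)[i],
                            log2fc_xo = NA_real_, p_xo = NA_real_,
                            log2fc_xy = NA_real_, p_xy = NA_real_,
                            upregulated = NA))
    }
    lfc_xo <- log2(mean(vals$xo) / mean(vals$xx))
    lfc_xy <- log2(mean(vals$xy) / mean(vals$xx))
    tv <- if (log_transform) purrr::map(vals, log2) else vals
    th <- tukey_hsd(tv)
    p_of <- function(a, b) {
      hit <- (th$group1 == a & th$group2 == b) |
        (th$group1 == b & th$group2 == a)
      th$p_adj[hit]
    }
    p_xo <- p_of("xx", "xo")
    p_xy <- p_of("xx", "xy")
    tibble::tibble(protein_id = rownames(m_cc$abund)[i],
                   log2fc_xo = lfc_xo, p_xo = p_xo,
                   log2fc_xy = lfc_xy, p_xy = p_xy,
                   upregulated = lfc_xo > 0 && p_xo < alpha &&
                     lfc_xy > 0 && p_xy < alpha)
  })
  res$gene_id <- m_cc$map$gene_id[match(res$protein_id, m_cc$map$protein_id)]
  structure(res, class = c("protein_da", class(res)))
}

#' RNA-protein concordance of dosage compensation
#'
#' Classifies each gene of the shared universe by whether it is upregulated
#' at the RNA level, the protein level, both or neither. The default rule is
#' the raw fold-change comparison (copy-corrected XO/XX FC > 1 counts as
#' increased); `rule = "significant_calls"` uses pre-computed boolean calls
#' instead. Also reports the Pearson correlation of the paired log2 fold
#' changes.
#'
#' @param rna_fc Named vector of copy-corrected XO/XX RNA fold changes.
#' @param prot_fc Named vector of copy-corrected XO/XX protein fold changes
#'   (names are gene ids).
#' @param rule `"fc_gt_1"` or `"significant_calls"`.
#' @param rna_up,prot_up Named logical vectors (required for
#'   `"significant_calls"`).
#' @return A `concordance` object: list with `records` (tibble `gene_id`,
#'   `rna_up`, `protein_up`, `category`), `proportions`, `correlation`.
#' @export
classify_rna_protein_concordance <- function(rna_fc, prot_fc,
                                             rule = c("fc_gt_1",
                                                      "significant_calls"),
                                             rna_up = NULL, prot_up = NULL) {
  rule <- match.arg(rule)
  genes <- intersect(names(rna_fc), names(prot_fc))
  if (length(genes) == 0) stop("empty gene intersection", call. = FALSE)
  if (rule == "fc_gt_1") {
    r_up <- rna_fc[genes] > 1
    p_up <- prot_fc[genes] > 1
  } else {
    if (is.null(rna_up) || is.null(prot_up)) {
      stop("significant_calls rule needs rna_up and prot_up", call. = FALSE)
    }
    r_up <- rna_up[genes]
    p_up <- prot_up[genes]
  }
  category <- dplyr::case_when(
    r_up & p_up ~ "both",
    r_up & !p_up ~ "rna_only",
    !r_up & p_up ~ "protein_only",
    TRUE ~ "neither"
  )
  records <- tibble::tibble(gene_id = genes, rna_up = unname(r_up),
                            protein_up = unname(p_up), category = category)
  proportions <- dplyr::count(records, .data$category) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
  r <- stats::cor(log2(rna_fc[genes]), log2(prot_fc[genes]),
                  use = "complete.obs")
  structure(list(records = records, proportions = proportions,
                 correlation = r),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("<concordance>", nrow(x$records), "genes; r =",
      round(x$correlation, 3), "\n")
  print(x$proportions)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.concordance <- function(x, ...) {
  wide <- stats::setNames(as.list(x$proportions$proportion),
                          x$proportions$category)
  tibble::as_tibble(c(list(n_genes = nrow(x$records),
                           correlation = x$correlation), wide))
}
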