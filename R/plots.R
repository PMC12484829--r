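#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style view of XCU calls
#'
#' Fold change against the half-of-biallelic reference versus -log10 p, with
#' called genes highlighted and the fold-change gate drawn.
#'
#' @param object An `xcu_calls` tibble.
#' @param cfg An `analysis_config` (for the gate lines).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.xcu_calls <- function(object, cfg = analysis_config(), ...) {
  df <- tibble::as_tibble(unclass(object))
  df <- df[!is.na(df$p_value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$p_value),
                                   colour = .data$upregulated)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = log2(cfg$fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "seagreen")) +
    ggplot2::labs(x = "log2 FC (active allele vs half of XX)",
                  y = "-log10 p", colour = "upregulated") +
    ggplot2::theme_minimal()
}

#' Metaprofile line plot
#'
#' Mean signal per bin with a standard-error ribbon; segment boundaries
#' (TSS/TES) are marked.
#'
#' @param object A `metaprofile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metaprofile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  n_flank <- sum(df$segment == "upstream")
  n_body <- sum(df$segment == "body")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5,
                                       n_flank + n_body + 0.5),
                        linetype = "dotted") +
    ggplot2::labs(x = "bin (5' flank | scaled body | 3' flank)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-sample X:A ratios by group
#'
#' @param summary A `dosage_summary` (or compatible tibble with `sample_id`,
#'   `allele`, `x_to_a`).
#' @param groups Named vector mapping sample ids to group labels (e.g.
#'   genotypes); defaults to one group.
#' @return A ggplot.
#' @export
plot_x_to_a <- function(summary, groups = NULL) {
  df <- tibble::as_tibble(summary)
  df$group <- if (is.null(groups)) "all" else groups[df$sample_id]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$x_to_a,
                                   fill = factor(.data$allele))) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         alpha = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.8),
                        size = 0.5, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "X:A ratio", fill = "allele") +
    ggplot2::theme_minimal()
}

#' Concordance scatter of RNA versus protein fold changes
#'
#' @param conc A `concordance` object.
#' @param rna_fc,prot_fc The named fold-change vectors used to build it.
#' @return A ggplot.
#' @export
plot_concordance <- function(conc, rna_fc, prot_fc) {
  df <- conc$records
  df$rna_lfc <- log2(rna_fc[df$gene_id])
  df$prot_lfc <- log2(prot_fc[df$gene_id])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rna_lfc, y = .data$prot_lfc,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         inherit.aes = FALSE,
                         ggplot2::aes(x = .data$rna_lfc,
                                      y = .data$prot_lfc)) +
    ggplot2::scale_colour_manual(values = c(
      both = "darkorange", rna_only = "steelblue",
      protein_only = "seagreen", neither = "grey60")) +
    ggplot2::labs(x = "RNA log2 FC (XO / half XX)",
                  y = "protein log2 FC (XO / corrected XX)") +
    ggplot2::theme_minimal()
}
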