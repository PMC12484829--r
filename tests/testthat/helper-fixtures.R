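# Shared fixtures: everything is built in code at test time.

# tiny deterministic allelic matrix from explicit values
toy_matrix <- function(a1, a2, genes = NULL, samples = NULL,
                       unit = "raw_count", modality = "cell",
                       unassigned = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  genes <- genes %||% paste0("g", seq_len(nrow(a1)))
  samples <- samples %||% paste0("s", seq_len(ncol(a1)))
  dimnames(a1) <- dimnames(a2) <- list(genes, samples)
  if (!is.null(unassigned)) {
    unassigned <- as.matrix(unassigned)
    dimnames(unassigned) <- list(genes, samples)
  }
  allelic_matrix(a1, a2, unassigned = unassigned, unit = unit,
                 modality = modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation tibble from vectors, deriving tss/tes/length
toy_annotation <- function(gene_id, chrom, start, end, strand = "+") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand,
                 tss = ifelse(strand == "+", start, end),
                 tes = ifelse(strand == "+", end, start),
                 length = end - start)
}

# small but realistic simulation shared by several tests (cached per session)
small_sim_config <- function(seed = 5, ...) {
  simulation_config(
    seed = seed,
    chrom_plan = tibble::tibble(chrom = c("chrX", "chr1"),
                                length = c(171e6, 195e6),
                                n_genes = c(120L, 400L)),
    genotypes = tibble::tibble(label = c("XX", "XCastOMus"),
                               n = c(12L, 10L),
                               profile = c("XX", "XCastOMus"), dox = FALSE),
    ...
  )
}
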