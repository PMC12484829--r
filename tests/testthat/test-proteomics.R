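toy_proteins <- function(abund, genes = NULL, genotypes = NULL,
                         profiles = NULL) {
  abund <- as.matrix(abund)
  genes <- genes %||% paste0("g", seq_len(nrow(abund)))
  rownames(abund) <- paste0("P_", genes)
  colnames(abund) <- colnames(abund) %||% paste0("s", seq_len(ncol(abund)))
  st <- NULL
  if (!is.null(genotypes)) {
    st <- tibble::tibble(sample_id = colnames(abund),
                         genotype_label = genotypes,
                         copy_profile_id = genotypes)
  }
  protein_matrix(abund, map = tibble::tibble(protein_id = rownames(abund),
                                             gene_id = genes),
                 sample_table = st)
}

test_that("full-detection filter drops proteins missing anywhere", {
  a <- matrix(c(1, 2, 3, NA, 5, 6, 7, 8, 9), 3, byrow = TRUE) * 1e6
  colnames(a) <- paste0("s", 1:3)
  pm <- toy_proteins(a)
  f <- filter_fully_detected(pm)
  expect_equal(nrow(f$abund), 2)
  expect_equal(attr(f, "n_dropped"), 1L)
  none <- toy_proteins(matrix(c(NA, 1, 2, NA), 2) * 1e6)
  expect_warning(f0 <- filter_fully_detected(none), "no protein")
  expect_equal(nrow(f0$abund), 0)
})

test_that("protein copy correction halves two-copy contexts only", {
  ann <- dplyr::bind_rows(
    toy_annotation("xin", "chrX", 10e6, 10.1e6),
    toy_annotation("xout", "chrX", 120e6, 120.1e6),
    toy_annotation("auto", "chr1", 5e6, 5.1e6))
  profs <- standard_copy_profiles("chrX", 171e6)
  profs$DelE <- copy_profile(
    tibble::tibble(chrom = "chrX", start = 0, end = 50e6,
                   copies_allele1 = 0L, copies_allele2 = 1L), "DelE")
  a <- matrix(1e7, 3, 3,
              dimnames = list(NULL, c("xx1", "xo1", "del1")))
  pm <- toy_proteins(a, genes = ann$gene_id,
                     genotypes = c("XX", "XCastOMus", "DelE"))
  cc <- copy_number_correct_protein(pm, profs, ann)
  expect_equal(cc$abund["P_xin", "xx1"], 5e6)    # X-linked, XX: /2
  expect_equal(cc$abund["P_xin", "xo1"], 1e7)    # X-linked, XO: unchanged
  expect_equal(cc$abund["P_xin", "del1"], 1e7)   # inside deletion: 1 copy
  expect_equal(cc$abund["P_xout", "del1"], 5e6)  # outside deletion: /2
  expect_equal(unname(cc$abund["P_auto", ]), rep(5e6, 3))  # autosomal: /2
  # round trip: multiplying back by copies restores the input exactly
  back <- cc$abund
  for (g in unique(pm$sample_table$copy_profile_id)) {
    cn <- gene_copy_numbers(ann, profs[[g]])
    cols <- pm$sample_table$sample_id[pm$sample_table$copy_profile_id == g]
    back[, cols] <- back[, cols, drop = FALSE] *
      cn$copies_total[match(pm$map$gene_id, cn$gene_id)]
  }
  expect_equal(back, pm$abund)
})

test_that("protein X:A applies the XX abundance filter and per-sample autosomal mean", {
  ann <- dplyr::bind_rows(
    toy_annotation("xhi", "chrX", 10e6, 10.1e6),
    toy_annotation("xlo", "chrX", 20e6, 20.1e6),
    toy_annotation("a1g", "chr1", 5e6, 5.1e6),
    toy_annotation("a2g", "chr1", 8e6, 8.1e6))
  a <- rbind(c(2e7, 2e7), c(1.1e7, 1.1e7), c(4e7, 3e7), c(4e7, 5e7))
  colnames(a) <- c("xx1", "xx2")
  pm <- toy_proteins(a, genes = ann$gene_id, genotypes = c("XX", "XX"))
  r <- protein_x_to_a(pm, ann, xx_samples = c("xx1", "xx2"))
  expect_equal(unique(r$per_protein$protein_id), "P_xhi")  # xlo < 1.2e7
  expect_equal(r$per_protein$x_to_a, c(0.5, 0.5))
  expect_error(protein_x_to_a(pm, ann, xx_samples = c("xx1", "xx2"),
                              min_xx_mean_abundance = 1e9),
               "no protein passes")
})

test_that("differential abundance requires upregulation in both monosomy contrasts", {
  ann <- dplyr::bind_rows(
    toy_annotation("dosage_loss", "chrX", 10e6, 10.1e6),
    toy_annotation("both_up", "chrX", 30e6, 30.1e6),
    toy_annotation("xo_only", "chrX", 60e6, 60.1e6))
  profs <- standard_copy_profiles("chrX", 171e6)
  set.seed(71)
  n <- 3
  noise <- function(mu) mu * 2^rnorm(n, 0, 0.05)
  a <- rbind(
    c(noise(1e7), noise(0.5e7), noise(0.5e7)),  # halves with copy loss
    c(noise(1e7), noise(1e7), noise(1e7)),      # maintained: compensated
    c(noise(1e7), noise(1e7), noise(0.5e7)))    # compensated in XO only
  colnames(a) <- c(paste0("xx", 1:n), paste0("xo", 1:n), paste0("xy", 1:n))
  pm <- toy_proteins(a, genes = ann$gene_id,
                     genotypes = rep(c("XX", "XCastOMus", "XY"), each = n))
  cc <- copy_number_correct_protein(pm, profs, ann)
  da <- differential_protein_abundance(cc)
  expect_false(da$upregulated[da$gene_id == "dosage_loss"])
  expect_true(da$upregulated[da$gene_id == "both_up"])
  expect_false(da$upregulated[da$gene_id == "xo_only"])
})

test_that("concordance categories partition the shared universe", {
  rna_fc <- c(A = 2, B = 1.8, C = 0.9, D = 0.7)
  prot_fc <- c(A = 0.8, B = 2.2, C = 1.6, D = 0.9)
  conc <- classify_rna_protein_concordance(rna_fc, prot_fc)
  rec <- conc$records
  expect_equal(rec$category[match(c("A", "B", "C", "D"), rec$gene_id)],
               c("rna_only", "both", "protein_only", "neither"))
  expect_equal(sum(conc$proportions$n), 4)
  expect_equal(sum(conc$proportions$proportion), 1)
  expect_true(conc$correlation >= -1 && conc$correlation <= 1)
  expect_error(classify_rna_protein_concordance(c(X = 1), c(Y = 1)),
               "empty")
  # explicit-call rule
  conc2 <- classify_rna_protein_concordance(
    rna_fc, prot_fc, rule = "significant_calls",
    rna_up = c(A = TRUE, B = TRUE, C = FALSE, D = FALSE),
    prot_up = c(A = FALSE, B = TRUE, C = TRUE, D = FALSE))
  expect_equal(conc2$records$category,
               conc$records$category)
})

test_that("protein recovery separates compensated genes from the null genes", {
  g <- tibble::tibble(label = c("XX", "XCastOMus", "XY"), n = 4L,
                      profile = label, dox = FALSE)
  cfg <- simulation_config(
    seed = 81, genotypes = g,
    chrom_plan = tibble::tibble(chrom = c("chrX", "chr1"),
                                length = c(171e6, 195e6),
                                n_genes = c(150L, 300L)))
  sim <- simulate_allelic_counts(cfg)
  pr <- simulate_proteins(sim)
  pm <- filter_fully_detected(pr$proteins)
  cc <- copy_number_correct_protein(pm, cfg$profiles, sim$annotation)
  da <- differential_protein_abundance(cc)
  xg <- sim$annotation$gene_id[sim$annotation$chrom == "chrX"]
  ponly <- intersect(pr$truth$protein_only_compensated_ids, xg)
  called <- da$gene_id[which(da$upregulated)]
  # compensated genes are recovered far above the autosomal false-positive
  # rate (the full-power sensitivity bound is exercised at scale in the
  # acceptance suite)
  expect_gt(mean(ponly %in% called), 0.5)
  auto <- setdiff(sim$annotation$gene_id, xg)
  expect_lt(mean(auto %in% called), 0.05)
  expect_gt(mean(ponly %in% called), 10 * mean(auto %in% called))
})
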